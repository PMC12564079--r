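#' Dynamic (preictal minus interictal) entropy matrix
#'
#' Element-wise difference between a subject's preictal and interictal
#' entropy matrices, pairing epoch i with epoch i (the two one-minute
#' states are recorded independently, so index pairing is a positional
#' convention, not a physiological alignment). The sign convention makes
#' a preictal entropy drop negative, matching the PNES-type shift.
#'
#' @param pre,inter `entropy_matrix` objects for the same subject,
#'   measure and shape.
#' @return An `entropy_matrix` with `state = "dynamic"`.
#' @export
dynamic_matrix <- function(pre, inter) {
  if (!identical(dim(pre), dim(inter))) stop("shape mismatch")
  if (!identical(attr(pre, "measure"), attr(inter, "measure")))
    stop("measure mismatch")
  sid <- attr(pre, "subject_id")
  if (!identical(sid, attr(inter, "subject_id"))) stop("subject mismatch")
  out <- unclass(pre) - unclass(inter)
  structure(out, class = c("entropy_matrix", "matrix"),
            measure = attr(pre, "measure"), params = attr(pre, "params"),
            subject_id = sid, state = "dynamic",
            channels = attr(pre, "channels"))
}

#' Stack per-subject entropy matrices into a design matrix
#'
#' Row-binds each subject's epochs-by-channels matrix into one
#' observations-by-channels design (74 subjects with 12 epochs give
#' 888 x 17), with aligned per-row class labels (PNES = 1, ES = 0) and
#' subject ids. Subjects with unequal epoch counts across states should
#' be truncated upstream; each subject contributes one contiguous block.
#'
#' @param mats Named or unnamed list of `entropy_matrix` objects, one per
#'   subject (consistent measure/state).
#' @param groups Per-subject group, `"PNES"` or `"ES"`, aligned to
#'   `mats`.
#' @return An `entropy_design`: list with `x` (matrix), `label` (integer
#'   0/1), `subject` (character), `channels`, `measure`, `state`.
#' @export
stack_design <- function(mats, groups) {
  stopifnot(length(mats) == length(groups))
  sids <- vapply(mats, function(m) as.character(attr(m, "subject_id")),
                 character(1))
  if (anyDuplicated(sids)) stop("duplicate subject in design")
  meas <- unique(vapply(mats, function(m) attr(m, "measure"), character(1)))
  st <- unique(vapply(mats, function(m) as.character(attr(m, "state")),
                      character(1)))
  if (length(meas) != 1 || length(st) != 1)
    stop("inconsistent measure or state across subjects")
  x <- do.call(rbind, lapply(mats, unclass))
  label <- rep(ifelse(groups == "PNES", 1L, 0L),
               vapply(mats, nrow, integer(1)))
  subject <- rep(sids, vapply(mats, nrow, integer(1)))
  structure(list(x = x, label = label, subject = subject,
                 channels = colnames(x), measure = meas, state = st),
            class = "entropy_design")
}

#' @export
print.entropy_design <- function(x, ...) {
  cat(sprintf("<entropy_design> %s/%s: %d rows x %d channels, %d subjects (%d PNES / %d ES)\n",
              x$measure, x$state, nrow(x$x), ncol(x$x),
              length(unique(x$subject)),
              length(unique(x$subject[x$label == 1])),
              length(unique(x$subject[x$label == 0]))))
  invisible(x)
}

#' Recover one subject's block from a design matrix
#'
#' Inverse of [stack_design()] for a single subject; the round trip is
#' lossless.
#'
#' @param design An `entropy_design`.
#' @param subject_id Subject to extract.
#' @return The subject's epochs-by-channels matrix.
#' @export
unstack_subject <- function(design, subject_id) {
  design$x[design$subject == subject_id, , drop = FALSE]
}

#' Export a design matrix as a long table
#'
#' @param design An `entropy_design`.
#' @return A data.frame with columns subject_id, group, state, measure,
#'   epoch, channel, value.
#' @export
design_to_table <- function(design) {
  epoch <- stats::ave(seq_along(design$subject), design$subject,
                      FUN = seq_along)
  data.frame(
    subject_id = rep(design$subject, ncol(design$x)),
    group = rep(ifelse(design$label == 1, "PNES", "ES"), ncol(design$x)),
    state = design$state, measure = design$measure,
    epoch = rep(epoch, ncol(design$x)),
    channel = rep(design$channels, each = nrow(design$x)),
    value = as.vector(design$x))
}
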