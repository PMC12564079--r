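#' Minimal 16-bit EDF writer/reader
#'
#' Writes a set of recordings to European Data Format files (one `.edf`
#' per subject/state plus a `labels.json` sidecar carrying group and state)
#' and reads them back. The codec implements the plain EDF layout: a
#' 256-byte ASCII header, one 256-byte ASCII block per signal, then
#' little-endian int16 data records. Signals are quantised onto the stored
#' physical/digital ranges, so a round trip is exact up to half the
#' quantisation step `(phys_max - phys_min) / (dig_max - dig_min)`.
#'
#' @param recordings List of `eeg_recording` objects sharing `fs` and
#'   channel set.
#' @param dir Output directory (created if missing).
#' @return `write_edf()` invisibly returns the written file paths;
#'   `read_edf()` returns the list of recordings.
#' @export
write_edf <- function(recordings, dir) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  fs <- unique(vapply(recordings, function(r) r$fs, numeric(1)))
  if (length(fs) != 1) stop("mixed sampling rates are not supported")
  chs <- lapply(recordings, function(r) r$channels)
  if (length(unique(vapply(chs, paste, character(1), collapse = ","))) != 1)
    stop("recordings must share one channel set")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- list()
  paths <- character(0)
  for (r in recordings) {
    fname <- sprintf("%s_%s.edf", r$subject_id, r$state)
    write_edf_file(r, file.path(dir, fname))
    labels[[fname]] <- list(subject_id = r$subject_id, group = r$group,
                            state = r$state)
    paths <- c(paths, file.path(dir, fname))
  }
  jsonlite::write_json(labels, file.path(dir, "labels.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' @rdname write_edf
#' @export
read_edf <- function(dir) {
  lab_path <- file.path(dir, "labels.json")
  if (!file.exists(lab_path)) stop("no labels.json sidecar in ", dir)
  labels <- jsonlite::read_json(lab_path)
  lapply(names(labels), function(fname) {
    meta <- labels[[fname]]
    raw <- read_edf_file(file.path(dir, fname))
    new_recording(meta$subject_id, meta$group, meta$state,
                  raw$data, raw$fs, raw$channels)
  })
}

.edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  if (nchar(s) > width) s <- substr(s, 1, width)
  s
}

# widest numeric representation that still fits the 8-char header field;
# the same string is reparsed for scaling so file and codec agree exactly
.edf_num <- function(v) {
  for (d in 6:1) {
    s <- formatC(v, digits = d, format = "g")
    if (nchar(s) <= 8) return(s)
  }
  formatC(v, digits = 1, format = "e")
}

#' Write / read one recording as a single EDF file
#'
#' Lower-level single-file interface; `write_edf()`/`read_edf()` use it
#' per recording. Records are 1 s long when the sample count divides
#' evenly, otherwise one record holds the whole signal.
#'
#' @param rec An `eeg_recording`.
#' @param path File path.
#' @export
write_edf_file <- function(rec, path) {
  x <- rec$data
  nc <- nrow(x); n <- ncol(x)
  if (n %% rec$fs == 0 && rec$fs == round(rec$fs)) {
    spr <- as.integer(rec$fs); nrec <- n %/% spr; recdur <- 1
  } else {
    spr <- n; nrec <- 1L; recdur <- n / rec$fs
  }
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  # symmetric digital range so a constant channel (physical midpoint)
  # encodes and decodes exactly
  dmin <- -32767; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8),
    .edf_field(rec$subject_id, 80),
    .edf_field(paste("Startdate 01-JAN-2026", rec$state), 80),
    .edf_field("01.01.26", 8), .edf_field("00.00.00", 8),
    .edf_field(256 * (nc + 1), 8), .edf_field("", 44),
    .edf_field(nrec, 8), .edf_field(format(recdur, digits = 8), 8),
    .edf_field(nc, 4))
  writeChar(hdr, con, eos = NULL)
  sig_block <- function(vals, width)
    paste(vapply(vals, .edf_field, character(1), width = width), collapse = "")
  writeChar(paste0(
    sig_block(rec$channels, 16),
    sig_block(rep("AgAgCl electrode", nc), 80),
    sig_block(rep("uV", nc), 8),
    sig_block(vapply(pmin, .edf_num, character(1)), 8),
    sig_block(vapply(pmax, .edf_num, character(1)), 8),
    sig_block(rep(dmin, nc), 8),
    sig_block(rep(dmax, nc), 8),
    sig_block(rep("", nc), 80),
    sig_block(rep(spr, nc), 8),
    sig_block(rep("", nc), 32)), con, eos = NULL)
  # re-read the header's (precision-limited) physical range for scaling so
  # the file is self-consistent
  pmin_h <- as.numeric(vapply(pmin, .edf_num, character(1)))
  pmax_h <- as.numeric(vapply(pmax, .edf_num, character(1)))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(nc)) {
      d <- round((x[ch, idx] - pmin_h[ch]) / (pmax_h[ch] - pmin_h[ch]) *
                   (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf_file
#' @export
read_edf_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8) # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labs <- trimws(vapply(seq_len(nc), function(i) rd(16), character(1)))
  for (i in seq_len(nc)) rd(80) # transducer
  for (i in seq_len(nc)) rd(8)  # dimension
  pmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8), character(1)))
  for (i in seq_len(nc)) rd(80) # prefiltering
  spr <- as.integer(vapply(seq_len(nc), function(i) rd(8), character(1)))
  for (i in seq_len(nc)) rd(32)
  x <- matrix(0, nc, nrec * spr[1], dimnames = list(labs, NULL))
  for (r in seq_len(nrec)) {
    for (ch in seq_len(nc)) {
      d <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little")
      x[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        (d - dmin[ch]) / (dmax[ch] - dmin[ch]) * (pmax[ch] - pmin[ch]) + pmin[ch]
    }
  }
  list(data = x, fs = spr[1] / recdur, channels = labs,
       quant_step = (pmax - pmin) / (dmax - dmin))
}
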