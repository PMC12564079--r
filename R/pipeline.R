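#' Entropy design matrices for a cohort
#'
#' Runs the standard chain for every subject of a cohort — preprocessing
#' to clean 5-s epochs, per-state entropy matrices, the dynamic
#' (preictal minus interictal) contrast — and stacks the per-subject
#' matrices into one design per requested state. Subjects whose two
#' states yield unequal epoch counts after cleaning are truncated to the
#' common count. Dynamic-state matrices are computed with the
#' dynamic-state entropy parameters applied identically to both states,
#' so the contrast reflects state change, not configuration change.
#'
#' @param recordings List of `eeg_recording` (two per subject), e.g. from
#'   [generate_cohort()] or [read_edf()].
#' @param measure Entropy measure name.
#' @param params `NULL` (per-state packaged defaults), a single
#'   parameter list from [entropy_params()] used for all states, or a
#'   named list with entries `preictal`, `interictal`, `dynamic`.
#' @param states Which designs to build.
#' @param target_fs,band,flat_ptp_uv,clean Passed to
#'   [preprocess_recording()].
#' @return Named list of `entropy_design` objects.
#' @export
cohort_entropy_designs <- function(recordings, measure = "SampEn",
                                   params = NULL,
                                   states = c("preictal", "interictal",
                                              "dynamic"),
                                   target_fs = 128, band = c(0.5, 40),
                                   flat_ptp_uv = 1, clean = "off") {
  states <- match.arg(states, several.ok = TRUE)
  measure <- match.arg(measure, entropy_measures())
  if (is.null(params)) {
    params <- lapply(c(preictal = "preictal", interictal = "interictal",
                       dynamic = "dynamic"),
                     function(s) default_entropy_params(s)[[measure]])
  } else if (!is.null(params$measure)) {
    params <- list(preictal = params, interictal = params, dynamic = params)
  }
  sids <- unique(vapply(recordings, function(r) r$subject_id, character(1)))
  by_subj <- lapply(sids, function(s)
    recordings[vapply(recordings, function(r) r$subject_id == s, logical(1))])

  mats <- list(preictal = list(), interictal = list(), dynamic = list())
  groups <- character(length(sids))
  for (i in seq_along(sids)) {
    pair <- by_subj[[i]]
    st <- vapply(pair, function(r) r$state, character(1))
    if (!setequal(st, c("preictal", "interictal")))
      stop("subject ", sids[i], " lacks a preictal/interictal pair")
    groups[i] <- pair[[1]]$group
    eps <- lapply(pair, preprocess_recording, target_fs = target_fs,
                  band = band, flat_ptp_uv = flat_ptp_uv, clean = clean)
    names(eps) <- st
    ne <- min(vapply(eps, function(e) dim(e$data)[1], integer(1)))
    eps <- lapply(eps, function(e) {
      e$data <- e$data[seq_len(ne), , , drop = FALSE]
      e$flags <- e$flags[seq_len(ne)]
      e
    })
    # memoise per (recording state, parameter set): when the dynamic
    # contrast uses the same entropy parameters as a static state, the
    # underlying matrices are computed once
    cache <- new.env(parent = emptyenv())
    get_mat <- function(rec_state, par) {
      key <- paste(rec_state, paste(deparse(par), collapse = ""))
      if (is.null(cache[[key]]))
        cache[[key]] <- entropy_matrix(eps[[rec_state]], par,
                                       subject_id = sids[i],
                                       state = rec_state)
      cache[[key]]
    }
    for (s in intersect(states, c("preictal", "interictal")))
      mats[[s]][[i]] <- get_mat(s, params[[s]])
    if ("dynamic" %in% states)
      mats$dynamic[[i]] <- dynamic_matrix(
        get_mat("preictal", params$dynamic),
        get_mat("interictal", params$dynamic))
  }
  out <- lapply(states, function(s) stack_design(mats[[s]], groups))
  stats::setNames(out, states)
}

.config_schema <- function() {
  list(
    cohort = c("n_pnes", "n_es", "fs", "duration_s", "effect",
               "spatial_profile", "noise_exponent", "amplitude_sd",
               "mix_base", "mix_sd", "seed"),
    input_dir = NULL,
    preprocess = c("target_fs", "band", "flat_ptp_uv", "clean"),
    measures = NULL, states = NULL, classifiers = NULL,
    seed = NULL, output_dir = NULL)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys at the top
#' and section level naming the offending field, and fills defaults.
#' `spatial_profile` may be `"uniform"`, `"posterior"`, or a channel
#' subset prefixed `"on:"` (e.g. `"on:O1,O2"`).
#'
#' @param config Path to a YAML file or a list.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  schema <- .config_schema()
  bad <- setdiff(names(config), names(schema))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  for (sec in c("cohort", "preprocess")) {
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad)) stop("unknown ", sec, " field(s): ",
                          paste(bad, collapse = ", "))
  }
  config$seed <- config$seed %||% 1L
  config$measures <- config$measures %||% "SampEn"
  for (m in config$measures) match.arg(m, entropy_measures())
  config$states <- config$states %||% c("preictal", "interictal", "dynamic")
  config$classifiers <- config$classifiers %||% c("lda", "lr")
  for (cl in config$classifiers) match.arg(cl, classifier_names())
  config$output_dir <- config$output_dir %||% tempfile("seizentropy_run_")
  pp <- config$preprocess %||% list()
  pp$target_fs <- pp$target_fs %||% 128
  pp$band <- pp$band %||% c(0.5, 40)
  pp$flat_ptp_uv <- pp$flat_ptp_uv %||% 1
  pp$clean <- pp$clean %||% "off"
  config$preprocess <- pp
  structure(config, class = c("run_config", "list"))
}

.cohort_from_config <- function(config) {
  co <- config$cohort %||% list()
  prof <- co$spatial_profile %||% "uniform"
  if (is.character(prof)) {
    prof <- if (prof == "uniform") spatial_profile_uniform()
      else if (prof == "posterior") spatial_profile_posterior()
      else if (startsWith(prof, "on:"))
        spatial_profile_subset(strsplit(sub("^on:", "", prof), ",")[[1]])
      else stop("unknown spatial_profile: ", prof)
  } else prof <- unlist(prof)
  cohort_spec(n_pnes = co$n_pnes %||% 46L, n_es = co$n_es %||% 28L,
              fs = co$fs %||% 128, duration_s = co$duration_s %||% 60,
              effect = co$effect %||% 0, spatial_profile = prof,
              noise_exponent = co$noise_exponent %||% 1,
              amplitude_sd = co$amplitude_sd %||% 20,
              mix_base = co$mix_base %||% 0.30,
              mix_sd = co$mix_sd %||% 0.06,
              seed = co$seed %||% config$seed)
}

#' Simulate a cohort to disk
#'
#' Generates the configured synthetic cohort and writes it as EDF files
#' plus a `labels.json` sidecar under `<output_dir>/edf`. Byte-identical
#' across re-runs with the same config.
#'
#' @param config A `run_config`, list, or YAML path.
#' @return Invisibly, the EDF directory.
#' @export
cmd_simulate <- function(config) {
  config <- read_run_config(config)
  recs <- generate_cohort(.cohort_from_config(config))
  edf_dir <- file.path(config$output_dir, "edf")
  write_edf(recs, edf_dir)
  message("wrote ", length(recs), " recordings to ", edf_dir)
  invisible(edf_dir)
}

#' Run the full analysis pipeline
#'
#' Generation (or EDF ingestion from `input_dir`), preprocessing, entropy
#' design assembly, group statistics and LOSO classification for every
#' configured measure, state and classifier. Per-unit results are
#' checkpointed as JSON under `<output_dir>/checkpoints`, so an
#' interrupted run resumes from completed units; output tables carry the
#' config's MD5 hash for provenance.
#'
#' @param config A `run_config`, list, or YAML path.
#' @return List with `stats` (global + per-channel tables) and `results`
#'   (classification table); both are also written as CSV in
#'   `output_dir`.
#' @export
cmd_analyze <- function(config) {
  config <- read_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$output_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  ckpt_dir <- file.path(config$output_dir, "checkpoints")
  dir.create(ckpt_dir, showWarnings = FALSE)

  recs <- if (!is.null(config$input_dir)) read_edf(config$input_dir)
          else generate_cohort(.cohort_from_config(config))
  message("cohort: ", length(recs), " recordings")

  stats_rows <- list(); topo_rows <- list(); res_rows <- list()
  for (ms in config$measures) {
    designs <- cohort_entropy_designs(
      recs, ms, states = config$states,
      target_fs = config$preprocess$target_fs,
      band = config$preprocess$band,
      flat_ptp_uv = config$preprocess$flat_ptp_uv,
      clean = config$preprocess$clean)
    for (s in config$states) {
      d <- designs[[s]]
      message(ms, "/", s, ": design ", nrow(d$x), " x ", ncol(d$x))
      stats_rows[[paste(ms, s)]] <- global_stats(d)
      tz <- topographic_z(d)
      tz$measure <- ms; tz$state <- s
      topo_rows[[paste(ms, s)]] <- tz
      for (cl in config$classifiers) {
        ck <- file.path(ckpt_dir, sprintf("%s_%s_%s.json", ms, s, cl))
        if (file.exists(ck)) {
          res <- as.data.frame(jsonlite::read_json(ck, simplifyVector = TRUE))
        } else {
          r <- loso_evaluate(d, cl, seed = config$seed)
          res <- data.frame(measure = ms, state = s, classifier = cl,
                            balanced_accuracy = r$metrics$balanced_accuracy,
                            f1 = r$metrics$f1,
                            sensitivity = r$metrics$sensitivity,
                            specificity = r$metrics$specificity)
          jsonlite::write_json(res, ck, auto_unbox = TRUE, digits = NA)
        }
        res_rows[[paste(ms, s, cl)]] <- res
      }
    }
  }
  out <- list(stats = do.call(rbind, stats_rows),
              topo = do.call(rbind, topo_rows),
              results = do.call(rbind, res_rows),
              config_hash = cfg_hash)
  for (nm in c("stats", "topo", "results")) {
    tab <- out[[nm]]
    tab$config_hash <- cfg_hash
    utils::write.csv(tab, file.path(config$output_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  out
}
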