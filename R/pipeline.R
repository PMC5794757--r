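#' Hypnogram CSV I/O
#'
#' Hypnograms travel as CSV with columns `epoch_index` (0-based), `stage`
#' (one of `STAGES`) and `artifact` (0/1).
#'
#' @param h a [hypnogram()] (for writing).
#' @param path file path.
#' @return `read_hypnogram_csv` returns a [hypnogram()];
#'   `write_hypnogram_csv` returns `path` invisibly.
#' @export
#' @rdname hypnogram_csv
write_hypnogram_csv <- function(h, path) {
  utils::write.csv(
    data.frame(epoch_index = seq_len(n_epochs(h)) - 1L, stage = h$stages,
               artifact = as.integer(h$artifact)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
#' @rdname hypnogram_csv
read_hypnogram_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "stage", "artifact")
  if (!all(need %in% names(d)))
    stop("hypnogram CSV must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$epoch_index), ]
  hypnogram(d$stage, as.logical(d$artifact))
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the simulation settings,
#' the analysis windows (the study analysed the entire night and the
#' first 2 h after lights out; a first-3-h window is included for the
#' follow-up comparison), the frequency bands, detector parameters and
#' output location.
#'
#' @param sim a [simulation_config()].
#' @param windows named list of [analysis_window()]s (or `NULL` for the
#'   entire night).
#' @param bands named band list as in [band_power()].
#' @param spindle_duration_bounds seconds, passed to [detect_spindles()].
#' @param so_amplitude_criterion uV, passed to [detect_half_waves()].
#' @param out_dir optional directory; when set, tidy CSV outputs are
#'   written there.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            windows = list(
                              entire_night = NULL,
                              first_2h = window_first_hours(2),
                              first_3h = window_first_hours(3)),
                            bands = default_bands(),
                            spindle_duration_bounds = c(0.3, 3),
                            so_amplitude_criterion = 37.5,
                            out_dir = NULL) {
  structure(list(sim = sim, windows = windows, bands = bands,
                 spindle_duration_bounds = spindle_duration_bounds,
                 so_amplitude_criterion = so_amplitude_criterion,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts a YAML file whose top-level keys mirror the arguments of
#' [simulation_config()] (under `sim:`) and [pipeline_config()]
#' (`windows:` as `start`/`end` epoch pairs, `out_dir:`).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$stage_transition_matrix))
    sim_args$stage_transition_matrix <-
      matrix(unlist(sim_args$stage_transition_matrix), 5, 5, byrow = TRUE)
  sim <- do.call(simulation_config, sim_args)
  windows <- if (is.null(y$windows)) NULL else
    lapply(y$windows, function(w)
      if (is.null(w)) NULL else analysis_window(w$start, w$end))
  args <- list(sim = sim)
  if (!is.null(windows)) args$windows <- windows
  if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

analyse_night <- function(h, se, config, subject, condition) {
  sim <- config$sim
  fs <- sim$sampling_rate
  c3 <- rereference(se$recording, "C3-A2")
  f3 <- rereference(se$recording, "F3-A2")
  spectra <- epoch_spectra(c3, h)
  bp <- band_power(spectra, config$bands)
  filt <- sigma_filter(drop(c3$samples), fs)
  thr <- estimate_thresholds(filt, h, fs)
  spindles <- detect_spindles(filt, thr, h, fs,
                              duration_bounds = config$spindle_duration_bounds)
  sw <- sw_preprocess(drop(f3$samples), fs)
  halfwaves <- detect_half_waves(sw, 128, config$so_amplitude_criterion,
                                 epoch_length = h$epoch_length)
  per_window <- lapply(names(config$windows), function(wn) {
    w <- config$windows[[wn]]
    arch <- architecture_report(h, w, wn)
    sc <- suppressWarnings(spindle_counts(spindles, h, w))
    so <- suppressWarnings(so_counts(halfwaves, h, w))
    bm <- suppressWarnings(nrem_band_means(bp, h, w))
    list(architecture = cbind(subject = subject, condition = condition, arch),
         counts = data.frame(subject = subject, condition = condition,
                             window = wn, spindle_count = sc$count,
                             spindle_density = sc$density,
                             so_count = so$count, so_density = so$density),
         bands = data.frame(subject = subject, condition = condition,
                            window = wn, band = names(bm),
                            power_uV2 = as.numeric(bm), row.names = NULL))
  })
  list(architecture = do.call(rbind, lapply(per_window, `[[`, "architecture")),
       counts = do.call(rbind, lapply(per_window, `[[`, "counts")),
       bands = do.call(rbind, lapply(per_window, `[[`, "bands")),
       spindles = if (nrow(spindles)) cbind(subject = subject,
                                            condition = condition, spindles)
                  else NULL,
       halfwaves = if (nrow(halfwaves)) cbind(subject = subject,
                                              condition = condition, halfwaves)
                   else NULL,
       timeline = build_timeline(condition, h),
       thresholds = data.frame(subject = subject, condition = condition,
                               mean_uV = thr$mean_rectified_amplitude,
                               lower_uV = thr$lower, upper_uV = thr$upper))
}

#' Run the full simulate-and-analyse pipeline
#'
#' For every subject and condition: generate a hypnogram and EEG with
#' ground truth, detect spindles and slow-oscillation half-waves, compute
#' band power, and derive the architecture metrics over every configured
#' window; then run the condition comparisons (randomized-block ANOVA
#' with LSD post hocs) on the headline features, generate and model the
#' word-pair behaviour, and compute the spindle-recall correlations.
#' Deterministic for a fixed `sim$seed`.
#'
#' @param config a [pipeline_config()].
#' @param progress print per-night progress to stderr.
#' @return List with tidy data.frames `architecture`, `counts`, `bands`,
#'   `spindles`, `halfwaves`, `thresholds`, the word-pair `sessions`,
#'   `stats` (list of `comparison_result`), `wordpair_stats`,
#'   `correlations`, and `timelines`.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  subjects <- paste0("S", seq_len(sim$n_subjects))
  nights <- list()
  for (subject in subjects) {
    for (condition in sim$conditions) {
      if (progress)
        message(sprintf("night %s/%s", subject, condition))
      res <- tryCatch({
        h <- generate_hypnogram(sim, subject, condition)
        se <- synthesize_eeg(h, sim)
        analyse_night(h, se, config, subject, condition)
      }, error = function(e) {
        stop(sprintf("pipeline failed at night %s/%s: %s",
                     subject, condition, conditionMessage(e)), call. = FALSE)
      })
      nights[[paste(subject, condition)]] <- res
    }
  }
  gather <- function(el) {
    parts <- Filter(Negate(is.null), lapply(nights, `[[`, el))
    if (length(parts)) do.call(rbind, c(parts, make.row.names = FALSE)) else NULL
  }
  counts <- gather("counts")
  arch <- gather("architecture")
  # headline condition comparisons over each window
  stats_out <- list()
  for (wn in names(config$windows)) {
    cw <- counts[counts$window == wn, ]
    aw <- arch[arch$window == wn, ]
    feats <- list(
      spindle_count = cohort_table(cw$subject, cw$condition, cw$spindle_count,
                                   paste0("spindle_count_", wn)),
      spindle_density = cohort_table(cw$subject, cw$condition,
                                     cw$spindle_density,
                                     paste0("spindle_density_", wn)),
      so_count = cohort_table(cw$subject, cw$condition, cw$so_count,
                              paste0("so_count_", wn)),
      n2_min = cohort_table(aw$subject, aw$condition, aw$n2_min,
                            paste0("n2_min_", wn)))
    for (ft in feats) {
      nm <- unique(ft$feature)
      stats_out[[nm]] <- tryCatch(
        suppressWarnings(condition_anova(ft)),
        error = function(e) {
          warning(sprintf("skipping comparison '%s': %s", nm,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
    }
  }
  # word-pair behaviour correlated with the entire-night spindle count
  cw <- counts[counts$window == names(config$windows)[1L], ]
  feat <- cohort_table(cw$subject, cw$condition, cw$spindle_count,
                       "spindle_count")
  sessions <- apply_ceiling_exclusion(
    generate_wordpair_data(sim, spindle_feature = feat))
  wp_stats <- wordpair_model(sessions, "improvement")
  keep <- !sessions$excluded
  key <- paste(sessions$subject, sessions$condition)[keep]
  sp <- feat$value[match(key, paste(feat$subject, feat$condition))]
  correlations <- do.call(rbind, lapply(
    c("improvement", "immediate", "delayed", "acquisition_rate"),
    function(msr) {
      y <- switch(msr,
        improvement = overnight_improvement(sessions[keep, ]),
        immediate = sessions$immediate[keep],
        delayed = sessions$delayed[keep],
        acquisition_rate = suppressWarnings(
          initial_acquisition_rate(sessions[keep, ])))
      ct <- pearson_with_bonferroni(sp, y, n_tests = 4)
      data.frame(feature = "spindle_count", measure = msr, r = ct$r,
                 p = ct$p, significant = ct$significant)
    }))
  out <- list(architecture = arch, counts = counts, bands = gather("bands"),
              spindles = gather("spindles"), halfwaves = gather("halfwaves"),
              thresholds = gather("thresholds"), sessions = sessions,
              stats = stats_out, wordpair_stats = wp_stats,
              correlations = correlations,
              timelines = lapply(nights, `[[`, "timeline"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("architecture", "counts", "bands", "spindles", "halfwaves",
                 "thresholds", "sessions", "correlations")) {
      if (!is.null(out[[nm]]))
        utils::write.csv(out[[nm]], file.path(config$out_dir,
                                              paste0(nm, ".csv")),
                         row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(out$timelines, function(tl) tl[c("condition", "on_interval",
                                              "noise_interval")]),
      file.path(config$out_dir, "timelines.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
  }
  out
}
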