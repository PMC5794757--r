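# --- seeded random streams ---------------------------------------------
#
# All randomness in the simulator flows from one master seed through
# named streams (subject / condition / purpose), so adding subjects or
# reordering the generation does not perturb existing nights.

#' Derive a named sub-seed from a master seed
#'
#' Deterministic 31-bit hash of the master seed and any number of labels;
#' used to give every subject x condition x purpose its own RNG stream.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) naming the stream.
#' @return Integer seed in `[0, 2^31 - 59)`.
#' @export
seed_stream <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), as.character, character(1))),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483587
  as.integer(h)
}

with_stream <- function(seed, ..., code) {
  withr::with_seed(seed_stream(seed, ...), code)
}

# --- simulation configuration ------------------------------------------

#' Default per-epoch stage transition matrix
#'
#' Markov transition probabilities over the stages `W, N1, N2, N3, REM`
#' per 20-s epoch, calibrated so that simulated baseline nights reproduce
#' the study population's architecture: sleep latency around 8-10 min,
#' sleep efficiency around 96-97%, roughly 230 min N2, 90 min N3 and
#' 10 min N1 over an 8-h night.  The chain does not model ultradian
#' cycling or the homeostatic decline of deep sleep; see the methods
#' vignette for what that implies.
#'
#' @return 5 x 5 row-stochastic matrix with dimnames `STAGES`.
#' @export
default_transition_matrix <- function() {
  rbind(
    W   = c(W = 0.9550, N1 = 0.0450, N2 = 0.0000, N3 = 0.0000, REM = 0.0000),
    N1  = c(W = 0.0200, N1 = 0.5000, N2 = 0.4500, N3 = 0.0000, REM = 0.0300),
    N2  = c(W = 0.0006, N1 = 0.0100, N2 = 0.9230, N3 = 0.0400, REM = 0.0264),
    N3  = c(W = 0.0006, N1 = 0.0020, N2 = 0.0950, N3 = 0.8950, REM = 0.0074),
    REM = c(W = 0.0010, N1 = 0.0150, N2 = 0.0540, N3 = 0.0000, REM = 0.9300))
}

#' Simulation configuration for synthetic PSG cohorts
#'
#' Defines the study conditions the simulator emulates: 18 subjects in
#' three within-subject conditions (B, C1, C2), 8-h nights scored in 20-s
#' epochs, spindle density near 2.2 and slow-oscillation half-wave
#' density near 6.3 per NREM epoch, 1/f background EEG, and condition
#' effects confined to the stimulation window (increased N2 dwell and
#' spindle density, the direction observed in the study; set the shifts
#' to 0 for a null simulation).
#'
#' @param n_subjects number of subjects.
#' @param conditions condition labels.
#' @param night_duration night length in seconds (multiple of
#'   `epoch_length`).
#' @param sampling_rate EEG sampling rate in Hz (>= 30 so that the sigma
#'   band is representable; the study recorded at 256 Hz).
#' @param epoch_length scoring epoch in seconds (20).
#' @param stage_transition_matrix row-stochastic 5 x 5 matrix over
#'   `STAGES`.
#' @param spindle_density_target injected spindles per artifact-free NREM
#'   20-s epoch.
#' @param so_density_target injected slow-oscillation half-waves per NREM
#'   epoch (full cycles inject two half-waves each).
#' @param so_stage_weights per-stage multipliers on the slow-oscillation
#'   density: deep NREM carries the full rate, N1 only a quarter, so that
#'   synthesized N3 has more delta power than N1 as in real sleep.
#' @param background list: `exponent_wake`, `exponent_nrem` (1/f spectral
#'   exponents), `scale_uV` (broadband RMS in microvolts).
#' @param spindle_amp_factor injected spindle amplitude as a multiple of
#'   the background's mean rectified sigma-band amplitude; the default 10
#'   places events safely above the 6x detection threshold.
#' @param so_amp_uV `c(min, max)` of the uniform peak-amplitude draw for
#'   injected slow-oscillation cycles; the default spans the 37.5 uV
#'   half-wave criterion so that sub-criterion waves exist.
#' @param wake_alpha_uV amplitude of the 10-Hz alpha added in W epochs.
#' @param artifact_rate per-epoch probability of an artifact flag (the
#'   study excluded roughly 2-3% of epochs).
#' @param condition_effects list: `n2_dwell_shift` (additive shift on the
#'   probability of transitioning into N2 inside the stimulation window
#'   of C1/C2), `spindle_density_shift` (additive density shift there).
#' @param wordpair list of word-pair generator parameters: `immediate_mean`,
#'   `immediate_sd`, `improvement_mean` (the study's overnight gain of
#'   about 6.7 pairs), `improvement_sd`, `spindle_correlation`,
#'   `ceiling_fraction`.
#' @param seed master seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 18,
                              conditions = c("B", "C1", "C2"),
                              night_duration = 28800,
                              sampling_rate = 256,
                              epoch_length = 20,
                              stage_transition_matrix = default_transition_matrix(),
                              spindle_density_target = 2.2,
                              so_density_target = 6.3,
                              so_stage_weights = c(N1 = 0.25, N2 = 1, N3 = 1),
                              background = list(exponent_wake = 1.0,
                                                exponent_nrem = 1.5,
                                                scale_uV = 10),
                              spindle_amp_factor = 10,
                              so_amp_uV = c(25, 80),
                              wake_alpha_uV = 20,
                              artifact_rate = 0.025,
                              condition_effects = list(n2_dwell_shift = 0.04,
                                                       spindle_density_shift = 0.25),
                              wordpair = list(immediate_mean = 27,
                                              immediate_sd = 4,
                                              improvement_mean = 6.72,
                                              improvement_sd = 3.76,
                                              spindle_correlation = 0.6,
                                              ceiling_fraction = 2 / 18),
                              seed = 1L) {
  m <- stage_transition_matrix
  if (!is.matrix(m) || any(dim(m) != 5L))
    stop("stage_transition_matrix must be 5 x 5")
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
    stop("stage_transition_matrix rows must be non-negative and sum to 1")
  dimnames(m) <- list(STAGES, STAGES)
  if (night_duration %% epoch_length != 0)
    stop("night_duration must be an integer multiple of epoch_length")
  if (sampling_rate < 30)
    stop("sampling_rate below 30 Hz cannot represent the sigma band")
  if (spindle_density_target < 0 || so_density_target < 0 ||
      artifact_rate < 0 || artifact_rate > 1)
    stop("densities and rates must be non-negative (rates <= 1)")
  structure(list(
    n_subjects = as.integer(n_subjects), conditions = conditions,
    night_duration = night_duration, sampling_rate = sampling_rate,
    epoch_length = epoch_length, stage_transition_matrix = m,
    spindle_density_target = spindle_density_target,
    so_density_target = so_density_target,
    so_stage_weights = so_stage_weights, background = background,
    spindle_amp_factor = spindle_amp_factor, so_amp_uV = so_amp_uV,
    wake_alpha_uV = wake_alpha_uV, artifact_rate = artifact_rate,
    condition_effects = condition_effects, wordpair = wordpair,
    seed = as.integer(seed)), class = "simulation_config")
}

# shift probability mass toward N2, preserving row-stochasticity
shift_toward_n2 <- function(p, shift) {
  if (shift == 0) return(p)
  p2 <- min(1, max(0, p[["N2"]] + shift))
  rest <- p[setdiff(names(p), "N2")]
  s <- sum(rest)
  if (s > 0) rest <- rest * (1 - p2) / s
  c(rest, N2 = p2)[names(p)]
}

#' Generate one night's hypnogram
#'
#' Simulates the stage sequence as a per-epoch Markov chain starting in W
#' at lights out, draws artifact flags, and applies the configured
#' condition effect (N2 dwell shift) inside the stimulation window: the
#' first 2 h for C2, and until the first run of 3 consecutive N2 epochs
#' completes for C1.
#'
#' @param config a [simulation_config()].
#' @param subject_id subject label (seeds the night's RNG stream).
#' @param condition condition label; effects apply only to `C1`/`C2`.
#' @return A [hypnogram()] with attributes `subject` and `condition`.
#' @export
generate_hypnogram <- function(config, subject_id = 1, condition = "B") {
  stopifnot(inherits(config, "simulation_config"))
  ne <- as.integer(config$night_duration / config$epoch_length)
  m <- config$stage_transition_matrix
  shift <- if (condition %in% c("C1", "C2"))
    config$condition_effects$n2_dwell_shift else 0
  stim_epochs <- as.integer(7200 / config$epoch_length)
  with_stream(config$seed, "hypnogram", subject_id, condition, code = {
    stages <- character(ne)
    stages[1L] <- "W"      # the night starts awake at lights out
    cur <- "W"
    n2_run <- 0L
    stim_on <- shift != 0
    for (e in seq_len(ne)[-1L]) {
      in_window <- switch(condition,
        C2 = e <= stim_epochs,
        C1 = stim_on && e <= stim_epochs,
        FALSE)
      p <- m[cur, ]
      if (in_window && shift != 0) p <- shift_toward_n2(p, shift)
      cur <- sample(STAGES, 1L, prob = p)
      stages[e] <- cur
      n2_run <- if (cur == "N2") n2_run + 1L else 0L
      if (condition == "C1" && n2_run >= 3L) stim_on <- FALSE
    }
    art <- stats::runif(ne) < config$artifact_rate
    h <- hypnogram(stages, art, lights_out_epoch = 0L,
                   epoch_length = config$epoch_length)
    attr(h, "subject") <- subject_id
    attr(h, "condition") <- condition
    h
  })
}

# --- EEG synthesis ------------------------------------------------------

# 1/f^beta Gaussian noise of length n at rate fs, scaled to the given RMS.
colored_noise <- function(n, beta, rms, fs) {
  nf <- n %/% 2
  f <- seq_len(nf) * fs / n
  w <- f^(-beta / 2)
  spec <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * w
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = stats::rnorm(1) * w[nf])
    full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# fraction of 1/f^beta spectral power inside [lo, hi] given the discrete
# per-epoch frequency grid used by colored_noise
band_power_fraction <- function(n, beta, fs, lo, hi) {
  f <- seq_len(n %/% 2) * fs / n
  w2 <- f^(-beta)
  sum(w2[f >= lo & f <= hi]) / sum(w2)
}

# Post-filter envelope gain of a Hann-enveloped sigma burst of duration d
# at carrier frequency f: short bursts spread their spectrum beyond the
# 12-15 Hz passband and come out attenuated.  The injector divides by this
# gain so that the *realized* envelope peak equals the requested multiple
# of the background amplitude (the contract is "thresholds are exceeded").
burst_gain <- function(d, f, fs) {
  d <- round(d, 2)   # memoized on a 10 ms x 0.1 Hz grid; the gain is smooth
  f <- round(f, 1)
  key <- sprintf("bg_%g_%g_%g", d, f, fs)
  cached_design(key, function() {
    ns <- as.integer(round(d * fs))
    tt <- seq.int(0, ns - 1L) / fs
    pad <- numeric(as.integer(fs))
    x <- c(pad, (0.5 - 0.5 * cos(2 * pi * tt / d)) * sin(2 * pi * f * tt), pad)
    y <- filtfilt_zp(design_sigma_filter(fs), x)
    max(signal_envelope(y))
  })
}

# place k non-overlapping intervals of the given durations inside [0, win],
# with a minimum gap; returns onsets (or fewer than k if space runs out)
place_events <- function(k, durations, win, min_gap = 0.5, max_tries = 50L) {
  onsets <- numeric(0)
  kept <- numeric(0)
  for (i in seq_len(k)) {
    d <- durations[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      o <- stats::runif(1, 0, max(0, win - d))
      if (all(o > onsets + kept + min_gap | o + d + min_gap < onsets)) {
        onsets <- c(onsets, o)
        kept <- c(kept, d)
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }
  list(onset = onsets, duration = kept)
}

#' Synthesize a night of EEG with known injected events
#'
#' Builds a three-channel recording (C3, F3, A2, all against the Cz
#' reference) whose derivations C3-A2 and F3-A2 carry the analysis
#' content: stage-conditional 1/f background (exponent 1.0 in wake, 1.5
#' in sleep), sleep spindles (12-15 Hz Hann-enveloped bursts of 0.5-1.5 s)
#' injected into C3 during NREM epochs, slow-oscillation cycles
#' (0.75-1.25 Hz, each contributing a positive and a negative half-wave)
#' injected into F3 during NREM epochs, and 10-Hz alpha in wake.  Spindle
#' amplitudes are set as a multiple of the background's mean rectified
#' sigma-band amplitude so that the detector thresholds are exceeded by
#' construction; slow-wave amplitudes are drawn uniformly from
#' `config$so_amp_uV`.  Every injected event is returned as ground truth.
#'
#' @param h the night's [hypnogram()] (typically from
#'   [generate_hypnogram()]).
#' @param config a [simulation_config()].
#' @param subject_id,condition labels naming the RNG stream (default from
#'   the hypnogram's attributes).
#' @return List with `recording` (an [eeg_recording()]) and
#'   `ground_truth`: list of `spindles` (onset, offset, amplitude,
#'   frequency), `so` (onset, offset, polarity, amplitude) and
#'   `delta_injected` (per-epoch mean square of the injected
#'   slow-oscillation waveform, uV^2).
#' @export
synthesize_eeg <- function(h, config, subject_id = attr(h, "subject"),
                           condition = attr(h, "condition")) {
  stopifnot(inherits(h, "hypnogram"), inherits(config, "simulation_config"))
  if (is.null(subject_id)) subject_id <- 1
  if (is.null(condition)) condition <- "B"
  fs <- config$sampling_rate
  spe <- as.integer(round(h$epoch_length * fs))
  ne <- n_epochs(h)
  n <- ne * spe
  bg <- config$background
  nrem <- c("N1", "N2", "N3")

  with_stream(config$seed, "eeg", subject_id, condition, code = {
    c3 <- numeric(n)
    f3 <- numeric(n)
    for (e in seq_len(ne)) {
      beta <- if (h$stages[e] == "W") bg$exponent_wake else bg$exponent_nrem
      i <- ((e - 1L) * spe + 1L):(e * spe)
      c3[i] <- colored_noise(spe, beta, bg$scale_uV, fs)
      f3[i] <- colored_noise(spe, beta, bg$scale_uV, fs)
      if (h$stages[e] == "W" && config$wake_alpha_uV > 0) {
        tt <- (i - 1L) / fs
        ph <- stats::runif(1, 0, 2 * pi)
        c3[i] <- c3[i] + config$wake_alpha_uV * sin(2 * pi * 10 * tt + ph)
      }
    }
    # expected background sigma-band mean rectified amplitude (Gaussian:
    # E|x| = sigma * sqrt(2/pi)), from the generator's own spectral weights
    sig_frac <- band_power_fraction(spe, bg$exponent_nrem, fs, 12, 15)
    m_bg <- bg$scale_uV * sqrt(sig_frac) * sqrt(2 / pi)
    spindle_amp <- config$spindle_amp_factor * m_bg

    stim_epochs <- 7200 / h$epoch_length
    sp_shift <- if (condition %in% c("C1", "C2"))
      config$condition_effects$spindle_density_shift else 0
    c1_off <- if (condition == "C1")
      suppressWarnings(stimulation_off_epoch_c1(h)) else NA_integer_

    sp_list <- list(); so_list <- list()
    delta_inj <- numeric(ne)
    for (e in seq_len(ne)) {
      if (!(h$stages[e] %in% nrem)) next
      t0 <- (e - 1L) * h$epoch_length
      i0 <- (e - 1L) * spe
      in_stim <- e <= stim_epochs &&
        (condition == "C2" || (condition == "C1" && !is.na(c1_off) && e <= c1_off + 1L))
      dens <- config$spindle_density_target + if (in_stim) sp_shift else 0
      # spindles
      k <- stats::rpois(1L, max(0, dens))
      if (k > 0 && spindle_amp > 0) {
        pl <- place_events(k, stats::runif(k, 0.5, 1.5), h$epoch_length)
        for (j in seq_along(pl$onset)) {
          d <- pl$duration[j]
          fr <- stats::runif(1, 12.5, 14.5)
          ph <- stats::runif(1, 0, 2 * pi)
          amp <- spindle_amp / min(1, burst_gain(d, fr, fs))
          ns <- as.integer(round(d * fs))
          tt <- seq.int(0, ns - 1L) / fs
          envl <- 0.5 - 0.5 * cos(2 * pi * tt / d)  # Hann envelope
          idx <- i0 + as.integer(round(pl$onset[j] * fs)) + seq_len(ns)
          idx <- idx[idx <= n]
          c3[idx] <- c3[idx] +
            (amp * envl * sin(2 * pi * fr * tt + ph))[seq_along(idx)]
          sp_list[[length(sp_list) + 1L]] <- data.frame(
            onset = t0 + pl$onset[j], offset = t0 + pl$onset[j] + d,
            amplitude = amp, frequency = fr, epoch_index = e - 1L)
        }
      }
      # slow-oscillation cycles (two half-waves each), stage-weighted
      sw_w <- config$so_stage_weights[[h$stages[e]]]
      kc <- stats::rpois(1L, config$so_density_target * sw_w / 2)
      if (kc > 0) {
        frq <- stats::runif(kc, 0.75, 1.25)
        pl <- place_events(kc, 1 / frq, h$epoch_length)
        for (j in seq_along(pl$onset)) {
          d <- pl$duration[j]
          amp <- stats::runif(1, config$so_amp_uV[1], config$so_amp_uV[2])
          ns <- as.integer(round(d * fs))
          tt <- seq.int(0, ns - 1L) / fs
          wavef <- amp * sin(2 * pi * tt / d)
          idx <- i0 + as.integer(round(pl$onset[j] * fs)) + seq_len(ns)
          idx <- idx[idx <= n]
          f3[idx] <- f3[idx] + wavef[seq_along(idx)]
          delta_inj[e] <- delta_inj[e] + sum(wavef^2) / spe
          on <- t0 + pl$onset[j]
          so_list[[length(so_list) + 1L]] <- data.frame(
            onset = c(on, on + d / 2), offset = c(on + d / 2, on + d),
            polarity = c("positive", "negative"), amplitude = amp,
            epoch_index = e - 1L, stringsAsFactors = FALSE)
        }
      }
    }
    a2 <- colored_noise(n, 1, 2, fs)  # small common-mode-free mastoid noise
    rec <- eeg_recording(rbind(C3 = c3 + a2, F3 = f3 + a2, A2 = a2), fs,
                         c("C3", "F3", "A2"), reference = "Cz")
    gt_empty_sp <- data.frame(onset = numeric(0), offset = numeric(0),
                              amplitude = numeric(0), frequency = numeric(0),
                              epoch_index = integer(0))
    gt_empty_so <- data.frame(onset = numeric(0), offset = numeric(0),
                              polarity = character(0), amplitude = numeric(0),
                              epoch_index = integer(0))
    list(recording = rec,
         ground_truth = list(
           spindles = if (length(sp_list)) do.call(rbind, sp_list) else gt_empty_sp,
           so = if (length(so_list)) do.call(rbind, so_list) else gt_empty_so,
           delta_injected = delta_inj))
  })
}

# --- word-pair behaviour ------------------------------------------------

#' Generate synthetic word-pair performance
#'
#' Draws immediate and delayed recall scores (0-40, half-point steps) per
#' subject and condition.  Delayed = immediate + an overnight improvement
#' with configurable mean (default 6.72 pairs, the study's baseline
#' gain); the immediate score is correlated with a supplied spindle
#' feature through a configurable latent correlation, mirroring the
#' positive spindle-recall association the study reports.  A configurable
#' fraction of subjects is forced to the 40-point ceiling so that the
#' ceiling-exclusion rule is exercised.
#'
#' @param config a [simulation_config()]; the `wordpair` element holds
#'   the generator parameters.
#' @param spindle_feature optional [cohort_table()] of a spindle feature
#'   (one value per subject x condition) to correlate recall with; if
#'   `NULL` a standard-normal latent feature is drawn.
#' @param seed optional override of `config$seed`.
#' @return A [wordpair_sessions()] table with an attribute
#'   `"spindle_feature"` holding the feature values used.
#' @export
generate_wordpair_data <- function(config, spindle_feature = NULL,
                                   seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  wp <- config$wordpair
  n <- config$n_subjects
  conds <- config$conditions
  master <- if (is.null(seed)) config$seed else seed
  grid <- expand.grid(subject = paste0("S", seq_len(n)), condition = conds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(spindle_feature)) {
    key <- paste(grid$subject, grid$condition)
    fk <- paste(spindle_feature$subject, spindle_feature$condition)
    if (!all(key %in% fk))
      stop("spindle_feature must cover every subject x condition")
    feat <- spindle_feature$value[match(key, fk)]
  } else feat <- NULL
  with_stream(master, "wordpair", code = {
    if (is.null(feat)) feat <- stats::rnorm(nrow(grid))
    z <- as.numeric(scale(feat))
    if (any(!is.finite(z))) z <- numeric(nrow(grid))
    rho <- wp$spindle_correlation
    imm_raw <- wp$immediate_mean + wp$immediate_sd *
      (rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(nrow(grid)))
    impr <- stats::rnorm(nrow(grid), wp$improvement_mean, wp$improvement_sd)
    del_raw <- imm_raw + impr
    half <- function(x) pmin(39.5, pmax(0, round(2 * x) / 2))
    imm <- half(imm_raw)
    del <- half(del_raw)
    n_ceiling <- round(wp$ceiling_fraction * n)
    if (n_ceiling > 0) {
      ceil_subj <- sample(unique(grid$subject), n_ceiling)
      for (sj in ceil_subj) {
        rows <- which(grid$subject == sj)
        pick <- rows[sample.int(length(rows), 1L)]
        del[pick] <- 40
      }
    }
    out <- wordpair_sessions(grid$subject, grid$condition, imm, del)
    attr(out, "spindle_feature") <- feat
    out
  })
}
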