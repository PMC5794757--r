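# Shared fixtures: random hypnograms, event matching, and a compact
# simulation config for detector experiments.

random_hypnogram <- function(n = 30, p_artifact = 0.1) {
  hypnogram(sample(STAGES, n, replace = TRUE,
                   prob = c(0.15, 0.1, 0.4, 0.2, 0.15)),
            artifact = runif(n) < p_artifact)
}

# greedy one-to-one matching of detected to true events by interval overlap
match_events <- function(detected, truth, tol = 0.25) {
  used <- rep(FALSE, nrow(detected))
  hits <- 0L
  for (i in seq_len(nrow(truth))) {
    j <- which(!used &
                 detected$onset < truth$offset[i] + tol &
                 detected$offset > truth$onset[i] - tol)
    if (length(j)) {
      used[j[1L]] <- TRUE
      hits <- hits + 1L
    }
  }
  list(sensitivity = hits / max(1L, nrow(truth)),
       precision = sum(used) / max(1L, nrow(detected)))
}

# low-background high-SNR settings used for the recovery experiments
recovery_config <- function(night_duration = 3600, seed = 7, ...) {
  simulation_config(
    night_duration = night_duration, sampling_rate = 128,
    background = list(exponent_wake = 1, exponent_nrem = 1.5, scale_uV = 3),
    so_amp_uV = c(45, 80), artifact_rate = 0, seed = seed, ...)
}
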