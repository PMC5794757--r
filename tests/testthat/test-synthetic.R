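test_that("configuration invariants are enforced", {
  m <- default_transition_matrix()
  expect_equal(rowSums(m), setNames(rep(1, 5), STAGES), tolerance = 1e-12)
  bad <- m; bad[1, 1] <- bad[1, 1] + 0.01
  expect_error(simulation_config(stage_transition_matrix = bad), "sum to 1")
  expect_error(simulation_config(night_duration = 28801), "multiple")
  expect_error(simulation_config(sampling_rate = 20), "sigma band")
  expect_error(simulation_config(spindle_density_target = -1), "non-negative")
})

test_that("a forcing transition chain lands N2 at epoch 2; zero artifact rate flags nothing", {
  m <- matrix(0, 5, 5, dimnames = list(STAGES, STAGES))
  m["W", "N1"] <- 1; m["N1", "N2"] <- 1; m["N2", "N2"] <- 1
  m["N3", "N3"] <- 1; m["REM", "REM"] <- 1
  cfg <- simulation_config(night_duration = 400, stage_transition_matrix = m,
                           artifact_rate = 0)
  h <- generate_hypnogram(cfg, 1, "B")
  expect_equal(h$stages[1:3], c("W", "N1", "N2"))
  expect_equal(which(h$stages == "N2")[1] - 1L, 2L)
  expect_equal(sum(h$artifact), 0L)
})

test_that("simulated baseline nights reproduce the reference sleep efficiency", {
  cfg <- simulation_config(seed = 42)
  eff <- vapply(1:100, function(i)
    sleep_efficiency(generate_hypnogram(cfg, i, "B")), numeric(1))
  expect_lt(abs(mean(eff) - 96.77), 3)
  # and the generated nights carry a 3-consecutive-N2 run for the C1 rule
  h <- generate_hypnogram(cfg, 1, "B")
  expect_false(is.na(stimulation_off_epoch_c1(h)))
})

test_that("stage fractions converge to the stationary distribution on long nights", {
  m <- default_transition_matrix()
  ev <- eigen(t(m))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  cfg <- simulation_config(night_duration = 288000, seed = 13)  # 10x night
  h <- generate_hypnogram(cfg, 1, "B")
  frac <- table(factor(h$stages, levels = STAGES)) / length(h$stages)
  expect_true(all(abs(as.numeric(frac) - stat) < 0.02))
})

test_that("identical seeds give bit-identical nights; zero densities give empty truth", {
  cfg <- recovery_config(night_duration = 600, seed = 5)
  h1 <- generate_hypnogram(cfg, 2, "C2")
  h2 <- generate_hypnogram(cfg, 2, "C2")
  expect_identical(h1, h2)
  expect_identical(synthesize_eeg(h1, cfg), synthesize_eeg(h2, cfg))
  cfg0 <- simulation_config(night_duration = 400, sampling_rate = 128,
                            spindle_density_target = 0, so_density_target = 0,
                            seed = 5)
  se <- synthesize_eeg(generate_hypnogram(cfg0, 1, "B"), cfg0)
  expect_equal(nrow(se$ground_truth$spindles), 0)
  expect_equal(nrow(se$ground_truth$so), 0)
})

test_that("N3 synthesis carries more delta power than N1 under the same seed", {
  cfg <- simulation_config(night_duration = 400, sampling_rate = 128, seed = 9,
                           spindle_density_target = 0)
  h3 <- hypnogram(rep("N3", 20)); attr(h3, "subject") <- 1; attr(h3, "condition") <- "B"
  h1 <- hypnogram(rep("N1", 20)); attr(h1, "subject") <- 1; attr(h1, "condition") <- "B"
  delta_of <- function(h) {
    se <- synthesize_eeg(h, cfg)
    sp <- epoch_spectra(rereference(se$recording, "F3-A2"), h)
    mean(nrem_band_means(band_power(sp), h)["delta"])
  }
  expect_gt(delta_of(h3), delta_of(h1))
})

test_that("event recovery: high-SNR injected events are found with >= 0.9 sensitivity and precision", {
  cfg <- recovery_config(night_duration = 1800, seed = 31)
  h <- generate_hypnogram(cfg, 1, "B")
  se <- synthesize_eeg(h, cfg)
  filt <- sigma_filter(drop(rereference(se$recording, "C3-A2")$samples), 128)
  ev <- detect_spindles(filt, estimate_thresholds(filt, h, 128), h, 128)
  m <- match_events(ev, se$ground_truth$spindles)
  expect_gte(m$sensitivity, 0.9)
  expect_gte(m$precision, 0.9)
  sw <- sw_preprocess(drop(rereference(se$recording, "F3-A2")$samples), 128)
  hw <- detect_half_waves(sw)
  m2 <- match_events(data.frame(onset = hw$start, offset = hw$end),
                     se$ground_truth$so)
  expect_gte(m2$sensitivity, 0.9)
  expect_gte(m2$precision, 0.9)
})

test_that("injected slow-oscillation density is recovered within 15% on pure N3", {
  cfg <- simulation_config(night_duration = 2000, sampling_rate = 128,
                           so_amp_uV = c(45, 80), spindle_density_target = 0,
                           artifact_rate = 0, seed = 11)
  h <- hypnogram(rep("N3", 100)); attr(h, "subject") <- 1; attr(h, "condition") <- "B"
  se <- synthesize_eeg(h, cfg)
  sw <- sw_preprocess(drop(rereference(se$recording, "F3-A2")$samples), 128)
  cnt <- so_counts(detect_half_waves(sw), h)
  expect_lt(abs(cnt$density - cfg$so_density_target) / cfg$so_density_target, 0.15)
})

test_that("condition effects raise N2 dwell and spindle density only inside the window", {
  cfg <- simulation_config(
    night_duration = 28800, seed = 77, sampling_rate = 128,
    condition_effects = list(n2_dwell_shift = 0.15, spindle_density_shift = 2))
  w2h <- window_first_hours(2)
  n2_b <- mean(vapply(1:12, function(i)
    stage_minutes(generate_hypnogram(cfg, i, "B"), w2h, "N2"), numeric(1)))
  n2_c2 <- mean(vapply(1:12, function(i)
    stage_minutes(generate_hypnogram(cfg, i, "C2"), w2h, "N2"), numeric(1)))
  expect_gt(n2_c2, n2_b)
  # null simulation: a zero shift leaves transition rows untouched, and the
  # shifted row stays a probability vector
  p <- default_transition_matrix()["N1", ]
  expect_identical(rockpsg:::shift_toward_n2(p, 0), p)
  p2 <- rockpsg:::shift_toward_n2(p, 0.15)
  expect_equal(sum(p2), 1, tolerance = 1e-12)
  expect_equal(p2[["N2"]], p[["N2"]] + 0.15)
})
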