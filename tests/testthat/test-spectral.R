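make_rec <- function(x, fs = 256, label = "C3-A2") eeg_recording(x, fs, label)

test_that("rereference cancels the common reference and names missing channels", {
  withr::local_seed(501)
  n <- 1000
  s <- sin(2 * pi * 3 * (0:(n - 1)) / 256)
  cm <- rnorm(n)
  rec <- eeg_recording(rbind(C3 = s + cm, A2 = cm), 256, c("C3", "A2"))
  der <- rereference(rec, "C3-A2")
  expect_equal(drop(der$samples), s)
  expect_equal(der$channel_labels, "C3-A2")
  # identical channels give a zero derivation
  rec0 <- eeg_recording(rbind(C3 = cm, A2 = cm), 256, c("C3", "A2"))
  expect_equal(max(abs(rereference(rec0, "C3-A2")$samples)), 0)
  expect_error(rereference(rec, "F3-A2"), "F3")
  # random signals equal the sample-wise subtraction oracle
  a <- rnorm(n); b <- rnorm(n)
  recr <- eeg_recording(rbind(C3 = a, A2 = b), 256, c("C3", "A2"))
  expect_equal(drop(rereference(recr, "C3-A2")$samples), a - b)
})

test_that("a bin-centered tone integrates to amplitude^2/2; zero signal gives zero", {
  fs <- 256
  h <- hypnogram(rep("N2", 3))
  t <- seq(0, 3 * 20 - 1 / fs, by = 1 / fs)
  a <- 21.3
  sp <- epoch_spectra(make_rec(a * sin(2 * pi * 10 * t), fs), h)
  expect_equal(sp$freq[2] - sp$freq[1], 0.25)
  bp <- band_power(sp)
  expect_equal(unname(bp[, "alpha"]), rep(a^2 / 2, 3), tolerance = 0.01)
  sp0 <- epoch_spectra(make_rec(numeric(length(t)), fs), h)
  expect_equal(max(abs(sp0$power)), 0)
})

test_that("white-noise band total matches the time-domain variance share", {
  withr::local_seed(502)
  fs <- 256
  h <- hypnogram(rep("N2", 10))
  x <- rnorm(10 * 20 * fs, sd = 7)
  sp <- epoch_spectra(make_rec(x, fs), h)
  tot <- mean(band_power(sp, list(all = c(0.25, 25)))[, "all"])
  share <- var(x) * (25 - 0.125) / (fs / 2)
  expect_equal(tot, share, tolerance = 0.05)
})

test_that("band edges are inclusive, overlapping bands independent, bad bands error", {
  fs <- 256
  h <- hypnogram(rep("N2", 1))
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  sp <- epoch_spectra(make_rec(10 * sin(2 * pi * 12 * t), fs), h)
  bp <- band_power(sp)
  # a 12 Hz tone lands in both the printed alpha (9-15) and sigma (11-15)
  expect_gt(bp[1, "alpha"], 45)
  expect_gt(bp[1, "sigma"], 45)
  expect_error(band_power(sp, list(bad = c(10, 5))), "malformed")
  expect_error(band_power(sp, list(bad = c(10, 200))), "outside")
  # random spectra: equals brute-force bin summation
  withr::local_seed(503)
  spr <- sp
  spr$power <- matrix(runif(length(sp$freq) * 4), nrow = 4)
  for (b in names(default_bands())) {
    rng <- default_bands()[[b]]
    sel <- sp$freq >= rng[1] & sp$freq <= rng[2]
    expect_equal(unname(band_power(spr)[, b]), rowSums(spr$power[, sel]))
  }
})

test_that("NREM band means mask artifacts and match the masked-mean oracle", {
  withr::local_seed(504)
  nb <- 101
  h <- hypnogram(sample(STAGES, 40, replace = TRUE),
                 artifact = runif(40) < 0.2)
  sp <- structure(list(power = matrix(runif(40 * nb), 40),
                       freq = seq(0, 25, by = 0.25), sampling_rate = 256),
                  class = "epoch_spectra")
  bp <- band_power(sp)
  m <- nrem_band_means(bp, h)
  sel <- h$stages %in% c("N1", "N2", "N3") & !h$artifact
  expect_equal(unname(m["delta"]), mean(bp[sel, "delta"]))
  # a flagged epoch with huge power leaves the mean unchanged
  flagged <- which(h$artifact)[1]
  bp2 <- bp
  bp2[flagged, ] <- 1e9
  expect_equal(nrem_band_means(bp2, h), m)
  h_all_art <- hypnogram(rep("N2", 5), artifact = rep(TRUE, 5))
  expect_warning(out <- nrem_band_means(bp[1:5, , drop = FALSE], h_all_art),
                 "undefined")
  expect_true(all(is.na(out)))
})

test_that("delta build-up: flat stays flat, ramps stay ramps, MA oracle agrees", {
  h <- hypnogram(c("W", rep("N2", 200)))
  base <- matrix(0, 201, 5, dimnames = list(NULL, names(default_bands())))
  flat <- base; flat[, "delta"] <- 42
  expect_equal(delta_buildup(flat, h), rep(42, 180))
  ramp <- base; ramp[, "delta"] <- seq_len(201)
  db <- delta_buildup(ramp, h)
  expect_equal(db[4:177], seq_len(201)[(1 + 3):(180 - 3) + 1])  # interior preserved
  withr::local_seed(505)
  rnd <- base; rnd[, "delta"] <- rnorm(201)
  db2 <- delta_buildup(rnd, h)
  x <- rnd[2:181, "delta"]
  oracle <- sapply(1:180, function(i) mean(x[max(1, i - 3):min(180, i + 3)]))
  expect_equal(db2, oracle)
  expect_error(delta_buildup(base[1:100, ], h), "epochs after sleep onset")
})

test_that("power scales quadratically and ignores out-of-band tones", {
  withr::local_seed(506)
  fs <- 256
  h <- hypnogram(rep("N2", 2))
  t <- seq(0, 2 * 20 - 1 / fs, by = 1 / fs)
  x <- rnorm(length(t))
  bp1 <- band_power(epoch_spectra(make_rec(x, fs), h))
  bp2 <- band_power(epoch_spectra(make_rec(2 * x, fs), h))
  expect_equal(unclass(bp2), 4 * unclass(bp1), tolerance = 1e-6)
  # adding a 30 Hz tone (beyond all bands, below Nyquist) changes nothing
  bp3 <- band_power(epoch_spectra(make_rec(x + 15 * sin(2 * pi * 30 * t), fs), h))
  expect_equal(unclass(bp3), unclass(bp1), tolerance = 1e-8)
})
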