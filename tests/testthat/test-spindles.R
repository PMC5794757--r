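mk_thresholds <- function(m) {
  structure(list(mean_rectified_amplitude = m, lower = 2 * m, upper = 6 * m),
            class = "spindle_thresholds")
}

test_that("sigma filter passes the band center and rejects theta", {
  fs <- 256
  t <- seq(0, 30, by = 1 / fs)
  mid <- 2000:5000
  a <- 3.7
  y <- sigma_filter(a * sin(2 * pi * 13.5 * t), fs)
  expect_gte(max(y[mid]), 0.95 * a)
  y5 <- sigma_filter(a * sin(2 * pi * 5 * t), fs)
  expect_lte(max(abs(y5[mid])), 0.05 * a)
  expect_equal(sigma_filter(numeric(1000), fs), numeric(1000))
})

test_that("thresholds are 2x and 6x the mean rectified NREM amplitude", {
  h <- hypnogram(rep("N2", 3))
  m <- 1.7
  thr <- estimate_thresholds(rep(m, 3 * 20 * 128), h, 128)
  expect_equal(thr$lower, 2 * m)
  expect_equal(thr$upper, 6 * m)
  expect_equal(thr$upper, 3 * thr$lower)
  h_art <- hypnogram(rep("N2", 3), artifact = rep(TRUE, 3))
  expect_warning(thr2 <- estimate_thresholds(rep(m, 3 * 20 * 128), h_art, 128),
                 "undefined")
  expect_true(is.na(thr2$upper))
  # random signal: masked-mean oracle over artifact-free NREM samples
  withr::local_seed(601)
  for (i in 1:30) {
    hr <- random_hypnogram(8)
    x <- rnorm(8 * 20 * 64)
    acc <- c()
    for (e in 1:8) {
      if (hr$stages[e] %in% c("N1", "N2", "N3") && !hr$artifact[e])
        acc <- c(acc, x[((e - 1) * 1280 + 1):(e * 1280)])
    }
    thr3 <- suppressWarnings(estimate_thresholds(x, hr, 64))
    if (length(acc)) expect_equal(thr3$mean_rectified_amplitude, mean(abs(acc)))
    else expect_true(is.na(thr3$mean_rectified_amplitude))
  }
})

test_that("detection: empty below threshold, accurate extent for a clean burst", {
  fs <- 128
  h <- hypnogram(rep("N2", 3))
  withr::local_seed(602)
  noise <- sigma_filter(rnorm(3 * 20 * fs, sd = 1), fs)
  thr <- estimate_thresholds(noise, h, fs)
  expect_equal(nrow(detect_spindles(noise, thr, h, fs)), 0)
  # one 1-s burst at 8x the mean rectified amplitude, on a faint steady
  # sigma background (clean N2 epochs)
  t_all <- seq(0, 3 * 20 - 1 / fs, by = 1 / fs)
  carrier <- sin(2 * pi * 13.5 * t_all)
  bg_amp <- 0.08
  x <- bg_amp * carrier
  burst_amp <- 8 * mean(abs(x))
  on_s <- 25
  in_burst <- t_all >= on_s & t_all < on_s + 1
  x[in_burst] <- x[in_burst] +
    burst_amp * sin(pi * (t_all[in_burst] - on_s))^2 * carrier[in_burst]
  thr2 <- estimate_thresholds(x, h, fs)
  ev <- detect_spindles(x, thr2, h, fs)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset - on_s), 0.1)
  expect_lt(abs(ev$offset - (on_s + 1)), 0.1)
  expect_equal(ev$epoch_index, 1L)
})

test_that("supra-lower gaps merge two bursts; sub-lower gaps keep them apart", {
  fs <- 128
  h <- hypnogram(rep("N2", 3))
  t_all <- seq(0, 3 * 20 - 1 / fs, by = 1 / fs)
  carrier <- sin(2 * pi * 13.5 * t_all)
  mk <- function(gap_level) {
    envl <- rep(0.1, length(t_all))          # keeps the mean amplitude finite
    envl[t_all >= 10 & t_all < 11] <- 10
    envl[t_all >= 11 & t_all < 11.4] <- gap_level
    envl[t_all >= 11.4 & t_all < 12.4] <- 10
    # smooth the modulation (0.1 s moving average) so the instantaneous
    # amplitude tracks it without step-edge ringing
    k <- round(0.1 * fs)
    envl <- stats::filter(envl, rep(1 / k, k), sides = 2)
    envl[is.na(envl)] <- 0.1
    as.numeric(envl) * carrier
  }
  m <- mean(abs(mk(0.1)))
  thr <- mk_thresholds(m)
  ev_bridge <- detect_spindles(mk(3 * m), thr, h, fs)     # gap above lower = 2m
  ev_split <- detect_spindles(mk(0.1), thr, h, fs)        # gap below lower
  expect_equal(nrow(ev_bridge), 1)
  expect_equal(nrow(ev_split), 2)
})

test_that("detection equals a sample-scan oracle on 60-s instances", {
  oracle_detect <- function(env, mask, lower, upper, fs, bounds = c(0.3, 3)) {
    n <- length(env)
    out <- NULL
    i <- 1L
    while (i <= n) {
      if (env[i] > upper && mask[i]) {
        lo <- i
        while (lo > 1L && env[lo - 1L] >= lower) lo <- lo - 1L
        hi <- i
        while (hi < n && env[hi + 1L] >= lower) hi <- hi + 1L
        out <- rbind(out, c(lo, hi))
        i <- hi + 1L
      } else i <- i + 1L
    }
    if (is.null(out)) return(data.frame(onset = numeric(0), offset = numeric(0)))
    dur <- (out[, 2] - out[, 1] + 1) / fs
    out <- out[dur >= bounds[1] & dur <= bounds[2], , drop = FALSE]
    data.frame(onset = (out[, 1] - 1) / fs, offset = out[, 2] / fs)
  }
  withr::local_seed(603)
  fs <- 128
  h <- hypnogram(sample(c("N2", "N3", "W"), 3, replace = TRUE, prob = c(.6, .3, .1)))
  for (rep in 1:15) {
    x <- sigma_filter(rnorm(3 * 20 * fs, sd = 1), fs)
    # sprinkle bursts so events exist
    for (k in 1:6) {
      o <- sample(1:(length(x) - 200), 1)
      tt <- seq(0, 1, by = 1 / fs)
      x[o + seq_along(tt)] <- x[o + seq_along(tt)] +
        runif(1, 3, 10) * mean(abs(x)) * sin(pi * tt)^2 * sin(2 * pi * 13 * tt)
    }
    thr <- suppressWarnings(estimate_thresholds(x, h, fs))
    if (is.na(thr$upper)) next
    ev <- detect_spindles(x, thr, h, fs)
    env <- rockpsg:::signal_envelope(x)
    mask <- rockpsg:::sample_mask(h, fs, c("N1", "N2", "N3"), length(x))
    orc <- oracle_detect(env, mask, thr$lower, thr$upper, fs)
    expect_equal(ev$onset, orc$onset)
    expect_equal(ev$offset, orc$offset)
  }
})

test_that("amplitude scaling leaves the detected event set unchanged", {
  withr::local_seed(604)
  fs <- 128
  h <- hypnogram(rep("N2", 3))
  x <- sigma_filter(rnorm(3 * 20 * fs, sd = 1), fs)
  for (k in 1:4) {
    o <- sample(1:(length(x) - 200), 1)
    tt <- seq(0, 1, by = 1 / fs)
    x[o + seq_along(tt)] <- x[o + seq_along(tt)] +
      8 * mean(abs(x)) * sin(pi * tt)^2 * sin(2 * pi * 13 * tt)
  }
  detect_at <- function(scale) {
    xs <- scale * x
    detect_spindles(xs, estimate_thresholds(xs, h, fs), h, fs)
  }
  base <- detect_at(1)
  expect_gt(nrow(base), 0)
  for (k in c(2, 0.25, 3, 17.3)) {
    ev <- detect_at(k)
    expect_equal(ev$onset, base$onset)
    expect_equal(ev$offset, base$offset)
    expect_equal(ev$peak_amplitude, k * base$peak_amplitude, tolerance = 1e-9)
  }
})

test_that("spindle counts and density follow the eligible-epoch bookkeeping", {
  h <- hypnogram(c(rep("N2", 5), rep("W", 5)))
  ev <- data.frame(onset = seq(1, 96, length.out = 10))
  ev$epoch_index <- as.integer(ev$onset %/% 20)
  ev <- ev[ev$epoch_index < 5, ]
  got <- spindle_counts(ev, h)
  expect_equal(got$count, nrow(ev))
  expect_equal(got$density, nrow(ev) / 5)
  empty <- data.frame(onset = numeric(0), epoch_index = integer(0))
  expect_equal(spindle_counts(empty, h)$count, 0L)
  expect_equal(spindle_counts(empty, h)$density, 0)
  # random placements vs oracle recount
  withr::local_seed(605)
  for (i in 1:50) {
    hr <- random_hypnogram(20)
    onsets <- runif(30, 0, 400)
    evr <- data.frame(onset = onsets, epoch_index = as.integer(onsets %/% 20))
    w <- analysis_window(0, 20)
    got <- suppressWarnings(spindle_counts(evr, hr, w))
    elig <- which(hr$stages %in% c("N1", "N2", "N3") & !hr$artifact)
    cnt <- sum((evr$epoch_index + 1) %in% elig)
    expect_equal(got$count, cnt)
    if (length(elig)) expect_equal(got$density, cnt / length(elig))
    else expect_true(is.na(got$density))
  }
})
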