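# independent from-scratch randomized-block sums of squares (no fitting
# library): grand mean, condition and subject effects, residual by
# subtraction
oracle_block_anova <- function(d) {
  k <- length(unique(d$condition))
  n <- length(unique(d$subject))
  g <- mean(d$value)
  ss_cond <- n * sum((tapply(d$value, d$condition, mean) - g)^2)
  ss_subj <- k * sum((tapply(d$value, d$subject, mean) - g)^2)
  ss_tot <- sum((d$value - g)^2)
  ss_res <- ss_tot - ss_cond - ss_subj
  df_res <- (k - 1) * (n - 1)
  list(F = (ss_cond / (k - 1)) / (ss_res / df_res),
       mse = ss_res / df_res, df_res = df_res)
}

rand_table <- function(n = 10, k = 3, effect = 0) {
  g <- expand.grid(subject = paste0("S", 1:n), condition = LETTERS[1:k],
                   stringsAsFactors = FALSE)
  subj_eff <- rnorm(n)[match(g$subject, paste0("S", 1:n))]
  cond_eff <- (effect * seq_len(k))[match(g$condition, LETTERS[1:k])]
  cohort_table(g$subject, g$condition, subj_eff + cond_eff + rnorm(nrow(g)))
}

test_that("degenerate and two-condition identities hold", {
  flat <- cohort_table(rep(paste0("S", 1:5), 2), rep(c("A", "B"), each = 5), 7)
  res <- condition_anova(flat)
  expect_equal(res$omnibus$F, 0)
  expect_equal(res$omnibus$p, 1)
  expect_equal(res$pairwise$p_lsd, 1)
  # two conditions: omnibus F equals the squared paired-t statistic
  withr::local_seed(901)
  tab <- rand_table(12, 2, effect = 0.5)
  res2 <- condition_anova(tab)
  wide <- matrix(tab$value[order(tab$condition, tab$subject)], ncol = 2)
  tt <- t.test(wide[, 2], wide[, 1], paired = TRUE)
  expect_equal(res2$omnibus$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$omnibus$p, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA agrees with the from-scratch sums-of-squares oracle", {
  withr::local_seed(902)
  for (i in 1:100) {
    tab <- rand_table(sample(4:12, 1), sample(2:4, 1), effect = runif(1, 0, 1))
    res <- condition_anova(tab)
    orc <- oracle_block_anova(tab)
    expect_equal(res$omnibus$F, orc$F, tolerance = 1e-8)
    expect_equal(res$mse, orc$mse, tolerance = 1e-8)
    expect_equal(res$df_resid, orc$df_res)
  }
})

test_that("LSD pairwise p equals a t-test with the pooled residual variance", {
  withr::local_seed(903)
  tab <- rand_table(10, 3, effect = 0.4)
  res <- condition_anova(tab)
  orc <- oracle_block_anova(tab)
  means <- tapply(tab$value, tab$condition, mean)
  for (i in seq_len(nrow(res$pairwise))) {
    pr <- strsplit(res$pairwise$pair[i], " - ")[[1]]
    tval <- (means[[pr[1]]] - means[[pr[2]]]) / sqrt(2 * orc$mse / 10)
    expect_equal(res$pairwise$t[i], tval, tolerance = 1e-8)
    expect_equal(res$pairwise$p_lsd[i],
                 2 * pt(-abs(tval), orc$df_res), tolerance = 1e-10)
  }
})

test_that("incomplete blocks are dropped listwise with a warning", {
  tab <- rand_table(6, 3)
  tab <- tab[!(tab$subject == "S6" & tab$condition == "C"), ]
  expect_warning(res <- condition_anova(tab), "S6")
  expect_equal(res$n_subjects, 5)
})

test_that("Cohen's d reproduces the published sleep effect sizes", {
  # Table-1-style summary statistics (mean, SD) at n = 18 per condition
  expect_equal(round(cohens_d(8.48, 5.80, 9.89, 5.68, 18)$d_corrected, 2), 0.24)   # sleep latency C1
  expect_equal(round(cohens_d(8.48, 5.80, 9.67, 5.43, 18)$d_corrected, 2), 0.21)   # sleep latency C2
  expect_equal(round(cohens_d(10.54, 7.79, 12.89, 11.57, 18)$d_corrected, 2), 0.23) # N1 C2
  expect_equal(round(cohens_d(232.50, 37.11, 232.89, 33.34, 18)$d_corrected, 2), 0.01) # N2 C1
  expect_equal(round(cohens_d(232.50, 37.11, 238.67, 28.63, 18)$d_corrected, 2), 0.18) # N2 C2
  expect_equal(round(cohens_d(638.22, 184.36, 671.33, 183.39, 18)$d_corrected, 2), 0.18) # spindles C2
  expect_equal(cohens_d(5, 1, 5, 1, 10)$d, 0)
  expect_error(cohens_d(1, 0, 2, 1, 10), "positive")
  d <- cohens_d(0, 1, 1, 1, 18)
  expect_equal(d$J, 1 - 3 / (4 * 34 - 1))
  expect_equal(d$d_corrected, d$d * d$J)
})

test_that("Pearson helper flags at the Bonferroni-corrected level", {
  x <- 1:10
  up <- pearson_with_bonferroni(x, x)
  expect_equal(up$r, 1)
  expect_true(up$significant)
  expect_equal(up$alpha_corrected, 0.0125)
  dn <- pearson_with_bonferroni(x, -x)
  expect_equal(dn$r, -1)
  expect_warning(out <- pearson_with_bonferroni(x, rep(1, 10)), "zero variance")
  expect_true(is.na(out$r))
})

test_that("word-pair model: Tukey reduces to unadjusted p at k = 2; exact gain detected", {
  withr::local_seed(904)
  n <- 10
  s <- wordpair_sessions(rep(paste0("S", 1:n), 2), rep(c("B", "C2"), each = n),
                         round(runif(2 * n, 20, 35)), 0)
  s$delayed <- pmin(39.5, s$immediate + round(2 * rnorm(2 * n, 6, 2)) / 2)
  res <- wordpair_model(s, "improvement")
  expect_equal(res$pairwise$p_tukey, res$pairwise$p_lsd, tolerance = 1e-9)
  # delayed = immediate + 6.5 exactly: improvement contrast is certain
  s2 <- wordpair_sessions(rep(paste0("S", 1:n), 2), rep(c("B", "C2"), each = n),
                          round(runif(2 * n, 20, 30)), 0)
  s2$delayed <- s2$immediate + 6.5
  res2 <- wordpair_model(s2, "immediate")
  expect_true(all(is.na(res2$improvement_tests$p) |
                    res2$improvement_tests$p < 1e-10))
  expect_equal(res2$improvement_tests$mean_improvement, c(6.5, 6.5))
})
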