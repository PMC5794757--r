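#' Build a cohort table
#'
#' The subject x condition long table that all condition-comparison
#' statistics consume: one value per subject, condition and feature.
#'
#' @param subject,condition,feature,value vectors of equal length
#'   (`feature` defaults to a single unnamed feature).
#' @return `data.frame` with columns `subject`, `condition`, `feature`,
#'   `value`.
#' @export
cohort_table <- function(subject, condition, value, feature = "feature") {
  data.frame(subject = as.character(subject),
             condition = as.character(condition),
             feature = as.character(feature),
             value = as.numeric(value), stringsAsFactors = FALSE)
}

complete_blocks <- function(d) {
  conds <- unique(d$condition)
  n_by_subj <- tapply(d$condition, d$subject, function(x) length(unique(x)))
  keep <- names(n_by_subj)[n_by_subj == length(conds)]
  dropped <- setdiff(unique(d$subject), keep)
  if (length(dropped) > 0L)
    warning("dropping subject(s) with incomplete blocks: ",
            paste(dropped, collapse = ", "))
  d[d$subject %in% keep, , drop = FALSE]
}

#' Condition comparison: randomized-block ANOVA with LSD post hocs
#'
#' The study's univariate general linear model for EEG features:
#' condition as fixed factor, subject as a (blocking) random factor, no
#' interaction.  Post hoc pairwise comparisons are Fisher's least
#' significant difference tests: pairwise t statistics using the pooled
#' residual mean square and its degrees of freedom, with *unadjusted*
#' p-values -- no multiplicity correction is applied; that absence is the
#' definition of the LSD test, not an omission.  Pairwise Cohen's d
#' (pooled SD, with and without small-sample correction) is attached per
#' pair as a descriptive effect size.
#'
#' @param table a [cohort_table()].
#' @param feature feature name to analyse (default: the only one present).
#' @return Object of class `comparison_result`: list with `feature`,
#'   `omnibus` (`data.frame` F, df1, df2, p), `pairwise` (`data.frame`
#'   with mean difference, t, unadjusted LSD p, Cohen's d), `means`,
#'   `n_subjects`, `mse`, `df_resid`.
#' @export
condition_anova <- function(table, feature = NULL) {
  if (is.null(feature)) {
    feature <- unique(table$feature)
    if (length(feature) != 1L)
      stop("table holds several features; name one")
  }
  d <- table[table$feature == feature & !is.na(table$value), , drop = FALSE]
  d <- complete_blocks(d)
  d$subject <- factor(d$subject)
  d$condition <- factor(d$condition)
  k <- nlevels(d$condition)
  n <- nlevels(d$subject)
  if (k < 2L) stop("need at least 2 conditions")
  if (n < 3L) stop("need at least 3 subjects with complete blocks")
  fit <- stats::aov(value ~ condition + subject, data = d)
  s <- summary(fit)[[1L]]
  rows <- trimws(rownames(s))
  ms_resid <- s[rows == "Residuals", "Mean Sq"]
  df_resid <- s[rows == "Residuals", "Df"]
  f_cond <- s[rows == "condition", "F value"]
  df_cond <- s[rows == "condition", "Df"]
  p_cond <- s[rows == "condition", "Pr(>F)"]
  if (stats::var(d$value) == 0) {
    # degenerate but well-defined: no variation at all, no condition effect
    f_cond <- 0
    p_cond <- 1
  }
  means <- tapply(d$value, d$condition, mean)
  sds <- tapply(d$value, d$condition, stats::sd)
  pairs <- utils::combn(levels(d$condition), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    diff <- means[[b]] - means[[a]]
    se <- sqrt(2 * ms_resid / n)
    tval <- if (se > 0) diff / se else if (diff == 0) 0 else sign(diff) * Inf
    dd <- if (sds[[a]] > 0 && sds[[b]] > 0)
      cohens_d(means[[a]], sds[[a]], means[[b]], sds[[b]], n)
    else list(d = NA_real_, d_corrected = NA_real_)
    data.frame(pair = paste(b, "-", a), mean_diff = diff, t = tval,
               p_lsd = 2 * stats::pt(-abs(tval), df_resid),
               d = dd$d, d_corrected = dd$d_corrected,
               stringsAsFactors = FALSE)
  }))
  rownames(pw) <- NULL
  structure(list(
    feature = feature,
    omnibus = data.frame(F = f_cond, df1 = df_cond, df2 = df_resid, p = p_cond),
    pairwise = pw,
    means = data.frame(condition = names(means), mean = as.numeric(means),
                       sd = as.numeric(sds), stringsAsFactors = FALSE),
    n_subjects = n, mse = ms_resid, df_resid = df_resid),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> feature: %s (n = %d subjects)\n",
              x$feature, x$n_subjects))
  cat(sprintf("  omnibus F(%d, %d) = %.3f, p = %.4g\n",
              x$omnibus$df1, x$omnibus$df2, x$omnibus$F, x$omnibus$p))
  print(x$pairwise, digits = 3)
  invisible(x)
}

#' Cohen's d from summary statistics
#'
#' Pooled-SD standardized mean difference,
#' `d = |m2 - m1| / sqrt((sd1^2 + sd2^2)/2)`, with the small-sample
#' (Hedges) correction factor `J = 1 - 3 / (4*(2n - 2) - 1)`.  Both the
#' raw and the corrected value are returned; the corrected value is the
#' one matching the effect sizes the study reports.
#'
#' @param mean1,sd1 summary statistics of group 1.
#' @param mean2,sd2 summary statistics of group 2.
#' @param n per-group sample size (> 1).
#' @return List with `d` (raw), `d_corrected`, and the correction
#'   factor `J`.
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2, n) {
  if (any(c(sd1, sd2) <= 0)) stop("standard deviations must be positive")
  if (n <= 1) stop("n must exceed 1")
  d <- abs(mean2 - mean1) / sqrt((sd1^2 + sd2^2) / 2)
  J <- 1 - 3 / (4 * (2 * n - 2) - 1)
  list(d = d, d_corrected = J * d, J = J)
}

#' Pearson correlation with Bonferroni-corrected significance flag
#'
#' Two-tailed Pearson correlation; the significance flag applies a
#' Bonferroni-corrected threshold `alpha / n_tests` to the raw p-value
#' (the study tested 4 performance measures per feature, hence the
#' p <= 0.0125 criterion).
#'
#' @param x,y paired numeric vectors (length >= 3).
#' @param n_tests number of tests in the family (default 4).
#' @param alpha family-wise level (default 0.05).
#' @return List with `r`, `p` (raw, two-tailed), `alpha_corrected` and
#'   `significant`.
#' @export
pearson_with_bonferroni <- function(x, y, n_tests = 4, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_,
                alpha_corrected = alpha / n_tests, significant = NA))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value,
       alpha_corrected = alpha / n_tests,
       significant = ct$p.value <= alpha / n_tests)
}

#' Word-pair performance model
#'
#' Condition comparison of a word-pair performance measure over the
#' non-excluded subjects.  The study fit a linear mixed model (condition
#' fixed, subject random) with Tukey post hocs; on the complete balanced
#' blocks analysed here this is equivalent to the randomized-block ANOVA
#' of [condition_anova()], so that model is used, with pairwise p-values
#' adjusted by the studentized-range (Tukey) distribution.  The
#' Kenward-Roger degrees-of-freedom machinery is deliberately not
#' reproduced.  A paired delayed-vs-immediate contrast per condition
#' tests the overnight improvement itself.
#'
#' @param sessions a [wordpair_sessions()] table, typically after
#'   [apply_ceiling_exclusion()].
#' @param feature one of `"improvement"`, `"immediate"`, `"delayed"`,
#'   `"acquisition_rate"`.
#' @return A `comparison_result` (with `p_tukey` added to the pairwise
#'   table) plus an `improvement_tests` data.frame of per-condition
#'   paired t-tests of delayed vs immediate recall.
#' @export
wordpair_model <- function(sessions,
                           feature = c("improvement", "immediate", "delayed",
                                       "acquisition_rate")) {
  feature <- match.arg(feature)
  d <- sessions[!sessions$excluded, , drop = FALSE]
  if (length(unique(d$subject)) < 3L)
    stop("need at least 3 non-excluded subjects")
  val <- switch(feature,
    improvement = overnight_improvement(d),
    immediate = d$immediate,
    delayed = d$delayed,
    acquisition_rate = suppressWarnings(initial_acquisition_rate(d)))
  tab <- cohort_table(d$subject, d$condition, val, feature)
  res <- condition_anova(tab, feature)
  k <- length(unique(d$condition))
  res$pairwise$p_tukey <- stats::ptukey(sqrt(2) * abs(res$pairwise$t), k,
                                        res$df_resid, lower.tail = FALSE)
  res$improvement_tests <- do.call(rbind, lapply(
    sort(unique(d$condition)), function(cc) {
      dc <- d[d$condition == cc, ]
      diffs <- dc$delayed - dc$immediate
      if (stats::sd(diffs) == 0) {
        # noise-free gain: the contrast is certain (p -> 0 unless the
        # gain itself is 0)
        return(data.frame(condition = cc, mean_improvement = mean(diffs),
                          t = if (mean(diffs) == 0) 0 else Inf * sign(mean(diffs)),
                          df = length(diffs) - 1,
                          p = if (mean(diffs) == 0) 1 else 0,
                          stringsAsFactors = FALSE))
      }
      tt <- stats::t.test(dc$delayed, dc$immediate, paired = TRUE)
      data.frame(condition = cc, mean_improvement = unname(tt$estimate),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }))
  res
}
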