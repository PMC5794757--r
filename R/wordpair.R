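# Word-pair task scores live on a 0-40 point scale in half-point steps
# (one point per correct pair, half a point for a correct pair with a
# minor mistake).  To keep the half-point granularity exact, scores are
# validated as doubled integers wherever they enter the package.
check_half_steps <- function(x, what = "score") {
  if (any(x < 0 | x > 40, na.rm = TRUE))
    stop(sprintf("%s must lie in [0, 40]", what))
  if (any(abs(2 * x - round(2 * x)) > 1e-9, na.rm = TRUE))
    stop(sprintf("%s must be in half-point steps", what))
  round(2 * x) / 2
}

#' Classify a recalled word against the target
#'
#' Operationalizes the scoring rule "correct word pairs containing
#' mistakes (plural/singular form, spelling) score half a point":
#' case-insensitive exact match is `"exact"`; an edit distance of 1 or a
#' pure pluralization-suffix difference is `"minor"`; anything else is
#' `"wrong"`.
#'
#' @param given the word the subject produced.
#' @param correct the target word.
#' @param plural_suffixes suffixes treated as plural/singular variants.
#' @return `"exact"`, `"minor"` or `"wrong"`.
#' @export
classify_mistake <- function(given, correct,
                             plural_suffixes = c("s", "es", "e", "n", "en")) {
  g <- tolower(trimws(given))
  c0 <- tolower(trimws(correct))
  if (identical(g, c0)) return("exact")
  if (nchar(g) == 0L) return("wrong")
  for (suf in plural_suffixes) {
    if (identical(paste0(c0, suf), g) || identical(paste0(g, suf), c0))
      return("minor")
  }
  if (utils::adist(g, c0) == 1L) return("minor")
  "wrong"
}

#' Score one recall response
#'
#' @param mistake_class `"exact"` (1 point), `"minor"` (half a point) or
#'   `"wrong"` (0); typically from [classify_mistake()].
#' @return Points: 1, 0.5 or 0.
#' @export
score_response <- function(mistake_class = c("exact", "minor", "wrong")) {
  switch(match.arg(mistake_class), exact = 1, minor = 0.5, wrong = 0)
}

#' Build a table of word-pair sessions
#'
#' @param subject,condition identifiers (recycled as usual).
#' @param immediate,delayed recall scores in points (0-40, half steps).
#' @return `data.frame` with columns `subject`, `condition`, `immediate`,
#'   `delayed`, `excluded` (initialized `FALSE`).
#' @export
wordpair_sessions <- function(subject, condition, immediate, delayed) {
  data.frame(subject = as.character(subject),
             condition = as.character(condition),
             immediate = check_half_steps(immediate, "immediate score"),
             delayed = check_half_steps(delayed, "delayed score"),
             excluded = FALSE, stringsAsFactors = FALSE)
}

#' Overnight memory improvement
#'
#' Delayed minus immediate recall score, in points.
#'
#' @param sessions a [wordpair_sessions()] table.
#' @return Numeric vector, one value per session.
#' @export
overnight_improvement <- function(sessions) {
  sessions$delayed - sessions$immediate
}

#' Initial acquisition rate
#'
#' Immediate recall expressed as a percentage of the delayed recall
#' performance: how much of the individual learning capacity was already
#' achieved in the evening.  Undefined (NA, with a warning) when the
#' delayed score is 0.
#'
#' @param sessions a [wordpair_sessions()] table.
#' @return Percent, one value per session.
#' @export
initial_acquisition_rate <- function(sessions) {
  out <- ifelse(sessions$delayed > 0,
                100 * sessions$immediate / sessions$delayed, NA_real_)
  if (anyNA(out)) warning("delayed score of 0: acquisition rate undefined")
  out
}

#' Apply the ceiling-effect exclusion
#'
#' A subject who reaches the maximum of 40 points in any session
#' (immediate or delayed recall, any condition) is excluded from the
#' word-pair statistics in *all* conditions: the study's subject counts
#' (18 enrolled, 16 analysed after two subjects hit the ceiling) imply
#' subject-level exclusion.
#'
#' @param sessions a [wordpair_sessions()] table.
#' @return The table with the `excluded` flag set.
#' @export
apply_ceiling_exclusion <- function(sessions) {
  at_ceiling <- sessions$immediate >= 40 | sessions$delayed >= 40
  hit <- unique(sessions$subject[at_ceiling])
  sessions$excluded <- sessions$subject %in% hit
  sessions
}
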