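# Word-usage comparison between genres: frequency-ranked vocabularies,
# the common-word curve over top-N lists, a slope-vs-1 test, and the
# inter-correlation of the three formulas.

#' Frequency-ranked vocabulary of a corpus
#'
#' Case-folded word types sorted by descending token frequency; ties
#' broken alphabetically so the ranking is deterministic. Purely numeric
#' tokens are excluded (they are measurements, not vocabulary).
#'
#' @param corpus List of [document()] objects, or a character vector of
#'   raw texts.
#' @return Character vector of types, most frequent first.
#' @export
frequency_ranked_vocabulary <- function(corpus) {
  texts <- if (is.character(corpus)) corpus
           else vapply(corpus, `[[`, "", "text")
  if (length(texts) == 0L)
    stop(errorCondition("empty corpus",
                        class = c("rp_empty_input", "error", "condition")))
  toks <- tolower(unlist(lapply(texts, tokenize), use.names = FALSE))
  toks <- toks[grepl("[[:alpha:]]", toks)]
  if (length(toks) == 0L)
    stop(errorCondition("corpus has no word tokens",
                        class = c("rp_empty_input", "error", "condition")))
  tab <- table(toks)
  # sort by descending frequency, then alphabetically within a frequency
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  names(tab)[ord]
}

#' Common-word curve between two ranked vocabularies
#'
#' For each N in `n_grid`, counts the word types present in the top N of
#' both vocabularies. Two corpora with the same word usage produce a
#' curve hugging the identity line; disjoint usage produces zeros.
#'
#' @param vocab_a,vocab_b Ranked vocabularies from
#'   [frequency_ranked_vocabulary()].
#' @param n_grid Increasing vector of list depths N; every N must be at
#'   most the smaller vocabulary size. Default: 100, 200, ... capped at
#'   `min(|A|, |B|, 5000)`.
#' @return An `"overlap_curve"` object: data frame columns `n` and
#'   `common`.
#' @export
common_word_curve <- function(vocab_a, vocab_b, n_grid = NULL) {
  stopifnot(length(vocab_a) > 0L, length(vocab_b) > 0L)
  vmax <- min(length(vocab_a), length(vocab_b))
  if (is.null(n_grid)) {
    top <- min(vmax, 5000L)
    n_grid <- seq(100L, top, by = 100L)
    if (length(n_grid) == 0L) n_grid <- top
  }
  stopifnot(!is.unsorted(n_grid), all(n_grid >= 1))
  if (any(n_grid > vmax))
    stop(errorCondition(
      sprintf("n_grid exceeds smaller vocabulary size (%d)", vmax),
      class = c("rp_grid_too_large", "error", "condition")))
  # rank of each A-word in B (NA if absent); common count at N is the
  # number of A-words with rank_A <= N and rank_B <= N
  rank_b <- match(vocab_a, vocab_b)
  common <- vapply(as.integer(n_grid), function(N) {
    rb <- rank_b[seq_len(N)]
    sum(!is.na(rb) & rb <= N)
  }, integer(1))
  structure(data.frame(n = as.integer(n_grid), common = common),
            class = c("overlap_curve", "data.frame"))
}

#' Slope of the common-word curve and test against 1
#'
#' Fits `common ~ n` by least squares (with intercept) and tests the
#' one-sided hypothesis that the slope is below 1 via the regression t
#' statistic. A slope of 1 means the two corpora draw on one vocabulary;
#' the smaller the slope, the more disjoint the genres' word usage.
#' Consecutive curve points are cumulative counts, so their residuals are
#' autocorrelated and the standard error is approximate (documented
#' limitation). When the fit is exact (zero residual error, e.g. the
#' curves for identical or fully disjoint vocabularies), the p-value is
#' reported as 1 if the slope is >= 1 and 0 otherwise.
#'
#' @param curve An `"overlap_curve"` from [common_word_curve()] (>= 3
#'   grid points).
#' @return List with `slope`, `se`, `p_less_than_1` and the fitted `lm`
#'   object.
#' @export
slope_test <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("n", "common") %in% names(curve)))
  if (nrow(curve) < 3L)
    stop(errorCondition("need >= 3 grid points",
                        class = c("rp_insufficient_data", "error", "condition")))
  fit <- stats::lm(common ~ n, data = curve)
  # a zero-residual fit (identical/disjoint vocabularies) is expected and
  # handled below; summary.lm's perfect-fit warning is noise here
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["n", "Estimate"]
  se <- sm["n", "Std. Error"]
  if (!is.finite(se) || se < sqrt(.Machine$double.eps) * max(1, abs(slope))) {
    p <- if (slope >= 1 - 1e-8) 1 else 0
  } else {
    tstat <- (slope - 1) / se
    p <- stats::pt(tstat, df = stats::df.residual(fit))
  }
  list(slope = unname(slope), se = unname(se), p_less_than_1 = unname(p),
       fit = fit)
}

#' Pairwise correlation among the three readability formulas
#'
#' Pearson correlations among the FKGL, SMOG and GFI columns of a scored
#' corpus, optionally restricted to one genre. Since the formulas share
#' their input statistics, strong correlation is expected — which is
#' exactly why running several of them adds little information.
#'
#' @param scores Data frame from [score_corpus()] (>= 3 rows after any
#'   genre filter).
#' @param genre Optional genre filter (`"wiki"`, `"med"`).
#' @return 3x3 correlation matrix over `fkgl`, `smog`, `gfi`.
#' @export
formula_intercorrelation <- function(scores, genre = NULL) {
  if (!is.null(genre)) scores <- scores[scores$genre %in% genre, ]
  if (nrow(scores) < 3L)
    stop(errorCondition("need >= 3 scored documents",
                        class = c("rp_insufficient_data", "error", "condition")))
  m <- as.matrix(scores[, c("fkgl", "smog", "gfi")])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop(errorCondition(
      sprintf("constant score vector(s): %s; correlation undefined",
              paste(colnames(m)[sds == 0], collapse = ", ")),
      class = c("rp_undefined_correlation", "error", "condition")))
  stats::cor(m)
}
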