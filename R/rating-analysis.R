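# Statistics over human difficulty ratings: Fisher z-averaged
# correlations (inter-rater, rater-vs-formula), genre distribution tests,
# percent differences, paired-difficulty tests and bootstrap-binned
# rating gaps.

#' Fisher z-averaged correlation
#'
#' Averages correlation coefficients on the variance-stabilized scale:
#' `tanh(mean(atanh(r)))`. Coefficients at exactly +/-1 (common when a
#' rater's handful of shared documents happen to rank identically) make
#' `atanh` infinite; they are clipped to +/-0.999999 with a warning.
#'
#' @param rs Non-empty numeric vector of correlations in `[-1, 1]`.
#' @return Single back-transformed mean correlation.
#' @examples
#' fisher_mean_correlation(c(0, 0.8))  # exactly 0.5
#' @export
fisher_mean_correlation <- function(rs) {
  stopifnot(is.numeric(rs), length(rs) >= 1L)
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0L) stop("no non-missing correlations")
  if (any(abs(rs) > 1)) stop("correlations must lie in [-1, 1]")
  if (any(abs(rs) == 1)) {
    warning("correlation(s) at +/-1 clipped to +/-0.999999 before atanh",
            call. = FALSE)
    rs <- pmin(pmax(rs, -0.999999), 0.999999)
  }
  tanh(mean(atanh(rs)))
}

# Average duplicate ratings by the same rater on the same document
# (across sessions/pairs) before any correlation.
collapse_ratings <- function(ratings) {
  stopifnot(all(c("rater_id", "doc_id", "rating") %in% names(ratings)))
  agg <- stats::aggregate(rating ~ rater_id + doc_id, data = ratings, FUN = mean)
  agg
}

cor_method <- function(spearman) if (spearman) "spearman" else "pearson"

#' Inter-rater agreement
#'
#' For each rater, the correlations between their ratings and every other
#' rater's ratings on the documents rated by both are Fisher z-averaged.
#' Rater pairs sharing fewer than `min_overlap` documents, or whose
#' shared ratings have zero variance, are excluded. The per-rater
#' averages are bucketed into weak (< 0.4), moderate (0.4-0.6) and strong
#' (> 0.6) agreement.
#'
#' @param ratings Data frame with `rater_id`, `doc_id`, `rating`
#'   (ratings 1-10); duplicate ratings of one document by one rater are
#'   averaged first.
#' @param min_overlap Minimum co-rated documents for a rater pair
#'   (default 4; correlations on fewer points are unstable).
#' @param spearman Use Spearman instead of Pearson correlation.
#' @return A `"correlation_summary"` object: `per_rater` (named vector of
#'   Fisher-averaged correlations), `fisher_mean` (overall Fisher mean of
#'   the per-rater values), `n_overlap` (named vector, mean co-rated
#'   documents per rater), `buckets` (named counts for `<0.4`, `0.4-0.6`,
#'   `>0.6`), `excluded_pairs` (count below `min_overlap`).
#' @export
inter_rater_agreement <- function(ratings, min_overlap = 4L,
                                  spearman = FALSE) {
  r <- collapse_ratings(ratings)
  raters <- sort(unique(r$rater_id))
  if (length(raters) < 2L)
    stop(errorCondition("need >= 2 raters",
                        class = c("rp_no_overlap", "error", "condition")))
  bydoc <- split(r, r$rater_id)
  per <- stats::setNames(rep(NA_real_, length(raters)), raters)
  nov <- stats::setNames(rep(NA_real_, length(raters)), raters)
  excluded <- 0L
  for (a in raters) {
    cors <- numeric(0); overlaps <- integer(0)
    ra <- bydoc[[a]]
    for (b in setdiff(raters, a)) {
      rb <- bydoc[[b]]
      shared <- intersect(ra$doc_id, rb$doc_id)
      if (length(shared) < min_overlap) { excluded <- excluded + 1L; next }
      xa <- ra$rating[match(shared, ra$doc_id)]
      xb <- rb$rating[match(shared, rb$doc_id)]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0) { excluded <- excluded + 1L; next }
      cors <- c(cors, stats::cor(xa, xb, method = cor_method(spearman)))
      overlaps <- c(overlaps, length(shared))
    }
    if (length(cors) > 0L) {
      per[a] <- suppressWarnings(fisher_mean_correlation(cors))
      nov[a] <- mean(overlaps)
    }
  }
  per_ok <- per[!is.na(per)]
  if (length(per_ok) == 0L)
    stop(errorCondition("no rater pair with sufficient overlap",
                        class = c("rp_no_overlap", "error", "condition")))
  buckets <- c("<0.4" = sum(per_ok < 0.4),
               "0.4-0.6" = sum(per_ok >= 0.4 & per_ok <= 0.6),
               ">0.6" = sum(per_ok > 0.6))
  structure(list(unit = "rater-vs-raters", per_rater = per_ok,
                 fisher_mean = suppressWarnings(fisher_mean_correlation(per_ok)),
                 n_overlap = nov[!is.na(per)], buckets = buckets,
                 excluded_pairs = excluded),
            class = "correlation_summary")
}

#' Rater-versus-formula correlation
#'
#' Per rater, the correlation between their ratings and a readability
#' formula's scores on the rated documents of one genre, Fisher
#' z-averaged over raters. Raters with fewer than `min_docs` rated
#' documents of that genre are excluded with a warning.
#'
#' @inheritParams inter_rater_agreement
#' @param scores Data frame from [score_corpus()].
#' @param formula One of `"fkgl"`, `"smog"`, `"gfi"`.
#' @param genre `"wiki"` or `"med"`.
#' @param min_docs Minimum rated documents per rater (default 3).
#' @return A `"correlation_summary"` object.
#' @export
rater_formula_correlation <- function(ratings, scores,
                                      formula = c("fkgl", "smog", "gfi"),
                                      genre = c("wiki", "med"),
                                      min_docs = 3L, spearman = FALSE) {
  formula <- match.arg(formula)
  genre <- match.arg(genre)
  covariate <- stats::setNames(scores[[formula]], scores$doc_id)
  genre_of <- stats::setNames(scores$genre, scores$doc_id)
  rating_covariate_correlation(ratings, covariate, genre_of, genre,
                               unit = "rater-vs-formula",
                               min_docs = min_docs, spearman = spearman)
}

# Shared engine: per-rater correlation of ratings against any
# per-document covariate, restricted to one genre, Fisher-averaged.
rating_covariate_correlation <- function(ratings, covariate, genre_of,
                                         genre, unit, min_docs = 3L,
                                         spearman = FALSE) {
  r <- collapse_ratings(ratings)
  r <- r[genre_of[r$doc_id] %in% genre & r$doc_id %in% names(covariate), ]
  per <- c(); nov <- c()
  for (a in sort(unique(r$rater_id))) {
    ra <- r[r$rater_id == a, ]
    if (nrow(ra) < min_docs) {
      warning(sprintf("rater %s has < %d rated '%s' documents; excluded",
                      a, min_docs, paste(genre, collapse = "/")), call. = FALSE)
      next
    }
    x <- ra$rating; y <- covariate[ra$doc_id]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("rater %s has constant ratings or covariate; excluded", a),
              call. = FALSE)
      next
    }
    per[a] <- stats::cor(x, y, method = cor_method(spearman))
    nov[a] <- nrow(ra)
  }
  if (length(per) == 0L)
    stop(errorCondition("no rater with sufficient data",
                        class = c("rp_no_overlap", "error", "condition")))
  structure(list(unit = unit, per_rater = per,
                 fisher_mean = suppressWarnings(fisher_mean_correlation(per)),
                 n_overlap = nov, buckets = NULL, excluded_pairs = NULL),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("Correlation summary (%s): Fisher-averaged mean r = %.4f over %d raters\n",
              x$unit, x$fisher_mean, length(x$per_rater)))
  if (!is.null(x$buckets)) {
    cat("  agreement buckets: ",
        paste(sprintf("%s: %d", names(x$buckets), x$buckets), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Mann-Whitney U test between two genre samples
#'
#' Rank-based, tie-corrected, two-sided test that two samples (e.g. the
#' FKGL scores of the wiki and med documents) come from the same
#' distribution.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return Two-sided p-value.
#' @export
genre_distribution_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop(errorCondition("each sample needs >= 2 values",
                        class = c("rp_insufficient_data", "error", "condition")))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
}

#' Percent difference between genre means
#'
#' `100 * (mean_med - mean_wiki) / mean_wiki`: by how many percent the
#' med-genre mean exceeds (positive) or falls below (negative) the
#' wiki-genre mean.
#'
#' @param mean_wiki,mean_med Genre means; `mean_wiki` must be nonzero.
#' @return Percent difference.
#' @examples
#' percent_difference(14.75, 9.87)  # about -33.08
#' @export
percent_difference <- function(mean_wiki, mean_med) {
  if (any(mean_wiki == 0)) stop("mean_wiki must be nonzero")
  100 * (mean_med - mean_wiki) / mean_wiki
}

#' Paired-difficulty tests on rated document pairs
#'
#' For every presentation of a pair of the requested type, the two sides'
#' ratings are differenced and tested with a Wilcoxon signed-rank test;
#' the two sides' rating distributions are additionally compared with a
#' two-sample Kolmogorov-Smirnov test. For mixed pairs the sides are
#' oriented wiki-minus-med; for same-genre pairs the orientation is
#' randomized per presentation under `seed` (the null of no systematic
#' difference is then symmetric even when individual pairs differ).
#'
#' @param ratings Data frame with `rater_id`, `doc_id`, `pair_id`,
#'   `rating`.
#' @param pairs Pair data frame from [enumerate_pairs()]`$pairs`.
#' @param pair_type `"wiki"`, `"med"` or `"mixed"`.
#' @param seed Integer seed for same-genre orientation.
#' @param min_pairs Minimum rated presentations required (default 5).
#' @return List with `wilcoxon_p`, `ks_p`, `n` (presentations used) and
#'   `mean_diff` (mean oriented rating difference).
#' @export
paired_difficulty_tests <- function(ratings, pairs,
                                    pair_type = c("wiki", "med", "mixed"),
                                    seed = 1L, min_pairs = 5L) {
  pair_type <- match.arg(pair_type)
  p <- pairs[pairs$pair_type == pair_type, ]
  key <- interaction(ratings$rater_id, ratings$pair_id, drop = TRUE)
  # one row per (rater, pair) presentation with both sides' ratings
  d1 <- numeric(0); d2 <- numeric(0)
  with_seed(seed, {
    for (k in levels(key)) {
      rr <- ratings[key == k, ]
      pid <- rr$pair_id[1]
      row <- p[p$pair_id == pid, ]
      if (nrow(row) == 0L) next
      ra <- rr$rating[match(row$doc_a, rr$doc_id)]
      rb <- rr$rating[match(row$doc_b, rr$doc_id)]
      if (is.na(ra) || is.na(rb)) next
      if (pair_type == "mixed") {
        # orient wiki side first
        if (row$genre_a != "wiki") { tmp <- ra; ra <- rb; rb <- tmp }
      } else if (sample(c(TRUE, FALSE), 1L)) {
        tmp <- ra; ra <- rb; rb <- tmp
      }
      d1 <- c(d1, ra); d2 <- c(d2, rb)
    }
  })
  n <- length(d1)
  if (n < min_pairs)
    stop(errorCondition(
      sprintf("only %d rated '%s' pairs (need >= %d)", n, pair_type, min_pairs),
      class = c("rp_insufficient_data", "error", "condition")))
  diffs <- d1 - d2
  if (all(diffs == 0)) {
    wp <- 1  # degenerate: every presentation judged both sides identical
  } else {
    wp <- suppressWarnings(stats::wilcox.test(diffs)$p.value)
  }
  kp <- suppressWarnings(stats::ks.test(d1, d2)$p.value)
  list(wilcoxon_p = wp, ks_p = kp, n = n, mean_diff = mean(diffs))
}

#' Rating differences binned by formula-score difference
#'
#' Rebuilds, per rater, every pair of documents that the rater rated
#' *except* the pairs shown in their session, orients each pair so the
#' higher-FKGL document comes first, bins the pairs by absolute FKGL
#' difference, and reports the mean oriented rating difference per bin
#' and pair type with a percentile bootstrap 95% CI (resampling pairs
#' within bin). If formulas tracked perception, the curve would rise
#' steeply with the FKGL gap; a flat curve near zero means raters do not
#' see the difference the formula reports.
#'
#' @inheritParams paired_difficulty_tests
#' @param scores Data frame from [score_corpus()].
#' @param sessions Session data frame from [build_sessions()] (used to
#'   exclude presented pairs); may be `NULL` to keep all pairs.
#' @param bin_edges Increasing numeric bin edges over the absolute FKGL
#'   difference (default `0:6`, i.e. six one-grade bins).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return Data frame: `pair_type`, `bin` (label), `bin_lo`, `bin_hi`,
#'   `n_pairs`, `mean_diff`, `ci_lo`, `ci_hi`. Empty bins are absent.
#' @export
binned_rating_difference <- function(ratings, scores, sessions = NULL,
                                     bin_edges = 0:6, n_boot = 2000L,
                                     seed = 1L, conf = 0.95) {
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges))
  r <- collapse_ratings(ratings)
  fk <- stats::setNames(scores$fkgl, scores$doc_id)
  gn <- stats::setNames(scores$genre, scores$doc_id)
  r <- r[r$doc_id %in% names(fk), ]

  shown <- character(0)
  if (!is.null(sessions)) {
    shown <- unique(c(
      paste(sessions$rater_id, pmin(sessions$doc_left, sessions$doc_right),
            pmax(sessions$doc_left, sessions$doc_right), sep = "\r")))
  }

  rows <- list()
  for (a in unique(r$rater_id)) {
    ra <- r[r$rater_id == a, ]
    k <- nrow(ra)
    if (k < 2L) next
    cmb <- utils::combn(k, 2L)
    da <- ra$doc_id[cmb[1, ]]; db <- ra$doc_id[cmb[2, ]]
    keep <- !(paste(a, pmin(da, db), pmax(da, db), sep = "\r") %in% shown)
    da <- da[keep]; db <- db[keep]
    if (length(da) == 0L) next
    # orient: higher-FKGL document first
    swap <- fk[da] < fk[db]
    hi <- ifelse(swap, db, da); lo <- ifelse(swap, da, db)
    rows[[a]] <- data.frame(
      rater_id = a,
      fkgl_gap = abs(fk[da] - fk[db]),
      rating_diff = ra$rating[match(hi, ra$doc_id)] -
        ra$rating[match(lo, ra$doc_id)],
      pair_type = ifelse(gn[da] == gn[db], gn[da], "mixed"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop(errorCondition("no post-hoc pairs available",
                        class = c("rp_insufficient_data", "error", "condition")))
  ph <- do.call(rbind, rows)
  ph$bin <- cut(ph$fkgl_gap, breaks = bin_edges, include.lowest = TRUE,
                right = FALSE)
  ph <- ph[!is.na(ph$bin), ]

  alpha <- (1 - conf) / 2
  boot_seeds <- substream_seeds(seed, 1L)
  out <- list()
  with_seed(boot_seeds[1], {
    for (tp in sort(unique(ph$pair_type))) {
      for (b in levels(ph$bin)) {
        x <- ph$rating_diff[ph$pair_type == tp & ph$bin == b]
        if (length(x) == 0L) next  # empty bin: missing, not zero
        if (length(x) == 1L) {
          ci <- c(x, x)  # a single pair: the CI collapses to the point
        } else {
          bm <- colMeans(matrix(sample(x, length(x) * n_boot, replace = TRUE),
                                nrow = length(x)))
          ci <- unname(stats::quantile(bm, c(alpha, 1 - alpha)))
        }
        edge_i <- match(b, levels(ph$bin))
        out[[length(out) + 1L]] <- data.frame(
          pair_type = tp, bin = b,
          bin_lo = bin_edges[edge_i], bin_hi = bin_edges[edge_i + 1L],
          n_pairs = length(x), mean_diff = mean(x),
          ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
      }
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
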