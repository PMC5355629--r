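test_that("Fisher-averaged correlation matches closed forms", {
  expect_equal(fisher_mean_correlation(c(0.5, 0.5)), 0.5)
  expect_equal(fisher_mean_correlation(c(0.0, 0.8)), tanh(atanh(0.8) / 2))
  expect_equal(fisher_mean_correlation(c(0.0, 0.8)), 0.5)  # exact closed form
  for (r in c(0.1, 0.45, 0.9))
    expect_equal(fisher_mean_correlation(c(-r, r)), 0)
  # lies between min and max; near arithmetic mean for small |r|
  rs <- c(0.02, 0.05, -0.01)
  fm <- fisher_mean_correlation(rs)
  expect_gte(fm, min(rs)); expect_lte(fm, max(rs))
  expect_equal(fm, mean(rs), tolerance = 1e-3)
  expect_warning(out <- fisher_mean_correlation(c(1, 0)), "clipped")
  expect_lt(out, 1)
})

test_that("inter-rater agreement recovers perfect and noisy regimes", {
  # identical raters on 10 shared docs: clipped r near 1, strong bucket
  docs <- sprintf("d%02d", 1:10)
  rt <- ratings_df(rep(c("A", "B"), each = 10), rep(docs, 2),
                   "p1", rep(c(2, 7, 4, 9, 1, 6, 3, 8, 5, 10), 2))
  ia <- suppressWarnings(inter_rater_agreement(rt))
  expect_gt(ia$fisher_mean, 0.99)
  expect_identical(unname(ia$buckets[">0.6"]), 2L)

  # synthetic raters with shared latent difficulty recover the regime
  st <- small_study()
  ia <- inter_rater_agreement(st$ratings)
  expect_gt(ia$fisher_mean, 0.4)
  expect_identical(sum(ia$buckets), length(ia$per_rater))
  expect_gt(ia$buckets[">0.6"] + ia$buckets["0.4-0.6"], ia$buckets["<0.4"])
  # overlap between raters should be several documents on this design
  expect_gt(mean(ia$n_overlap), 4)
})

test_that("rater pairs below the overlap floor are excluded", {
  rt <- ratings_df(rep(c("A", "B"), each = 3), rep(c("d1", "d2", "d3"), 2),
                   "p1", c(1, 5, 9, 2, 6, 10))
  expect_error(inter_rater_agreement(rt, min_overlap = 4),
               class = "rp_no_overlap")
  ia <- suppressWarnings(inter_rater_agreement(rt, min_overlap = 3))
  expect_length(ia$per_rater, 2L)
})

test_that("rater-vs-formula correlation hits the designed extremes", {
  st <- small_study()
  sc <- st$scores
  wiki_docs <- sc$doc_id[sc$genre == "wiki"][1:10]
  fk <- sc$fkgl[match(wiki_docs, sc$doc_id)]
  # ratings proportional to the score itself -> near 1
  rt <- ratings_df("A", wiki_docs, "p", rank(fk))
  cs <- rater_formula_correlation(rt, sc, "fkgl", "wiki")
  expect_gt(cs$fisher_mean, 0.9)
  # ratings independent of scores -> near 0 over many raters
  set.seed(42)
  rt2 <- ratings_df(rep(sprintf("R%02d", 1:20), each = 10),
                    rep(wiki_docs, 20), "p",
                    sample(1:10, 200, replace = TRUE))
  cs2 <- rater_formula_correlation(rt2, sc, "fkgl", "wiki")
  expect_lt(abs(cs2$fisher_mean), 0.2)
  # a rater with too few genre documents is dropped with a warning
  rt3 <- rbind(rt, ratings_df("B", wiki_docs[1:2], "p", c(1, 2)))
  expect_warning(cs3 <- rater_formula_correlation(rt3, sc, "fkgl", "wiki"),
                 "excluded")
  expect_length(cs3$per_rater, 1L)
})

test_that("weak formula agreement sits below inter-rater agreement on synthetic data", {
  st <- small_study()
  ia <- inter_rater_agreement(st$ratings)$fisher_mean
  for (g in c("wiki", "med")) {
    ff <- suppressWarnings(
      rater_formula_correlation(st$ratings, st$scores, "fkgl", g))$fisher_mean
    expect_lt(ff, ia)
  }
})

test_that("Mann-Whitney genre test matches exact enumeration and edge behaviour", {
  # identical samples: no evidence of difference
  expect_gt(genre_distribution_test(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.99)
  # extreme separation
  expect_lt(genre_distribution_test(1:20, 101:120), 0.001)
  expect_error(genre_distribution_test(1, c(1, 2)), class = "rp_insufficient_data")

  # exact rank enumeration oracle at n = m = 5 (tie-free)
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4); y <- c(2.9, 6.3, 7.7, 0.5, 8.1)
  u_obs <- sum(outer(x, y, ">"))
  pool <- c(x, y)
  u_dist <- apply(combn(10, 5), 2, function(ix)
    sum(outer(pool[ix], pool[-ix], ">")))
  p_enum <- min(1, 2 * min(mean(u_dist <= u_obs), mean(u_dist >= u_obs)))
  expect_equal(genre_distribution_test(x, y), p_enum, tolerance = 1e-12)
})

test_that("percent difference reproduces its algebra", {
  expect_equal(percent_difference(10, 10), 0)
  expect_equal(percent_difference(4.41, 5.35), 100 * 0.94 / 4.41)
  for (i in 1:10) {
    a <- runif(1, 1, 20); b <- runif(1, 1, 20)
    expect_equal(percent_difference(a, b),
                 -percent_difference(b, a) * b / a, tolerance = 1e-12)
  }
  expect_error(percent_difference(0, 5))
})

test_that("paired tests match exact enumeration on hand-built mixed pairs", {
  mk_pairs <- function(n) data.frame(
    pair_id = sprintf("p%d", 1:n),
    doc_a = sprintf("w%d", 1:n), doc_b = sprintf("m%d", 1:n),
    genre_a = "wiki", genre_b = "med", pair_type = "mixed",
    token_diff = 0, fkgl_diff = 0, stringsAsFactors = FALSE)

  # Wilcoxon oracle: 6 pairs, distinct nonzero |differences|
  d <- c(1, -2, 3, -4, 5, 6)
  side2 <- c(3, 5, 2, 8, 1, 4); side1 <- side2 + d
  pairs <- mk_pairs(6)
  rt <- rbind(ratings_df("A", pairs$doc_a, pairs$pair_id, side1),
              ratings_df("A", pairs$doc_b, pairs$pair_id, side2))
  out <- paired_difficulty_tests(rt, pairs, "mixed", seed = 1)
  r <- rank(abs(d)); w <- sum(r[d > 0])
  w_dist <- as.matrix(expand.grid(rep(list(c(0, 1)), 6))) %*% r
  p_enum <- min(1, 2 * min(mean(w_dist <= w), mean(w_dist >= w)))
  expect_equal(out$wilcoxon_p, p_enum, tolerance = 1e-12)
  expect_equal(out$mean_diff, mean(d))

  # KS oracle: disjoint tie-free sides, full label enumeration
  pairs5 <- mk_pairs(5)
  rt5 <- rbind(ratings_df("A", pairs5$doc_a, pairs5$pair_id, 6:10),
               ratings_df("A", pairs5$doc_b, pairs5$pair_id, 1:5))
  out5 <- paired_difficulty_tests(rt5, pairs5, "mixed", seed = 1)
  dstat <- function(a, b) {
    pool <- sort(c(a, b))
    max(abs(ecdf(a)(pool) - ecdf(b)(pool)))
  }
  obs <- dstat(6:10, 1:5)
  pool <- 1:10
  d_dist <- apply(combn(10, 5), 2, function(ix) dstat(pool[ix], pool[-ix]))
  expect_equal(out5$ks_p, mean(d_dist >= obs - 1e-12), tolerance = 1e-12)
})

test_that("identical sides give a degenerate Wilcoxon p of 1", {
  pairs <- data.frame(pair_id = sprintf("p%d", 1:5),
                      doc_a = sprintf("a%d", 1:5), doc_b = sprintf("b%d", 1:5),
                      genre_a = "wiki", genre_b = "med", pair_type = "mixed",
                      token_diff = 0, fkgl_diff = 0, stringsAsFactors = FALSE)
  rt <- rbind(ratings_df("A", pairs$doc_a, pairs$pair_id, c(3, 5, 7, 2, 8)),
              ratings_df("A", pairs$doc_b, pairs$pair_id, c(3, 5, 7, 2, 8)))
  out <- paired_difficulty_tests(rt, pairs, "mixed", seed = 1)
  expect_identical(out$wilcoxon_p, 1)
  expect_error(paired_difficulty_tests(rt[1:4, ], pairs[1:2, ], "mixed", seed = 1),
               class = "rp_insufficient_data")
})

test_that("binned rating differences: point collapse, flatness, and exclusions", {
  sc <- fake_scores(n_tokens = rep(100, 6),
                    fkgl = c(10, 10.8, 12, 12.6, 14, 14.9))
  # one rater, two docs, one post-hoc pair: CI collapses to the point
  rt <- ratings_df("A", c("d001", "d002"), "p1", c(4, 6))
  out <- binned_rating_difference(rt, sc, sessions = NULL, bin_edges = 0:3,
                                  n_boot = 50, seed = 1)
  expect_identical(nrow(out), 1L)
  expect_equal(out$ci_lo, out$mean_diff)
  expect_equal(out$ci_hi, out$mean_diff)
  expect_equal(out$mean_diff, 2)  # d002 has the higher FKGL and was rated 6 vs 4

  # raters ignoring the formula: flat curve near zero in filled bins
  set.seed(77)
  n_raters <- 40
  rt2 <- do.call(rbind, lapply(sprintf("R%02d", 1:n_raters), function(r)
    ratings_df(r, sc$doc_id, "p", sample(1:10, 6, replace = TRUE))))
  out2 <- binned_rating_difference(rt2, sc, sessions = NULL, bin_edges = 0:6,
                                   n_boot = 200, seed = 2)
  big <- out2[out2$n_pairs >= 30, ]
  expect_gt(nrow(big), 0L)
  # per-bin means hover around zero (within-rater pairs are correlated,
  # so individual bins carry ~2x the iid standard error)
  expect_true(all(abs(big$mean_diff) < 1))
  expect_lt(abs(sum(out2$mean_diff * out2$n_pairs) / sum(out2$n_pairs)), 0.4)

  # session pairs are excluded from the post-hoc pool
  sess <- data.frame(rater_id = "A", pair_id = "p1", position = 1,
                     doc_left = "d001", doc_right = "d002",
                     pair_type = "wiki", stringsAsFactors = FALSE)
  expect_error(binned_rating_difference(rt, sc, sessions = sess,
                                        bin_edges = 0:3, n_boot = 50, seed = 1),
               class = "rp_insufficient_data")
})

test_that("bootstrap CIs cover the true mean difference at close to nominal rate", {
  sc <- fake_scores(n_tokens = rep(100, 2), fkgl = c(1.0, 0.5))
  truth <- 0.8  # mean of the discrete difference distribution below
  set.seed(123)
  n_rep <- 500; n_raters <- 30
  covered <- 0L
  for (rep in seq_len(n_rep)) {
    base <- sample(3:7, n_raters, replace = TRUE)
    diff <- sample(c(0, 1, 2), n_raters, replace = TRUE, prob = c(.4, .4, .2))
    rt <- rbind(
      ratings_df(sprintf("R%03d", 1:n_raters), "d001", "p", base + diff),
      ratings_df(sprintf("R%03d", 1:n_raters), "d002", "p", base))
    out <- binned_rating_difference(rt, sc, sessions = NULL, bin_edges = c(0, 1),
                                    n_boot = 400, seed = rep)
    if (out$ci_lo <= truth && truth <= out$ci_hi) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.90)
})
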