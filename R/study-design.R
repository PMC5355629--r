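# Pairing documents of similar length and grade level, and assembling
# stratified rater sessions. Pairing is an eligibility graph: a document
# is "paired" if it has at least one partner; a pair may be shown to many
# raters.

#' Enumerate eligible document pairs
#'
#' Two documents form an eligible pair when their token counts differ by
#' at most `max_token_diff` and their scores on `metric` differ by at most
#' `max_fkgl_diff` (both inclusive). Genre does not restrict pairing;
#' cross-genre pairs get `pair_type = "mixed"`.
#'
#' @param scored Data frame from [score_corpus()] (needs `doc_id`,
#'   `genre`, `n_tokens` and the `metric` column).
#' @param max_token_diff Maximum token-count difference (default 50).
#' @param max_fkgl_diff Maximum grade-level difference (default 0.5).
#' @param metric Score column used for the grade constraint; default
#'   `"fkgl"`. The same thresholds applied to `"smog"` or `"gfi"` select
#'   the analogous subsets.
#' @return List with `pairs` (data frame: `pair_id`, `doc_a`, `doc_b`,
#'   `genre_a`, `genre_b`, `pair_type`, `token_diff`, `fkgl_diff`) and
#'   `paired_docs` (ids of documents appearing in at least one pair).
#' @export
enumerate_pairs <- function(scored, max_token_diff = 50,
                            max_fkgl_diff = 0.5, metric = "fkgl") {
  stopifnot(is.data.frame(scored),
            all(c("doc_id", "genre", "n_tokens", metric) %in% names(scored)))
  n <- nrow(scored)
  if (n < 2L) {
    return(list(pairs = empty_pairs_df(), paired_docs = character(0)))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  tok_d <- abs(scored$n_tokens[i] - scored$n_tokens[j])
  sc <- scored[[metric]]
  sc_d <- abs(sc[i] - sc[j])
  keep <- tok_d <= max_token_diff & sc_d <= max_fkgl_diff
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L)
    return(list(pairs = empty_pairs_df(), paired_docs = character(0)))
  ga <- scored$genre[i]; gb <- scored$genre[j]
  pairs <- data.frame(
    pair_id = sprintf("P%05d", seq_along(i)),
    doc_a = scored$doc_id[i], doc_b = scored$doc_id[j],
    genre_a = ga, genre_b = gb,
    pair_type = ifelse(ga == gb, ga, "mixed"),
    token_diff = tok_d[keep], fkgl_diff = sc_d[keep],
    stringsAsFactors = FALSE)
  list(pairs = pairs,
       paired_docs = sort(unique(c(pairs$doc_a, pairs$doc_b))))
}

empty_pairs_df <- function() {
  data.frame(pair_id = character(0), doc_a = character(0),
             doc_b = character(0), genre_a = character(0),
             genre_b = character(0), pair_type = character(0),
             token_diff = numeric(0), fkgl_diff = numeric(0),
             stringsAsFactors = FALSE)
}

#' Assemble stratified rater sessions
#'
#' Each rater's session holds `n_wiki + n_med + n_mixed` pairs (default
#' 5 + 5 + 10 = 20), sampled without replacement within the session,
#' stratified by pair type. Sessions are independent across raters — a
#' popular pair may be shown to several raters — and left/right display
#' order is randomized per presentation. Fully reproducible given `seed`.
#'
#' @param pairs Pair data frame from [enumerate_pairs()]`$pairs`.
#' @param n_raters Number of raters.
#' @param seed Integer seed.
#' @param n_wiki,n_med,n_mixed Session composition by pair type.
#' @return Data frame with columns `rater_id`, `pair_id`, `position`
#'   (1-based within session), `doc_left`, `doc_right`, `pair_type`.
#' @export
build_sessions <- function(pairs, n_raters, seed,
                           n_wiki = 5L, n_med = 5L, n_mixed = 10L) {
  stopifnot(is.data.frame(pairs), n_raters >= 1L)
  want <- c(wiki = n_wiki, med = n_med, mixed = n_mixed)
  have <- table(factor(pairs$pair_type, levels = names(want)))
  short <- names(want)[as.integer(have) < want]
  if (length(short) > 0)
    stop(errorCondition(
      sprintf("insufficient pairs in stratum(s): %s (have %s, need %s)",
              paste(short, collapse = ", "),
              paste(have[short], collapse = ", "),
              paste(want[short], collapse = ", ")),
      class = c("rp_insufficient_pairs", "error", "condition")))

  with_seed(seed, {
    out <- lapply(seq_len(n_raters), function(r) {
      picks <- unlist(lapply(names(want), function(tp) {
        pool <- which(pairs$pair_type == tp)
        pool[sample.int(length(pool), want[[tp]])]
      }), use.names = FALSE)
      picks <- picks[sample.int(length(picks))]  # shuffle presentation order
      flip <- sample(c(TRUE, FALSE), length(picks), replace = TRUE)
      data.frame(
        rater_id = sprintf("R%02d", r),
        pair_id = pairs$pair_id[picks],
        position = seq_along(picks),
        doc_left = ifelse(flip, pairs$doc_b[picks], pairs$doc_a[picks]),
        doc_right = ifelse(flip, pairs$doc_a[picks], pairs$doc_b[picks]),
        pair_type = pairs$pair_type[picks],
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive k reproducible substream seeds from one root seed.
substream_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
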