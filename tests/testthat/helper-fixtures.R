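# Small in-code fixtures shared across test files.

# A tiny hand-written bilingual-genre corpus.
tiny_corpus <- function() {
  list(
    document("w1", "wiki", "Diabetes mellitus is a metabolic disorder. It affects glucose regulation in the body."),
    document("w2", "wiki", "Insulin therapy remains common. Many patients manage well-being with diet."),
    document("m1", "med", "BP 130/80\nA1c 7.2\nContinue metformin 500 mg daily."),
    document("m2", "med", "Patient stable. Follow up in 3 months.")
  )
}

# Deterministic random-ish tokens for property tests (letters only).
random_words <- function(n, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(letters, sample(1:12, 1), replace = TRUE), collapse = "")
  }, character(1))
}

# Scored-corpus data frame with controllable token counts and scores,
# for pairing tests.
fake_scores <- function(n_tokens, fkgl, genre = rep("wiki", length(fkgl)),
                        smog = fkgl, gfi = fkgl) {
  data.frame(doc_id = sprintf("d%03d", seq_along(fkgl)), genre = genre,
             n_tokens = n_tokens, fkgl = fkgl, smog = smog, gfi = gfi,
             stringsAsFactors = FALSE)
}

# Ratings data frame builder.
ratings_df <- function(rater_id, doc_id, pair_id, rating) {
  data.frame(rater_id = rater_id, doc_id = doc_id, pair_id = pair_id,
             rating = rating, stringsAsFactors = FALSE)
}

# A small synthetic study reused by several analysis tests (cached per
# session; generation is seeded so the object is reproducible).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      wp <- wiki_genre_params(); wp$docs <- 80L
      mp <- med_genre_params(); mp$docs <- 130L
      cache <<- simulate_study(wp, mp, rater_params(), seed = 421L)
    }
    cache
  }
})
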