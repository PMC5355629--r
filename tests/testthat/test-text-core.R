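test_that("sentence segmentation handles prose, clinical lines and abbreviations", {
  expect_identical(segment_sentences(""), character(0))
  expect_identical(segment_sentences("   \n \t"), character(0))

  expect_identical(segment_sentences("Patient stable. Continue metformin."),
                   c("Patient stable.", "Continue metformin."))
  # newline terminates a sentence even without punctuation
  expect_identical(segment_sentences("BP 130/80\nA1c 7.2\n"),
                   c("BP 130/80", "A1c 7.2"))
  # abbreviation periods ("Dr.", "mg.") do not split
  expect_length(segment_sentences("Dr. Smith reviewed. Take 5 mg. Daily dose."), 2L)
  expect_length(segment_sentences("Take q.d. With food."), 1L)
  # period followed by lowercase does not split
  expect_length(segment_sentences("pH was 7.2 and stable. next check tomorrow"), 1L)
})

test_that("segmentation preserves every non-whitespace character exactly once", {
  texts <- c("Patient stable. Continue metformin.",
             "BP 130/80\nA1c 7.2\nfollow up",
             "One. Two! Three? Four",
             "Dr. Who saw patient. Plan: rest.")
  for (tx in texts) {
    sents <- segment_sentences(tx)
    expect_identical(gsub("\\s", "", paste(sents, collapse = "")),
                     gsub("\\s", "", tx))
  }
})

test_that("tokenization keeps internal apostrophes/hyphens and drops punctuation", {
  expect_identical(tokenize("Type 2 diabetes."), c("Type", "2", "diabetes"))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("patient's well-being"), c("patient's", "well-being"))
  expect_identical(tokenize("... !!"), character(0))
  expect_identical(tokenize("BP 130/80"), c("BP", "130", "80"))
})

test_that("re-tokenizing concatenated sentences preserves the token multiset", {
  texts <- c("Patient stable. Continue metformin 500 mg. Daily checks.",
             "BP 130/80\nA1c 7.2\nno acute distress. Follow up.")
  for (tx in texts) {
    whole <- tokenize(gsub("\n", " ", tx))
    parts <- unlist(lapply(segment_sentences(tx), tokenize))
    expect_identical(sort(whole), sort(parts))
  }
})

test_that("syllable counting follows the vowel-group heuristic", {
  expect_identical(count_syllables("the"), 1L)
  expect_identical(count_syllables("COPD"), 1L)       # single vowel group "O"
  expect_identical(count_syllables("polysyllabic"), 5L)
  expect_identical(count_syllables("12345"), 1L)      # no letters
  expect_identical(count_syllables("make"), 1L)       # terminal silent e
  expect_identical(count_syllables("be"), 1L)         # silent-e rule cannot reach 0
  expect_identical(count_syllables("diabetes"), 3L)  # "ia" merges to one group
  expect_error(count_syllables(""), class = "rp_invalid_input")
})

test_that("spell-out mode counts one syllable per letter of all-caps tokens", {
  expect_identical(count_syllables("COPD", abbrev_mode = "spellout"), 4L)
  expect_identical(count_syllables("the", abbrev_mode = "spellout"), 1L)
  # counting is case-insensitive in plain mode
  expect_identical(count_syllables("COPD"), count_syllables("copd"))
})

test_that("every alphabetic token counts at least one syllable", {
  for (w in random_words(300, seed = 11))
    expect_gte(count_syllables(w), 1L)
})

test_that("text statistics match a brute-force recount on generated documents", {
  set.seed(31)
  for (i in 1:20) {
    n_sent <- sample(1:6, 1)
    sents <- vapply(seq_len(n_sent), function(s) {
      words <- random_words(sample(3:10, 1), seed = i * 100 + s)
      paste(paste(words, collapse = " "), ".", sep = "")
    }, character(1))
    text <- paste(sents, collapse = "\n")
    st <- compute_text_stats(text)
    # independent recount straight from the pieces
    toks <- unlist(lapply(sents, tokenize))
    syl <- vapply(toks, function(w) {
      g <- gregexpr("[aeiouy]+", tolower(w))[[1]]
      k <- if (g[1] == -1) 0L else length(g)
      if (grepl("[^aeiouy]e$", tolower(w)) && k > 1L) k <- k - 1L
      max(k, 1L)
    }, integer(1))
    expect_identical(st$n_sentences, n_sent)
    expect_identical(st$n_words, length(toks))
    expect_identical(st$n_syllables, sum(syl))
    expect_identical(st$n_polysyllabic, sum(syl >= 3L))
    expect_equal(st$words_per_sentence, length(toks) / n_sent)
    expect_equal(st$syllables_per_word, sum(syl) / length(toks))
  }
})

test_that("degenerate documents are rejected with a typed condition", {
  expect_error(compute_text_stats(""), class = "rp_degenerate_document")
  expect_error(compute_text_stats("... !!"), class = "rp_degenerate_document")
  expect_error(compute_text_stats(document("d", "med", "")),
               class = "rp_degenerate_document")
})

test_that("polysyllable threshold is configurable between >=3 and >=4", {
  txt <- "Diabetes management. Metformin helps."
  st3 <- compute_text_stats(txt, polysyllable_min = 3L)
  st4 <- compute_text_stats(txt, polysyllable_min = 4L)
  expect_gte(st3$n_polysyllabic, st4$n_polysyllabic)
  expect_identical(st3$n_syllables, st4$n_syllables)
})

test_that("corpus round-trips through the directory + manifest interface", {
  corp <- tiny_corpus()
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  back <- read_corpus(dir, file.path(dir, "manifest.csv"))
  expect_identical(vapply(back, `[[`, "", "doc_id"),
                   vapply(corp, `[[`, "", "doc_id"))
  expect_identical(vapply(back, `[[`, "", "genre"),
                   vapply(corp, `[[`, "", "genre"))
  expect_identical(trimws(vapply(back, `[[`, "", "text")),
                   trimws(vapply(corp, `[[`, "", "text")))
})
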