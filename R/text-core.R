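# Deterministic decomposition of raw text into sentences, tokens and
# syllable counts.  These counts feed every readability formula, so the
# rules here are fixed, documented, and independent of locale.

#' Construct a document
#'
#' A document is the atomic unit of a corpus: an identifier, a genre label
#' and its raw text. Genre `"wiki"` denotes lay-audience encyclopedia text,
#' `"med"` clinical (EHR-style) notes.
#'
#' @param doc_id Character scalar, unique within a corpus.
#' @param genre One of `"wiki"`, `"med"`, `"other"`.
#' @param text Character scalar (may be empty).
#' @return An object of class `"rp_document"`: a list with elements
#'   `doc_id`, `genre`, `text`.
#' @examples
#' d <- document("d1", "med", "Patient stable. Continue metformin.")
#' @export
document <- function(doc_id, genre = c("wiki", "med", "other"), text) {
  genre <- match.arg(genre)
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id),
            is.character(text), length(text) == 1L)
  structure(list(doc_id = doc_id, genre = genre, text = text),
            class = "rp_document")
}

#' @export
print.rp_document <- function(x, ...) {
  cat(sprintf("<document %s [%s], %d chars>\n", x$doc_id, x$genre,
              nchar(x$text)))
  invisible(x)
}

#' Abbreviations that never terminate a sentence
#'
#' Clinical notes are dense with dotted abbreviations; a period belonging
#' to one of these never ends a sentence. Matching is case-insensitive on
#' the token ending at the period.
#'
#' @return Character vector of dotted abbreviations.
#' @export
default_abbreviations <- function() {
  c("Dr.", "Mr.", "Mrs.", "Ms.", "St.",
    "mg.", "ml.", "oz.", "lb.", "tab.",
    "q.d.", "b.i.d.", "t.i.d.", "q.i.d.", "p.o.", "p.r.n.",
    "i.e.", "e.g.", "vs.", "etc.", "approx.", "no.")
}

#' Split text into sentences
#'
#' A sentence ends at `.`, `?` or `!` followed by whitespace and a capital
#' letter, or at a newline. Clinical notes are list-like — fragments such
#' as `"BP 130/80"` on their own lines are sentences — so the newline rule
#' is essential. Periods inside known abbreviations (see
#' [default_abbreviations()]) never split.
#'
#' Every non-whitespace character of `text` lands in exactly one sentence;
#' sentences are returned in order, trimmed of surrounding whitespace.
#'
#' @param text Character scalar; may be empty.
#' @param abbreviations Character vector of dotted abbreviations whose
#'   internal/terminal periods are not boundaries.
#' @return Character vector of sentences (length 0 for blank input).
#' @examples
#' segment_sentences("Patient stable. Continue metformin.")
#' segment_sentences("BP 130/80\nA1c 7.2\n")
#' @export
segment_sentences <- function(text, abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))

  n <- nchar(text)
  # candidate terminators: punctuation followed by horizontal space + capital
  punct <- gregexpr("[.?!](?=[ \t]+[A-Z])", text, perl = TRUE)[[1]]
  punct <- punct[punct > 0]
  if (length(punct) > 0 && length(abbreviations) > 0) {
    abbr <- tolower(abbreviations)
    keep <- vapply(punct, function(p) {
      # token ending at p, including its dots (e.g. "q.d." or "mg.")
      prefix <- substr(text, max(1L, p - 12L), p)
      tok <- regmatches(prefix, regexpr("[[:alnum:].]+$", prefix))
      length(tok) == 0L || !(tolower(tok) %in% abbr)
    }, logical(1))
    punct <- punct[keep]
  }
  newl <- gregexpr("\n", text, fixed = TRUE)[[1]]
  newl <- newl[newl > 0]
  breaks <- sort(unique(c(punct, newl)))

  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  pieces <- substring(text, starts, ends)
  pieces <- trimws(pieces)
  pieces[nzchar(pieces)]
}

#' Tokenize a sentence into word tokens
#'
#' Tokens are maximal runs of alphanumeric characters, allowing internal
#' apostrophes and hyphens (`"patient's"`, `"well-being"`). Standalone
#' punctuation is discarded. Case is preserved.
#'
#' @param sentence Character scalar.
#' @return Character vector of tokens (length 0 for no word content).
#' @examples
#' tokenize("Type 2 diabetes.")
#' @export
tokenize <- function(sentence) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  if (is.na(sentence) || !nzchar(sentence)) return(character(0))
  m <- gregexpr("[[:alnum:]]+(?:['-][[:alnum:]]+)*", sentence)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(sentence, list(m))[[1]]
}

#' Count syllables in a word token
#'
#' Vowel-group heuristic: a syllable is a maximal run of vowels
#' (a, e, i, o, u, y, case-insensitive); a terminal silent "e" forming its
#' own group is subtracted unless that would leave zero; the minimum is 1.
#' Tokens without letters (pure numbers) count as 1.
#'
#' All-caps abbreviations are deliberately treated as ordinary tokens by
#' default, so `"COPD"` counts as one syllable (the single vowel group
#' "O") — exactly the distortion that makes grade-level formulas
#' unreliable on clinical text. `abbrev_mode = "spellout"` instead counts
#' one syllable per letter for all-caps tokens of two or more letters, as
#' a reader spelling the abbreviation aloud would.
#'
#' @param word Character vector of non-empty tokens (vectorized).
#' @param abbrev_mode `"plain"` (default) or `"spellout"`.
#' @return Integer vector of counts, each >= 1.
#' @examples
#' count_syllables(c("the", "COPD", "polysyllabic"))
#' count_syllables("COPD", abbrev_mode = "spellout")
#' @export
count_syllables <- function(word, abbrev_mode = c("plain", "spellout")) {
  abbrev_mode <- match.arg(abbrev_mode)
  stopifnot(is.character(word))
  if (any(is.na(word) | !nzchar(word)))
    stop(errorCondition("count_syllables: empty token",
                        class = c("rp_invalid_input", "error", "condition")))
  low <- tolower(word)
  # maximal vowel groups
  groups <- vapply(gregexpr("[aeiouy]+", low), function(m)
    if (m[1] == -1) 0L else length(m), integer(1))
  # terminal silent e: last character is "e" and it is its own vowel group
  silent <- grepl("[^aeiouy]e$", low)
  out <- groups - ifelse(silent & groups > 1L, 1L, 0L)
  out[out < 1L] <- 1L
  if (abbrev_mode == "spellout") {
    caps <- grepl("^[A-Z]{2,}[0-9]*$", word)
    out[caps] <- nchar(word[caps])
  }
  as.integer(out)
}

#' Aggregate text statistics for the readability formulas
#'
#' Segments, tokenizes and syllable-counts a document and returns the
#' aggregate counts every grade-level formula consumes: sentences (S),
#' words (W), syllables (Syl), polysyllabic words, and the two ratios
#' W/S and Syl/W.
#'
#' @param doc An [document()] object, or a character scalar of raw text.
#' @param polysyllable_min Minimum syllable count for a word to be
#'   "polysyllabic". The conventional SMOG/GFI definition is 3
#'   (>= 3 syllables, the default); some readings use 4 (> 3 syllables).
#' @param abbrev_mode Passed to [count_syllables()].
#' @param abbreviations Passed to [segment_sentences()].
#' @return An object of class `"text_stats"`: list with `n_sentences`,
#'   `n_words`, `n_syllables`, `n_polysyllabic`, `words_per_sentence`,
#'   `syllables_per_word`.
#' @examples
#' compute_text_stats("Patient stable. Continue metformin.")
#' @export
compute_text_stats <- function(doc, polysyllable_min = 3L,
                               abbrev_mode = c("plain", "spellout"),
                               abbreviations = default_abbreviations()) {
  abbrev_mode <- match.arg(abbrev_mode)
  stopifnot(polysyllable_min %in% c(3L, 4L))
  text <- if (inherits(doc, "rp_document")) doc$text else doc
  stopifnot(is.character(text), length(text) == 1L)

  sents <- segment_sentences(text, abbreviations)
  toks <- unlist(lapply(sents, tokenize), use.names = FALSE)
  if (length(sents) == 0L || length(toks) == 0L)
    stop(errorCondition(
      "degenerate document: no sentences or no words; formulas undefined",
      class = c("rp_degenerate_document", "error", "condition")))

  syl <- count_syllables(toks, abbrev_mode = abbrev_mode)
  text_stats(n_sentences = length(sents),
             n_words = length(toks),
             n_syllables = sum(syl),
             n_polysyllabic = sum(syl >= polysyllable_min))
}

#' @rdname compute_text_stats
#' @param n_sentences,n_words,n_syllables,n_polysyllabic Non-negative
#'   counts, for constructing a `text_stats` object directly.
#' @export
text_stats <- function(n_sentences, n_words, n_syllables, n_polysyllabic) {
  stopifnot(n_sentences >= 0, n_words >= 0, n_syllables >= 0,
            n_polysyllabic >= 0, n_polysyllabic <= n_words)
  structure(list(
    n_sentences = as.integer(n_sentences),
    n_words = as.integer(n_words),
    n_syllables = as.integer(n_syllables),
    n_polysyllabic = as.integer(n_polysyllabic),
    words_per_sentence = if (n_sentences > 0) n_words / n_sentences else NA_real_,
    syllables_per_word = if (n_words > 0) n_syllables / n_words else NA_real_
  ), class = "text_stats")
}

#' @export
print.text_stats <- function(x, ...) {
  cat(sprintf(paste0("Text statistics: %d sentences, %d words, ",
                     "%d syllables (%d polysyllabic)\n"),
              x$n_sentences, x$n_words, x$n_syllables, x$n_polysyllabic))
  cat(sprintf("  words/sentence = %.2f, syllables/word = %.3f\n",
              x$words_per_sentence, x$syllables_per_word))
  invisible(x)
}

#' Read a corpus from a directory of text files
#'
#' The manifest CSV must have columns `doc_id`, `genre`, `filename`;
#' files are UTF-8 plain text under `dir`.
#'
#' @param dir Directory containing the `.txt` files.
#' @param manifest Path to the manifest CSV.
#' @return List of [document()] objects.
#' @export
read_corpus <- function(dir, manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("doc_id", "genre", "filename")
  if (!all(need %in% names(man)))
    stop("manifest must have columns doc_id, genre, filename")
  if (anyDuplicated(man$doc_id))
    stop("duplicate doc_id in manifest")
  lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(dir, man$filename[i])
    txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
    document(man$doc_id[i], man$genre[i], txt)
  })
}

#' Write a corpus to a directory plus manifest
#'
#' Inverse of [read_corpus()]: one UTF-8 `.txt` per document and a
#' `manifest.csv` with columns `doc_id`, `genre`, `filename`.
#'
#' @param corpus List of [document()] objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- data.frame(
    doc_id = vapply(corpus, `[[`, "", "doc_id"),
    genre = vapply(corpus, `[[`, "", "genre"),
    filename = paste0(vapply(corpus, `[[`, "", "doc_id"), ".txt"),
    stringsAsFactors = FALSE)
  for (i in seq_along(corpus))
    writeLines(corpus[[i]]$text, file.path(dir, man$filename[i]),
               useBytes = TRUE)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
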