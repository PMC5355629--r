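# Grade-level readability formulas. All three combine sentence-level and
# word-level length statistics into an estimated US school grade; the
# constants are the canonical published ones.

check_stats <- function(stats, need_words = TRUE) {
  if (!inherits(stats, "text_stats"))
    stop("expected a 'text_stats' object")
  if (stats$n_sentences < 1L || (need_words && stats$n_words < 1L))
    stop(errorCondition(
      "degenerate document: formulas need >= 1 sentence and >= 1 word",
      class = c("rp_degenerate_document", "error", "condition")))
  invisible(stats)
}

#' Flesch-Kincaid Grade Level
#'
#' `FKGL = 0.39 * W/S + 11.8 * Syl/W - 15.59`, where W, S and Syl are the
#' word, sentence and syllable counts. Grades may be non-integer, exceed
#' 12, or be negative for very short, simple text.
#'
#' @param stats A [text_stats()] object with at least one sentence and one
#'   word.
#' @return Numeric grade level.
#' @examples
#' fkgl(text_stats(1, 10, 15, 0))  # 6.01
#' @export
fkgl <- function(stats) {
  check_stats(stats)
  0.39 * stats$words_per_sentence + 11.8 * stats$syllables_per_word - 15.59
}

#' Simple Measure of Gobbledygook (SMOG) grade
#'
#' `SMOG = 1.0430 * sqrt(30 * P/S) + 3.1291`, where P is the polysyllabic
#' word count and S the sentence count. The formula floors at 3.1291 when
#' no word is polysyllabic, and ignores word length below the polysyllable
#' threshold entirely.
#'
#' @inheritParams fkgl
#' @return Numeric grade level (>= 3.1291).
#' @examples
#' smog(text_stats(30, 600, 900, 30))  # 1.0430 * sqrt(30) + 3.1291
#' @export
smog <- function(stats) {
  check_stats(stats, need_words = FALSE)
  1.0430 * sqrt(30 * stats$n_polysyllabic / stats$n_sentences) + 3.1291
}

#' Gunning-Fog Index
#'
#' `GFI = 0.4 * (W/S + 100 * P/W)`: mean sentence length plus the
#' percentage of polysyllabic ("complex") words, scaled by 0.4. Depends
#' only on ratios, so it is invariant to document scale.
#'
#' @inheritParams fkgl
#' @return Numeric grade level.
#' @examples
#' gfi(text_stats(10, 100, 150, 10))  # 0.4 * (10 + 10) = 8
#' @export
gfi <- function(stats) {
  check_stats(stats)
  0.4 * (stats$words_per_sentence + 100 * stats$n_polysyllabic / stats$n_words)
}

#' Score every document in a corpus
#'
#' Computes text statistics and all three formulas per document.
#' Degenerate documents (no sentences or no words) are excluded with a
#' warning rather than aborting the run — clinical corpora routinely
#' contain empty or header-only notes. Documents shorter than the classic
#' 30-sentence recommendation are flagged, not dropped.
#'
#' @param corpus Non-empty list of [document()] objects.
#' @inheritParams compute_text_stats
#' @return Data frame with one row per non-degenerate document:
#'   `doc_id`, `genre`, `n_sentences`, `n_tokens`, `n_syllables`,
#'   `n_polysyllabic`, `fkgl`, `smog`, `gfi`, `short_document`.
#' @export
score_corpus <- function(corpus, polysyllable_min = 3L,
                         abbrev_mode = c("plain", "spellout"),
                         abbreviations = default_abbreviations()) {
  abbrev_mode <- match.arg(abbrev_mode)
  if (!is.list(corpus) || length(corpus) == 0L)
    stop(errorCondition("empty corpus",
                        class = c("rp_empty_input", "error", "condition")))
  rows <- lapply(corpus, function(d) {
    st <- tryCatch(
      compute_text_stats(d, polysyllable_min = polysyllable_min,
                         abbrev_mode = abbrev_mode,
                         abbreviations = abbreviations),
      rp_degenerate_document = function(e) NULL)
    if (is.null(st)) {
      warning(sprintf("document '%s' is degenerate (no sentences/words); excluded",
                      d$doc_id), call. = FALSE)
      return(NULL)
    }
    data.frame(doc_id = d$doc_id, genre = d$genre,
               n_sentences = st$n_sentences, n_tokens = st$n_words,
               n_syllables = st$n_syllables,
               n_polysyllabic = st$n_polysyllabic,
               fkgl = fkgl(st), smog = smog(st), gfi = gfi(st),
               short_document = st$n_sentences < 30L,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop(errorCondition("all documents degenerate",
                        class = c("rp_empty_input", "error", "condition")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
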