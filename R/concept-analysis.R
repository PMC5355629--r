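# Lexicon-based medical-concept tagging (a deterministic, testable
# stand-in for a full concept-mapping engine), semantic-group exclusion,
# concept counting, and correlation of concept load with ratings.

#' Semantic groups excluded from concept counting
#'
#' Coarse semantic groups and types that rarely carry technical medical
#' jargon (people, places, organizations, everyday activities), plus
#' Anatomical Structure, whose mentions in this domain are dominated by
#' common body words a lay reader knows. Mentions tagged with any of
#' these labels are dropped before counting.
#'
#' @return Character vector of group labels.
#' @export
excluded_semantic_groups <- function() {
  c("Activities & Behaviors", "Concepts & Ideas", "Geographic Areas",
    "Objects", "Occupations", "Organizations", "Age Group", "Animal",
    "Family Group", "Group", "Human", "Patient or Disabled Group",
    "Population Group", "Professional or Occupational Group",
    "Educational Activity", "Health Care Activity", "Research Activity",
    "Anatomical Structure")
}

#' Read a concept lexicon
#'
#' Tab-separated file with two columns, `term` and `group` (no header
#' expected by default). Terms are lowercased; each term must have 1-5
#' tokens.
#'
#' @param path Path to the TSV file.
#' @param header Does the file have a header row? Default `FALSE`.
#' @return A `"concept_lexicon"`: data frame with `term`, `group`.
#' @export
read_lexicon <- function(path, header = FALSE) {
  d <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("lexicon needs two tab-separated columns")
  names(d)[1:2] <- c("term", "group")
  concept_lexicon(d$term, d$group)
}

#' @rdname read_lexicon
#' @param term,group Character vectors of equal length.
#' @export
concept_lexicon <- function(term, group) {
  stopifnot(length(term) == length(group), all(nzchar(term)))
  term <- tolower(trimws(term))
  ntok <- lengths(strsplit(term, "[ \t]+"))
  if (any(ntok < 1L | ntok > 5L))
    stop("lexicon terms must have 1-5 tokens")
  if (anyDuplicated(term))
    stop("duplicate lexicon terms")
  structure(data.frame(term = term, group = as.character(group),
                       stringsAsFactors = FALSE),
            class = c("concept_lexicon", "data.frame"))
}

#' Tag concept mentions in a document
#'
#' Case-insensitive longest-match scan over token n-grams (n <= 5):
#' at each token position the longest lexicon term starting there is
#' matched; matched tokens are consumed, so mentions never overlap
#' ("diabetes mellitus" beats "diabetes"). After matching, mentions whose
#' semantic group is in `excluded_groups` are dropped — exclusion filters
#' the output and never unblocks shorter overlapping matches, so
#' shrinking the exclusion list can only add mentions.
#'
#' @param doc A [document()] object or character scalar of text.
#' @param lexicon A [concept_lexicon()].
#' @param excluded_groups Character vector of group labels to drop
#'   (default [excluded_semantic_groups()]).
#' @return Data frame of mentions: `start_token`, `end_token` (1-based,
#'   inclusive, over the document's token sequence), `term` (lexicon
#'   form), `group`.
#' @export
tag_concepts <- function(doc, lexicon,
                         excluded_groups = excluded_semantic_groups()) {
  stopifnot(inherits(lexicon, "concept_lexicon"), nrow(lexicon) > 0L)
  text <- if (inherits(doc, "rp_document")) doc$text else doc
  toks <- unlist(lapply(segment_sentences(text), tokenize), use.names = FALSE)
  low <- tolower(toks)
  n <- length(low)
  lex <- stats::setNames(lexicon$group, lexicon$term)
  max_len <- max(lengths(strsplit(lexicon$term, " ", fixed = TRUE)))

  starts <- integer(0); ends <- integer(0); terms <- character(0)
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      cand <- paste(low[i:(i + len - 1L)], collapse = " ")
      if (!is.na(lex[cand])) { hit <- len; break }
    }
    if (hit > 0L) {
      starts <- c(starts, i); ends <- c(ends, i + hit - 1L)
      terms <- c(terms, paste(low[i:(i + hit - 1L)], collapse = " "))
      i <- i + hit
    } else {
      i <- i + 1L
    }
  }
  out <- data.frame(start_token = starts, end_token = ends, term = terms,
                    group = unname(lex[terms]), stringsAsFactors = FALSE)
  out[!(out$group %in% excluded_groups), , drop = FALSE]
}

#' Concept counts for a tagged document
#'
#' @param mentions Mention data frame from [tag_concepts()].
#' @return List with `n_all` (mention count) and `n_unique` (distinct
#'   case-folded concept strings).
#' @export
concept_counts <- function(mentions) {
  list(n_all = nrow(mentions),
       n_unique = length(unique(tolower(mentions$term))))
}

#' Tag and count concepts across a corpus
#'
#' @param corpus List of [document()] objects.
#' @inheritParams tag_concepts
#' @return Data frame: `doc_id`, `n_all`, `n_unique`, `n_tokens`.
#' @export
concept_counts_corpus <- function(corpus, lexicon,
                                  excluded_groups = excluded_semantic_groups()) {
  rows <- lapply(corpus, function(d) {
    m <- tag_concepts(d, lexicon, excluded_groups)
    cc <- concept_counts(m)
    ntok <- length(unlist(lapply(segment_sentences(d$text), tokenize),
                          use.names = FALSE))
    data.frame(doc_id = d$doc_id, n_all = cc$n_all, n_unique = cc$n_unique,
               n_tokens = ntok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between concept counts and ratings
#'
#' Per rater, the Pearson correlation between their ratings and the
#' documents' concept counts (all mentions or unique concepts) within one
#' genre, Fisher z-averaged over raters.
#'
#' @inheritParams rater_formula_correlation
#' @param counts Data frame with `doc_id` and `n_all`/`n_unique` (e.g.
#'   from [concept_counts_corpus()]).
#' @param mode `"all"` or `"unique"` concept counts.
#' @param genre_of Named character vector mapping `doc_id` to genre (e.g.
#'   from a scored corpus).
#' @param genre `"wiki"` or `"med"`.
#' @return A `"correlation_summary"` object.
#' @export
concept_rating_correlation <- function(ratings, counts,
                                       mode = c("all", "unique"),
                                       genre_of, genre = c("wiki", "med"),
                                       min_docs = 3L, spearman = FALSE) {
  mode <- match.arg(mode)
  genre <- match.arg(genre)
  col <- if (mode == "all") "n_all" else "n_unique"
  covariate <- stats::setNames(counts[[col]], counts$doc_id)
  rating_covariate_correlation(ratings, covariate, genre_of, genre,
                               unit = "concepts-vs-ratings",
                               min_docs = min_docs, spearman = spearman)
}
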