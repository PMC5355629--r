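# End-to-end orchestration: score -> pair -> sessions -> (simulated)
# ratings -> every table analog, collected into one report object that
# serializes to JSON.

#' Run the full analysis pipeline
#'
#' Executes the whole study on either a synthetic corpus (the default)
#' or user-supplied corpus/ratings files, and collects every analysis
#' into an `"analysis_report"`:
#' genre means with percent differences and Mann-Whitney p-values
#' (`genre_summary`), inter-rater agreement buckets (`agreement`),
#' rater-versus-formula correlations (`formula_agreement`),
#' paired-difficulty tests (`paired_tests`), concept-count correlations
#' (`concept_agreement`), the vocabulary-overlap curve and slope test
#' (`overlap`), the formula inter-correlation (`intercorrelation`), the
#' FKGL-binned rating differences (`binned`), and provenance.
#'
#' @param config A named list, or path to a YAML file holding one.
#'   Recognized entries (all optional): `seed` (root seed, default 1);
#'   `simulate` with `wiki`, `med` (lists of [genre_params()]
#'   overrides) and `raters` ([rater_params()] overrides); or `corpus`
#'   (list with `dir`, `manifest`), `ratings` (CSV path), `lexicon`
#'   (TSV path) for real data; `analysis` with `min_overlap`,
#'   `bin_edges`, `n_boot`, `polysyllable_min`, `abbrev_mode`.
#' @return An `"analysis_report"` object.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  an <- config$analysis %||% list()
  poly <- as.integer(an$polysyllable_min %||% 3L)
  abbrev_mode <- an$abbrev_mode %||% "plain"

  if (is.null(config$corpus)) {
    sim <- config$simulate %||% list()
    wiki <- do.call(genre_params, utils::modifyList(
      unclass(wiki_genre_params()), sim$wiki %||% list()))
    med <- do.call(genre_params, utils::modifyList(
      unclass(med_genre_params()), sim$med %||% list()))
    rp <- do.call(rater_params, sim$raters %||% list())
    study <- simulate_study(wiki, med, rp, seed)
    corpus <- study$corpus
    scores <- score_corpus(corpus, polysyllable_min = poly,
                           abbrev_mode = abbrev_mode)
    pairs <- study$pairs
    sessions <- study$sessions
    ratings <- study$ratings
    lexicon <- study$lexicon
    source_kind <- "synthetic"
  } else {
    corpus <- read_corpus(config$corpus$dir, config$corpus$manifest)
    scores <- score_corpus(corpus, polysyllable_min = poly,
                           abbrev_mode = abbrev_mode)
    pr <- enumerate_pairs(scores)
    pairs <- pr$pairs
    sessions <- NULL
    if (is.null(config$ratings)) stop("config$ratings is required for a real corpus")
    ratings <- utils::read.csv(config$ratings, stringsAsFactors = FALSE)
    lexicon <- if (!is.null(config$lexicon)) read_lexicon(config$lexicon)
               else default_concept_lexicon()
    source_kind <- "files"
  }
  seeds <- substream_seeds(seed + 1L, 2L)

  # --- genre summary (score/rating means, percent differences, MW p)
  rat <- collapse_ratings(ratings)
  genre_of <- stats::setNames(scores$genre, scores$doc_id)
  rat$genre <- genre_of[rat$doc_id]
  metrics <- list(fkgl = scores$fkgl, smog = scores$smog, gfi = scores$gfi)
  genre_summary <- lapply(names(metrics), function(m) {
    w <- metrics[[m]][scores$genre == "wiki"]
    d <- metrics[[m]][scores$genre == "med"]
    list(metric = m, mean_wiki = mean(w), mean_med = mean(d),
         percent_difference = percent_difference(mean(w), mean(d)),
         mw_p = genre_distribution_test(w, d))
  })
  rw <- rat$rating[rat$genre == "wiki"]; rm_ <- rat$rating[rat$genre == "med"]
  genre_summary$rating <- list(
    metric = "rating", mean_wiki = mean(rw), mean_med = mean(rm_),
    percent_difference = percent_difference(mean(rw), mean(rm_)),
    mw_p = genre_distribution_test(rw, rm_))
  names(genre_summary) <- c(names(metrics), "rating")

  # --- agreement analyses
  agreement <- inter_rater_agreement(ratings,
                                     min_overlap = an$min_overlap %||% 4L)
  formula_agreement <- list()
  for (f in c("fkgl", "smog", "gfi"))
    for (g in c("wiki", "med"))
      formula_agreement[[paste(f, g, sep = "_")]] <-
        suppressWarnings(rater_formula_correlation(ratings, scores, f, g))

  # --- paired-difficulty tests
  paired_tests <- lapply(stats::setNames(nm = c("wiki", "med", "mixed")),
                         function(tp) {
    tryCatch(paired_difficulty_tests(ratings, pairs, tp, seed = seeds[1]),
             rp_insufficient_data = function(e) NULL)
  })

  # --- concept analyses
  ccounts <- concept_counts_corpus(corpus, lexicon)
  concept_agreement <- list()
  for (m in c("all", "unique"))
    for (g in c("wiki", "med"))
      concept_agreement[[paste(m, g, sep = "_")]] <-
        suppressWarnings(concept_rating_correlation(
          ratings, ccounts, m, genre_of, g))

  # --- overlap and intercorrelation
  wiki_docs <- corpus[vapply(corpus, `[[`, "", "genre") == "wiki"]
  med_docs <- corpus[vapply(corpus, `[[`, "", "genre") == "med"]
  va <- frequency_ranked_vocabulary(wiki_docs)
  vb <- frequency_ranked_vocabulary(med_docs)
  curve <- common_word_curve(va, vb)
  slope <- slope_test(curve)
  intercorrelation <- formula_intercorrelation(scores)

  # --- binned rating differences
  binned <- binned_rating_difference(ratings, scores, sessions,
                                     bin_edges = an$bin_edges %||% 0:6,
                                     n_boot = an$n_boot %||% 2000L,
                                     seed = seeds[2])

  structure(list(
    genre_summary = genre_summary,
    agreement = agreement,
    formula_agreement = formula_agreement,
    paired_tests = paired_tests,
    concept_agreement = concept_agreement,
    overlap = list(curve = as.data.frame(curve), slope = slope$slope,
                   slope_se = slope$se, p_less_than_1 = slope$p_less_than_1),
    intercorrelation = intercorrelation,
    binned = binned,
    provenance = list(seed = seed, source = source_kind,
                      n_documents = length(corpus),
                      n_ratings = nrow(ratings),
                      package_version = as.character(
                        utils::packageVersion("readperception")),
                      r_version = as.character(getRversion()))
  ), class = "analysis_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analysis_report <- function(x, ...) {
  cat("Readability-versus-perception analysis report\n")
  cat(sprintf("  source: %s, %d documents, %d ratings, seed %d\n",
              x$provenance$source, x$provenance$n_documents,
              x$provenance$n_ratings, x$provenance$seed))
  cat("\nGenre means (wiki / med, % difference, Mann-Whitney p):\n")
  for (g in x$genre_summary)
    cat(sprintf("  %-7s %7.2f / %7.2f   %+7.2f%%   p = %.3g\n", g$metric,
                g$mean_wiki, g$mean_med, g$percent_difference, g$mw_p))
  cat(sprintf("\nInter-rater agreement: Fisher mean r = %.3f (buckets %s)\n",
              x$agreement$fisher_mean,
              paste(sprintf("%s: %d", names(x$agreement$buckets),
                            x$agreement$buckets), collapse = ", ")))
  cat("Rater-vs-formula Fisher mean r:\n")
  for (k in names(x$formula_agreement))
    cat(sprintf("  %-10s %6.3f\n", k, x$formula_agreement[[k]]$fisher_mean))
  cat("Paired-difficulty tests (Wilcoxon p / KS p):\n")
  for (tp in names(x$paired_tests)) {
    pt <- x$paired_tests[[tp]]
    if (is.null(pt)) next
    cat(sprintf("  %-6s %.3g / %.3g  (n = %d)\n", tp, pt$wilcoxon_p,
                pt$ks_p, pt$n))
  }
  cat("Concept-count vs rating Fisher mean r:\n")
  for (k in names(x$concept_agreement))
    cat(sprintf("  %-12s %6.3f\n", k, x$concept_agreement[[k]]$fisher_mean))
  cat(sprintf("Vocabulary overlap slope = %.3f (p[slope<1] = %.3g)\n",
              x$overlap$slope, x$overlap$p_less_than_1))
  invisible(x)
}

#' @export
summary.analysis_report <- function(object, ...) print(object, ...)

#' Write / read an analysis report as JSON
#'
#' The JSON round-trips: `read_report(write_report(x, f))` restores the
#' same structure (data frames as row-wise records, matrices by row).
#'
#' @param report An `"analysis_report"`.
#' @param path Output path.
#' @return `write_report` invisibly returns `path`; `read_report`
#'   returns the parsed report (an `"analysis_report"`).
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  x$agreement <- serialize_corsum(x$agreement)
  x$formula_agreement <- lapply(x$formula_agreement, serialize_corsum)
  x$concept_agreement <- lapply(x$concept_agreement, serialize_corsum)
  x$intercorrelation <- list(metrics = colnames(report$intercorrelation),
                             values = as.data.frame(report$intercorrelation))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

serialize_corsum <- function(cs) {
  list(unit = cs$unit, per_rater = as.list(cs$per_rater),
       fisher_mean = cs$fisher_mean, n_overlap = as.list(cs$n_overlap),
       buckets = if (!is.null(cs$buckets)) as.list(cs$buckets) else NULL)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "analysis_report")
}
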