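# Synthetic two-genre corpora and simulated raters with known ground
# truth. Vocabulary is built from CV(C) syllable units so that syllable
# counts are exact by construction; concept terms and abbreviations use
# disjoint character alphabets so injected material is recoverable
# exactly by the taggers.

base_consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t")
base_vowels <- c("a", "i", "o", "u")
concept_consonants <- c("v", "w", "z", "c", "h", "j")

#' Genre parameters for the synthetic corpus generator
#'
#' Describes one genre of a two-genre corpus: vocabulary size and Zipf
#' exponent, the fraction of word types shared with the partner genre,
#' sentence-length distribution, the per-word syllable distribution,
#' abbreviation rate, medical-concept density, and corpus dimensions.
#' Per-document heterogeneity knobs (`doc_complexity_sd`,
#' `sentence_length_doc_sd`, `concept_density_cv`) spread documents out
#' in grade level and concept load the way real corpora spread.
#'
#' @param vocab_size Number of word types.
#' @param zipf_exponent Zipf rank exponent for token sampling.
#' @param shared_core_fraction Fraction of types shared with the partner
#'   genre, in `[0, 1]`.
#' @param mean_sentence_length Mean words per sentence.
#' @param sentence_length_dispersion Negative-binomial size parameter for
#'   sentence lengths (smaller = more dispersed).
#' @param syllable_distribution Probabilities over 1..6 syllables per
#'   word type.
#' @param abbreviation_rate Per-token probability of replacement by an
#'   all-caps, one-syllable abbreviation.
#' @param concept_density Expected injected concept mentions per 100
#'   words.
#' @param docs Number of documents.
#' @param doc_length_range Min/max document length in tokens.
#' @param doc_complexity_sd SD of the per-document exponential tilt on
#'   the syllable distribution (0 = homogeneous documents).
#' @param sentence_length_doc_sd SD (log scale) of the per-document
#'   sentence-length multiplier.
#' @param concept_density_cv Coefficient of variation of the
#'   per-document concept density (gamma multiplier; 0 = homogeneous).
#' @return A `"genre_params"` list.
#' @export
genre_params <- function(vocab_size = 2000L, zipf_exponent = 1.1,
                         shared_core_fraction = 0.5,
                         mean_sentence_length = 15,
                         sentence_length_dispersion = 5,
                         syllable_distribution = c(0.40, 0.33, 0.17, 0.07, 0.025, 0.005),
                         abbreviation_rate = 0.01,
                         concept_density = 3,
                         docs = 100L,
                         doc_length_range = c(200L, 1000L),
                         doc_complexity_sd = 0.15,
                         sentence_length_doc_sd = 0.15,
                         concept_density_cv = 0.4) {
  stopifnot(vocab_size >= 10, zipf_exponent > 0,
            shared_core_fraction >= 0, shared_core_fraction <= 1,
            mean_sentence_length > 1, sentence_length_dispersion > 0,
            length(syllable_distribution) == 6L,
            all(syllable_distribution >= 0),
            abs(sum(syllable_distribution) - 1) < 1e-8,
            abbreviation_rate >= 0, abbreviation_rate <= 1,
            concept_density >= 0, docs >= 1,
            length(doc_length_range) == 2L,
            doc_length_range[1] <= doc_length_range[2],
            doc_length_range[1] >= 10)
  structure(as.list(environment()), class = "genre_params")
}

#' @rdname genre_params
#' @details `wiki_genre_params()` and `med_genre_params()` are the
#'   default study conditions: the wiki genre has long sentences and a
#'   heavier syllable tail (high grade level), few abbreviations and a
#'   low concept density; the med genre has short, list-like sentences,
#'   frequent one-syllable all-caps abbreviations (which *lower* its
#'   grade level) and a high concept density — so the formulas call med
#'   easier while simulated raters, driven by concept load and genre,
#'   call it harder.
#' @export
wiki_genre_params <- function() {
  genre_params(vocab_size = 2000L, zipf_exponent = 0.9,
               shared_core_fraction = 0.5,
               mean_sentence_length = 22,
               sentence_length_dispersion = 5,
               syllable_distribution = c(0.10, 0.23, 0.28, 0.22, 0.11, 0.06),
               abbreviation_rate = 0.005,
               concept_density = 1.5,
               docs = 140L,
               doc_length_range = c(500L, 1500L),
               doc_complexity_sd = 0.25,
               sentence_length_doc_sd = 0.2,
               concept_density_cv = 0.4)
}

#' @rdname genre_params
#' @export
med_genre_params <- function() {
  genre_params(vocab_size = 2000L, zipf_exponent = 0.9,
               shared_core_fraction = 0.5,
               mean_sentence_length = 10,
               sentence_length_dispersion = 3,
               syllable_distribution = c(0.12, 0.25, 0.28, 0.21, 0.09, 0.05),
               abbreviation_rate = 0.08,
               concept_density = 6,
               docs = 242L,
               doc_length_range = c(250L, 750L),
               doc_complexity_sd = 0.25,
               sentence_length_doc_sd = 0.2,
               concept_density_cv = 0.4)
}

#' Simulated-rater parameters
#'
#' The latent difficulty a simulated rater perceives for a document is
#' `intercept + weight_concepts * (unique concepts per 100 words) +
#' weight_genre * 1[med] + weight_fkgl * FKGL`; the emitted rating is
#' `clamp(round(bias_r + D + Normal(0, noise_sd)), 1, 10)` with a
#' per-rater bias drawn from `Normal(0, rater_bias_sd)`. The defaults
#' put inter-rater agreement in the moderate-to-strong band while
#' keeping rater-versus-formula correlation weak — the regime the
#' analyses are designed to detect.
#'
#' @param n_raters Number of raters.
#' @param weight_concepts,weight_genre,weight_fkgl Difficulty weights.
#' @param noise_sd Per-rating noise SD (> 0).
#' @param rater_bias_sd SD of the per-rater additive bias.
#' @param intercept Baseline difficulty.
#' @return A `"rater_params"` list.
#' @export
rater_params <- function(n_raters = 15L, weight_concepts = 0.7,
                         weight_genre = 1.2, weight_fkgl = 0.1,
                         noise_sd = 1.0, rater_bias_sd = 0.5,
                         intercept = 2.2) {
  stopifnot(n_raters >= 1, noise_sd > 0, rater_bias_sd >= 0)
  structure(as.list(environment()), class = "rater_params")
}

# ---- vocabulary construction -------------------------------------------

# One CV(C) syllable unit; `coda` adds a trailing consonant half the time.
sample_units <- function(n, consonants, vowels) {
  coda <- sample(c("", consonants), n, replace = TRUE,
                 prob = c(length(consonants), rep(1, length(consonants))))
  paste0(sample(consonants, n, replace = TRUE),
         sample(vowels, n, replace = TRUE), coda)
}

# n distinct words with syllable counts drawn from `syl_probs` (over
# 1..6); returns data.frame(word, syllables). Duplicates are resolved by
# appending another unit, so realized counts can exceed the draw.
make_words <- function(n, syl_probs,
                       consonants = base_consonants, vowels = base_vowels,
                       avoid = character(0)) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (w in avoid) assign(w, TRUE, envir = seen)
  words <- character(n); syls <- integer(n)
  ks <- sample.int(6L, n, replace = TRUE, prob = syl_probs)
  for (i in seq_len(n)) {
    k <- ks[i]
    w <- paste(sample_units(k, consonants, vowels), collapse = "")
    while (!is.null(seen[[w]])) {
      w <- paste0(w, sample_units(1L, consonants, vowels))
      k <- k + 1L
    }
    assign(w, TRUE, envir = seen)
    words[i] <- w; syls[i] <- k
  }
  data.frame(word = words, syllables = syls, stringsAsFactors = FALSE)
}

#' Build a pair of genre vocabularies with a shared core
#'
#' The two genres share `shared_core_fraction` of their word types; the
#' shared types are placed at the same evenly spaced rank positions in
#' both genres, so the top-N frequency lists overlap by about that
#' fraction at every depth — the quantity the common-word curve
#' estimates.
#'
#' @param params_a,params_b [genre_params()] for the two genres.
#' @param seed Integer seed.
#' @return List with `a` and `b`: each a data frame (`word`,
#'   `syllables`) in rank order (most frequent first), plus `shared`
#'   (the shared word types).
#' @export
shared_vocabulary <- function(params_a, params_b, seed) {
  stopifnot(inherits(params_a, "genre_params"),
            inherits(params_b, "genre_params"))
  with_seed(seed, {
    va <- params_a$vocab_size; vb <- params_b$vocab_size
    frac <- mean(c(params_a$shared_core_fraction,
                   params_b$shared_core_fraction))
    n_shared <- round(frac * min(va, vb))
    mix_probs <- (params_a$syllable_distribution +
                    params_b$syllable_distribution) / 2
    shared <- if (n_shared > 0)
      make_words(n_shared, mix_probs) else
      data.frame(word = character(0), syllables = integer(0))
    own_a <- make_words(va - n_shared, params_a$syllable_distribution,
                        avoid = shared$word)
    own_b <- make_words(vb - n_shared, params_b$syllable_distribution,
                        avoid = c(shared$word, own_a$word))
    # frequent types are shorter, as in natural language: order every
    # word list by jittered syllable count before assigning ranks (this
    # also stabilises the corpus-level syllable mix across seeds)
    jit <- function(d) d[order(d$syllables + stats::rnorm(nrow(d), 0, 0.3)), ,
                         drop = FALSE]
    shared <- jit(shared); own_a <- jit(own_a); own_b <- jit(own_b)
    list(a = interleave_ranks(shared, own_a, va),
         b = interleave_ranks(shared, own_b, vb),
         shared = shared$word)
  })
}

# Place shared words at evenly spaced rank positions 1..v.
interleave_ranks <- function(shared, own, v) {
  out <- data.frame(word = character(v), syllables = integer(v),
                    stringsAsFactors = FALSE)
  ns <- nrow(shared)
  if (ns > 0) {
    pos <- unique(round(seq(1, v, length.out = ns)))
    while (length(pos) < ns)  # rounding collisions at high fractions
      pos <- sort(union(pos, setdiff(seq_len(v), pos)[1]))
    out[pos, ] <- shared
    out[setdiff(seq_len(v), pos), ] <- own
  } else {
    out <- own
  }
  out
}

#' Default synthetic concept lexicon
#'
#' Sixty deterministic concept terms (1-3 tokens each) built from a
#' character alphabet disjoint from the base vocabulary and the
#' abbreviation pool, so an injected mention can only ever match itself.
#' Groups cycle through four countable medical groups and two groups on
#' the default exclusion list, exercising the exclusion filter.
#'
#' @return A [concept_lexicon()].
#' @export
default_concept_lexicon <- function() {
  units <- as.vector(outer(concept_consonants, base_vowels, paste0))
  toks <- as.vector(outer(units, units, paste0))[1:100]
  terms <- c(toks[1:30],
             paste(toks[seq(31, 69, 2)], toks[seq(32, 70, 2)]),
             paste(toks[seq(71, 98, 3)], toks[seq(72, 99, 3)],
                   toks[seq(73, 100, 3)]))
  groups <- rep_len(c("Disorders", "Chemicals & Drugs", "Procedures",
                      "Signs & Symptoms", "Anatomical Structure",
                      "Concepts & Ideas"), length(terms))
  concept_lexicon(terms, groups)
}

# Deterministic all-caps, vowel-free (hence one-syllable) abbreviations.
abbreviation_pool <- function(n = 40L) {
  cons <- toupper(c("b", "d", "g", "k", "l", "m", "n", "p", "r", "s", "t"))
  two <- as.vector(outer(cons, cons, paste0))
  three <- as.vector(outer(two, cons, paste0))
  head(c(two[seq(1, length(two), 3)], three), n)
}

# Tilt a syllable distribution by exp(t * k) (doc-level complexity).
tilt_probs <- function(p, t) {
  q <- p * exp(t * seq_along(p))
  q / sum(q)
}

#' Generate one synthetic genre corpus
#'
#' Samples word tokens from a Zipf distribution over the genre
#' vocabulary, groups them into sentences with a negative-binomial
#' length distribution, replaces tokens with abbreviations at
#' `abbreviation_rate`, and injects concept-lexicon mentions at the
#' genre's concept density. Returns the documents together with the
#' exact ground truth used for injection, so every downstream counter
#' can be validated in a closed loop.
#'
#' @param params A [genre_params()].
#' @param genre_label `"wiki"` or `"med"`.
#' @param seed Integer seed (byte-identical output for equal seeds).
#' @param vocabulary Rank-ordered vocabulary data frame (`word`,
#'   `syllables`), typically one side of [shared_vocabulary()]. If
#'   `NULL`, a standalone vocabulary is built from `params`.
#' @param lexicon A [concept_lexicon()] supplying injectable terms
#'   (default [default_concept_lexicon()]).
#' @return List with `corpus` (list of [document()]) and `truth` (data
#'   frame: `doc_id`, `genre`, `n_sentences`, `n_tokens`, `n_syllables`,
#'   `concepts_injected`, `concepts_all`, `concepts_unique`,
#'   `unique_per_100w`; the `concepts_*` counts apply the default
#'   semantic-group exclusions).
#' @export
generate_corpus <- function(params, genre_label = c("wiki", "med"), seed,
                            vocabulary = NULL,
                            lexicon = default_concept_lexicon()) {
  genre_label <- match.arg(genre_label)
  stopifnot(inherits(params, "genre_params"))
  seeds <- substream_seeds(seed, 2L)
  if (is.null(vocabulary))
    vocabulary <- with_seed(seeds[1],
                            make_words(params$vocab_size,
                                       params$syllable_distribution))
  v <- nrow(vocabulary)
  zipf_p <- seq_len(v)^(-params$zipf_exponent)
  zipf_p <- zipf_p / sum(zipf_p)

  abbrevs <- abbreviation_pool()
  lex_terms <- strsplit(lexicon$term, " ", fixed = TRUE)
  countable <- !(lexicon$group %in% excluded_semantic_groups())
  # exact syllable counts for every token the generator can emit
  syl_of <- c(stats::setNames(vocabulary$syllables, vocabulary$word),
              stats::setNames(rep(1L, length(abbrevs)), tolower(abbrevs)),
              local({
                lt <- unique(unlist(lex_terms, use.names = FALSE))
                stats::setNames(count_syllables(lt), lt)
              }))

  with_seed(seeds[2], {
    docs <- vector("list", params$docs)
    truth <- vector("list", params$docs)
    for (d in seq_len(params$docs)) {
      len <- sample(params$doc_length_range[1]:params$doc_length_range[2], 1L)
      toks <- vocabulary$word[sample.int(v, len, replace = TRUE, prob = zipf_p)]
      # per-document syllable tilt: resample word identities from the
      # tilted type distribution
      if (params$doc_complexity_sd > 0) {
        t_d <- stats::rnorm(1L, 0, params$doc_complexity_sd)
        w <- tilt_probs(params$syllable_distribution, t_d)
        ratio <- (w / params$syllable_distribution)[vocabulary$syllables]
        ratio[is.na(ratio) | !is.finite(ratio)] <- 1
        toks <- vocabulary$word[sample.int(v, len, replace = TRUE,
                                           prob = zipf_p * ratio)]
      }
      # abbreviations
      ab <- stats::runif(len) < params$abbreviation_rate
      if (any(ab)) toks[ab] <- sample(abbrevs, sum(ab), replace = TRUE)
      # concept injection
      dens <- params$concept_density
      if (params$concept_density_cv > 0 && dens > 0) {
        shp <- 1 / params$concept_density_cv^2
        dens <- dens * stats::rgamma(1L, shape = shp, rate = shp)
      }
      n_c <- if (dens > 0) stats::rpois(1L, dens * len / 100) else 0L
      inj_terms <- integer(0)
      if (n_c > 0) {
        inj_terms <- sample.int(nrow(lexicon), n_c, replace = TRUE)
        at <- sort(sample.int(length(toks) + 1L, n_c, replace = TRUE),
                   decreasing = TRUE)
        for (m in seq_len(n_c))
          toks <- append(toks, lex_terms[[inj_terms[m]]], after = at[m] - 1L)
      }
      n_tok <- length(toks)
      # sentence lengths (per-document mean multiplier, lognormal)
      mu <- params$mean_sentence_length *
        exp(stats::rnorm(1L, 0, params$sentence_length_doc_sd))
      sl <- integer(0)
      while (sum(sl) < n_tok)
        sl <- c(sl, pmax(1L, stats::rnbinom(16L, size = params$sentence_length_dispersion,
                                            mu = mu)))
      sl <- sl[cumsum(sl) - sl < n_tok]
      sl[length(sl)] <- n_tok - sum(sl[-length(sl)])
      stops <- cumsum(sl)
      starts <- c(1L, stops[-length(stops)] + 1L)
      sents <- vapply(seq_along(sl), function(s) {
        piece <- toks[starts[s]:stops[s]]
        piece[1] <- paste0(toupper(substr(piece[1], 1, 1)),
                           substr(piece[1], 2, nchar(piece[1])))
        paste(piece, collapse = " ")
      }, character(1))
      text <- paste0(paste(sents, collapse = ".\n"), ".")
      doc_id <- sprintf("%s%03d", genre_label, d)
      docs[[d]] <- document(doc_id, genre_label, text)
      cnt <- inj_terms[countable[inj_terms]]
      truth[[d]] <- data.frame(
        doc_id = doc_id, genre = genre_label,
        n_sentences = length(sl), n_tokens = n_tok,
        n_syllables = sum(syl_of[tolower(toks)]),
        concepts_injected = n_c,
        concepts_all = length(cnt),
        concepts_unique = length(unique(cnt)),
        unique_per_100w = 100 * length(unique(cnt)) / n_tok,
        stringsAsFactors = FALSE)
    }
    list(corpus = docs, truth = do.call(rbind, truth))
  })
}

#' Simulate rater difficulty judgments
#'
#' Applies the [rater_params()] perception model to every document
#' presentation in `sessions`, producing one 1-10 rating per (rater,
#' document, pair) triple.
#'
#' @param scores Scored corpus from [score_corpus()] (supplies FKGL and
#'   genre).
#' @param truth Ground-truth data frame from [generate_corpus()]
#'   (supplies `unique_per_100w`).
#' @param rparams A [rater_params()].
#' @param sessions Session data frame from [build_sessions()].
#' @param seed Integer seed.
#' @return Ratings data frame: `rater_id`, `doc_id`, `pair_id`,
#'   `rating`.
#' @export
simulate_raters <- function(scores, truth, rparams, sessions, seed) {
  stopifnot(inherits(rparams, "rater_params"))
  fk <- stats::setNames(scores$fkgl, scores$doc_id)
  gn <- stats::setNames(scores$genre, scores$doc_id)
  cu <- stats::setNames(truth$unique_per_100w, truth$doc_id)
  with_seed(seed, {
    raters <- unique(sessions$rater_id)
    bias <- stats::setNames(
      stats::rnorm(length(raters), 0, rparams$rater_bias_sd), raters)
    long <- rbind(
      data.frame(rater_id = sessions$rater_id, doc_id = sessions$doc_left,
                 pair_id = sessions$pair_id, stringsAsFactors = FALSE),
      data.frame(rater_id = sessions$rater_id, doc_id = sessions$doc_right,
                 pair_id = sessions$pair_id, stringsAsFactors = FALSE))
    d <- rparams$intercept +
      rparams$weight_concepts * cu[long$doc_id] +
      rparams$weight_genre * as.numeric(gn[long$doc_id] == "med") +
      rparams$weight_fkgl * fk[long$doc_id]
    raw <- bias[long$rater_id] + d + stats::rnorm(nrow(long), 0, rparams$noise_sd)
    long$rating <- pmin(pmax(round(raw), 1L), 10L)
    rownames(long) <- NULL
    long[order(long$rater_id, long$pair_id, long$doc_id), ]
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: builds the shared vocabularies, both genre
#' corpora, scores, eligible pairs, sessions and simulated ratings from
#' one root seed (split into named substreams so each stage is
#' independently reproducible).
#'
#' @param wiki_params,med_params [genre_params()] for the two genres.
#' @param rparams A [rater_params()].
#' @param seed Integer root seed.
#' @param lexicon A [concept_lexicon()].
#' @return List with `corpus` (both genres), `truth`, `scores`, `pairs`,
#'   `paired_docs`, `sessions`, `ratings`, `lexicon`.
#' @export
simulate_study <- function(wiki_params = wiki_genre_params(),
                           med_params = med_genre_params(),
                           rparams = rater_params(), seed = 1L,
                           lexicon = default_concept_lexicon()) {
  seeds <- substream_seeds(seed, 5L)
  vocab <- shared_vocabulary(wiki_params, med_params, seeds[1])
  gw <- generate_corpus(wiki_params, "wiki", seeds[2], vocab$a, lexicon)
  gm <- generate_corpus(med_params, "med", seeds[3], vocab$b, lexicon)
  corpus <- c(gw$corpus, gm$corpus)
  truth <- rbind(gw$truth, gm$truth)
  scores <- score_corpus(corpus)
  pr <- enumerate_pairs(scores)
  sessions <- build_sessions(pr$pairs, rparams$n_raters, seeds[4])
  ratings <- simulate_raters(scores, truth, rparams, sessions, seeds[5])
  list(corpus = corpus, truth = truth, scores = scores, pairs = pr$pairs,
       paired_docs = pr$paired_docs, sessions = sessions,
       ratings = ratings, lexicon = lexicon)
}
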