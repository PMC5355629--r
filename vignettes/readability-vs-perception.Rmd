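---
title: "Readability formulas versus perceived difficulty: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Readability formulas versus perceived difficulty: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in
`readperception`, the design decisions behind them, and what the
package's synthetic validation does — and does not — establish about
real clinical text.

## The question

Grade-level readability formulas (FKGL, SMOG, GFI) reduce a document to
sentence-length and word-length statistics. Their shared assumption —
longer units mean harder text — fails in two directions on clinical
notes: the notes are list-like and abbreviation-dense, which *lowers*
their scores, while their jargon density *raises* the difficulty actual
readers experience. The package operationalizes this comparison: score
two genres of text, collect (or simulate) paired human difficulty
ratings, and measure where formula predictions and perception agree or
part ways.

## Text decomposition

All three formulas consume `TextStats`: sentence count `S`, word count
`W`, syllable count `Syl`, and the polysyllabic-word count `P`.

**Sentences.** A sentence ends at `.`, `?` or `!` followed by
whitespace and a capital letter, or at any newline. The newline rule is
essential for clinical text, where vitals and medication lists appear
one item per line with no terminal punctuation. A configurable list of
dotted abbreviations (`"Dr."`, `"mg."`, `"q.d."`, ...) suppresses
splits; the trade-off is that a genuine sentence boundary immediately
after such a token is missed, which we consider the cheaper error in
this domain. Segmentation is total: every non-whitespace character
lands in exactly one sentence, so token multisets are preserved.

**Tokens.** Maximal alphanumeric runs with internal apostrophes and
hyphens. No stop-word removal anywhere; case is preserved until a
consumer folds it (syllable counting and vocabulary ranking fold,
word-usage display does not).

**Syllables.** The standard vowel-group heuristic: count maximal runs
of `a e i o u y`, subtract one for a terminal silent "e" that forms its
own group (unless that would reach zero), floor at one; letterless
tokens count one. This matches the behaviour of Flesch-style tooling
and is exact on the synthetic vocabulary (below). It deliberately
treats abbreviations as ordinary tokens — `COPD` is one syllable — to
reproduce the distortion under study. The optional *spell-out* mode
(`abbrev_mode = "spellout"`) instead counts one syllable per letter of
an all-caps token, modelling a reader pronouncing the letters; it
changes only syllable-derived quantities.

**Polysyllables.** Default threshold ≥ 3 syllables, the convention
SMOG and GFI were published with. Because "more than 3" also circulates
as a definition, `polysyllable_min = 4` is supported; nothing else in
the pipeline changes.

## The formulas

```
FKGL = 0.39 · W/S + 11.8 · Syl/W − 15.59
SMOG = 1.0430 · √(30 · P/S) + 3.1291     (floor 3.1291 at P = 0)
GFI  = 0.4 · (W/S + 100 · P/W)
```

Constants are the canonical published values. No minimum-length gate is
applied (clinical notes are often short); documents under the classic
30-sentence SMOG recommendation carry a `short_document` flag instead.
Documents with zero sentences or words are *degenerate*: scoring them
raises a typed condition, and `score_corpus()` drops them with a
warning rather than failing a whole corpus.

## Study design

Pairing is an *eligibility graph*, not a matching: two documents are
pairable when their token counts differ by at most 50 and their FKGL by
at most 0.5 (both inclusive — "within" is read inclusively, and the
boundary behaviour is tested). A document is "paired" if it has at
least one partner; a pair may be shown to any number of raters.
Sessions stratify 5 wiki + 5 med + 10 mixed pairs per rater, sampled
without replacement within a session and independently across sessions,
with left/right display order randomized per presentation. Everything
is reproducible from one seed.

## Rating statistics

**Fisher averaging.** Correlations are averaged on the z scale:
`tanh(mean(atanh(r)))`. With integer ratings on a handful of shared
documents, per-pair correlations of exactly ±1 occur; they are clipped
to ±0.999999 with a warning rather than propagating infinities.
Pearson is the default coefficient (the z-transform is conventional for
Pearson); Spearman is available behind a flag.

**Inter-rater agreement.** For each rater, correlations against every
other rater over co-rated documents (duplicate ratings of a document by
one rater are averaged first), Fisher-averaged, then bucketed
(< 0.4 / 0.4–0.6 / > 0.6). Rater pairs sharing fewer than
`min_overlap = 4` documents are excluded: a correlation on 3 points is
sign noise, and typical designs give ~8–9 shared documents per pair.

**Paired-difficulty tests.** Within-pair rating differences go into a
Wilcoxon signed-rank test; the two sides' pooled rating distributions
into a two-sample KS test. Mixed pairs are oriented wiki-minus-med.
Same-genre pairs have no natural orientation; we randomize it *per
presentation* (not per pair), so repeated presentations of one pair
carry independent signs and the null of no systematic genre-internal
difference is symmetric even though individual pairs genuinely differ
in concept load. If every difference is zero the Wilcoxon p is
reported as 1. Both tests inherit R's exact small-sample behaviour,
verified against full sign/label enumeration in the test suite.

**Binned rating differences.** Per rater, all pairs of rated documents
are rebuilt, the pairs actually shown in that rater's session are
removed, each pair is oriented higher-FKGL-first, and pairs are binned
by absolute FKGL difference (default one-grade bins from 0 to 6; the
choice is a display granularity, not a model parameter). Each bin
reports the mean *signed* oriented difference — the sign convention is
the content: a formula that tracked perception would push the curve
steeply positive — with a percentile bootstrap 95% CI (default 2000
resamples of pairs within bin, seeded). An empty bin is reported as
missing, never as zero; a single-pair bin collapses its CI to the
point.

**Genre summaries.** Mann-Whitney U (rank-based, tie-corrected,
two-sided) compares a score's distribution across genres; percent
difference is `100·(mean_med − mean_wiki)/mean_wiki`, always recomputed
from the report's own means.

## Corpus comparison

Vocabularies are case-folded types ranked by frequency with
alphabetical tie-breaks (deterministic); numerals are excluded. The
common-word curve counts `|top-N(A) ∩ top-N(B)|` over a grid of N
(default every 100 up to the smaller vocabulary, capped at 5000). The
slope of `common ~ N` (least squares, with intercept) is tested
one-sided against 1 via the regression t statistic.

Two caveats are part of the design, not bugs:

- The curve is cumulative, so residuals are autocorrelated and the
  slope's standard error is approximate. We accept this and document
  it; the test is used on effects (slope ≈ 0.5 versus 1) far outside
  the error's resolution.
- Under *resampling* — two independent token samples from the same
  source — the realized curve genuinely bends below the identity line
  in the tail, because finite samples disagree about tail ranks. The
  test rejecting there is signal about the realized rankings, not a
  type-I error; the slope-1 null is exactly true only when the ranked
  vocabularies coincide (e.g. comparing a corpus with any reordering of
  itself, where the fit is exact and p = 1). The test suite pins both
  behaviours.
- A zero-residual fit has no t statistic; `slope_test()` then reports
  p = 1 when the slope is ≥ 1 (within 1e-8) and p = 0 otherwise.

## Concept analysis

MetaMap-style concept mapping is replaced by a pluggable dictionary
tagger: case-insensitive longest-match over token n-grams (n ≤ 5)
against a term → semantic-group lexicon, left to right, matched tokens
consumed (so mentions never overlap and "diabetes mellitus" beats
"diabetes"). Exclusion by semantic group happens *after* matching — the
default exclusion list covers the groups that rarely carry technical
jargon (people, places, organizations, everyday activities) plus
Anatomical Structure, whose mentions in this domain are dominated by
common body words. Filtering after matching guarantees monotonicity:
shrinking the exclusion list can only add mentions. Unique concepts are
keyed by case-folded surface string (the stand-in has no concept IDs).
Counts are used raw, as is conventional when reporting "number of
concepts"; length normalization is left to the difficulty model.

## The synthetic study

The generator exists so that every stage has a closed-loop oracle: it
emits exact ground truth for sentence, token, syllable and concept
counts alongside the text.

**Vocabulary.** Words are concatenations of consonant-vowel(-coda)
units over the alphabet `{b d f g k l m n p r s t} × {a i o u}`, so the
unit count *is* the syllable count under the package's heuristic (no
silent-e forms, no adjacent vowel groups). Concept-lexicon tokens use a
disjoint consonant alphabet (`v w z c h j`) and abbreviations are
vowel-free all-caps strings, so injected material can never collide
with base words and the tagger must recover injections exactly — the
tests assert equality, not approximation.

**Two genres.** Defaults are the package's standing study conditions
(chosen once, by measuring the resulting corpora across several seeds,
then frozen):

| parameter | wiki | med | rationale |
| --- | --- | --- | --- |
| documents | 140 | 242 | the two-genre corpus sizes of the motivating design |
| tokens/doc | 500–1500 | 250–750 | long articles vs short notes |
| mean words/sentence | 22 | 10 | prose vs list-like notes |
| abbreviation rate | 0.005 | 0.08 | one-syllable all-caps tokens depress med scores |
| concept density /100w | 1.5 | 6 | jargon load drives perceived difficulty |
| shared core fraction | 0.5 | 0.5 | top-N overlap slope ≈ 0.5 |
| Zipf exponent | 0.9 | 0.9 | natural-ish head mass |

Frequent types are systematically shorter (rank order follows jittered
syllable count), as in natural language; besides realism this pins the
corpus-level syllable mix, which would otherwise swing by whole grades
between seeds as a few heavy head words changed length. Per-document
heterogeneity — a lognormal sentence-length multiplier (sd 0.2), an
exponential tilt on the syllable distribution (sd 0.25), and a gamma
multiplier on concept density (CV 0.4) — spreads documents over 2–3
FKGL grades within each genre. Without that spread, FKGL-matched
cross-genre pairs would barely exist; with it, the default corpora
yield on the order of 40–120 mixed pairs and the genre means land near
a 14.5 (wiki) versus 9 (med) FKGL contrast.

**Raters.** A rater perceives latent difficulty

```
D = 2.2 + 0.7 · (unique concepts / 100 words) + 1.2 · 1[med] + 0.1 · FKGL
```

and reports `clamp(round(bias_r + D + N(0, 1)), 1, 10)` with a per-rater
bias `N(0, 0.5)`. The weights were set (again before freezing any
tests) so the summary statistics land in the regimes the analyses are
meant to detect: inter-rater Fisher mean ≈ 0.6–0.7, rater-versus-formula
≈ 0.1–0.3, rater-versus-unique-concepts ≈ 0.35–0.5 with unique counts
correlating at least as well as total counts. Clamping affects well
under 5% of ratings, so regressing ratings on the generating covariates
recovers the weights within two standard errors at 5000 ratings.

**What passing does and does not show.** The synthetic corpus has no
syntax, semantics, negation, discourse structure, or genuine
morphology; its "jargon" is an injected dictionary, so tagger recall is
1 by construction; rater behaviour is a linear model plus noise, with
none of the fatigue, anchoring or education effects of real annotators.
Green tests therefore certify the *pipeline* — counting, pairing,
statistics, reproducibility — under known ground truth, not the
substantive conclusion for any real corpus. What carries over to real
data is the machinery and the demonstrated sensitivity: when a corpus
contrast of the designed size exists, the analyses detect it at the
designed rates.

## Numerical and reproducibility choices

- All randomness flows from one root seed, split into named substream
  seeds (`build_sessions`, corpus generation, rater simulation,
  bootstrap), so any stage reruns identically in isolation. RNG state
  is saved and restored around every seeded operation.
- Correlations at ±1 are clipped (±0.999999) with a warning before
  `atanh`.
- Ties: vocabulary ranks break alphabetically; Mann-Whitney and
  Wilcoxon use R's tie-corrected machinery; KS warns on ties and those
  warnings are suppressed at the call site since ratings are discrete
  by design.
- Degenerate inputs raise typed conditions
  (`rp_degenerate_document`, `rp_insufficient_pairs`, `rp_no_overlap`,
  `rp_grid_too_large`, ...) so callers can distinguish data problems
  from bugs.
- Reports serialize to JSON with full precision (`digits = NA`) and
  round-trip; scores are *displayed* to two decimals but never rounded
  internally.

## Problem sizes in the validation suite

The test suite exercises the default-size study (382 documents, 15
raters) where the regime matters, and reduced corpora (50–210
documents) where only mechanics are under test. Replicated checks use
100 rater simulations over a fixed default corpus: the replicated unit
is the rater experiment, which is where the sampling variability under
study lives; regenerating the corpus each time would measure the same
regime at many times the cost. Bootstrap coverage is assessed with 500
replicates of 30 independent pairs at 400 resamples each.

## Known limitations

- The slope test's standard error ignores the curve's autocorrelation
  (see above); treat its p-values as decisive only for large effects.
- The syllable heuristic miscounts some real English ("stable" → 1,
  "diabetes" → 3); counts are exact only on the synthetic vocabulary.
  Real-corpus grade levels will differ slightly from dictionary-based
  tools, in the same way Flesch-style tools differ among themselves.
- Sentence segmentation is rule-based; prose with unusual punctuation
  (quotations, parenthetical sentences) may merge or split units.
- The same-genre Wilcoxon null holds marginally (random orientation),
  but presentations of the same pair share its true difficulty gap;
  with small pair pools and many raters the effective sample size is
  below the presentation count.
- `enumerate_pairs` materializes all document pairs; fine to a few
  thousand documents, quadratic beyond.
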