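Package: readperception
Title: Readability Formulas Versus Perceived Difficulty of Health Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating classic readability formulas (Flesch-Kincaid
    Grade Level, SMOG, Gunning-Fog Index) against human-perceived difficulty
    on two genres of health text: lay-audience encyclopedia articles and
    clinical (EHR-style) notes. Provides deterministic sentence, token and
    syllable counting tuned to list-like clinical text; document pairing by
    length and grade level and stratified rater-session assembly; inter-rater
    and rater-versus-formula agreement via Fisher z-averaged correlations;
    paired-difficulty tests (Wilcoxon signed-rank, Kolmogorov-Smirnov) and
    bootstrap-binned rating differences; genre vocabulary-overlap curves with
    a slope test; dictionary longest-match medical-concept tagging with a
    semantic-group exclusion filter; and a seeded synthetic two-genre corpus
    and simulated-rater generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
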