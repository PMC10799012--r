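Package: onscore
Title: Hierarchical Athlete Ratings from Box-Score Composites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage rating of athletes observed repeatedly within a
    team/season hierarchy. Stage one builds a per-game composite score from
    box-score responses via coefficient-of-variation adjusted
    standardisation and an eigenvalue-weighted principal component
    combination. Stage two models the composite with a three-level
    random-intercept mixed model fitted by REML, from which the package
    derives intraclass correlations, BLUP-based consistency scores with
    Monte-Carlo empirical-Bayes intervals, median relevance scores with
    Wilcoxon signed-rank confidence intervals, ranking tables, and two
    systematic validation schemes summarised by Lin's concordance
    correlation coefficient. Includes a synthetic game-log generator with
    known truth for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
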