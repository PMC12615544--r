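Package: precrastr
Title: Ordinal Response-Time Models of Motor Sequence Pre-Crastination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of preview-plus-six-click motor
    sequencing experiments in which one of six targets is withheld from a
    preview.  Encodes four ordinal planning models (slow/fast procrastination
    and slow/fast pre-crastination) as 6x6 level matrices, generates synthetic
    per-trial response-time records with the design's structure (60 trials per
    subject, six withheld-target conditions, practice trials, rare long-time
    outliers), applies the trial-exclusion rules (practice drop, 3-second
    cutoff), reduces trials to per-subject condition-by-response cell means,
    fits each model's ordered level times by exact order-constrained least
    squares (pooled adjacent violators) and by seeded Monte Carlo search,
    selects winners by adjusted R-squared, and computes the accompanying
    group statistics: exact binomial winner probabilities, paired and Welch
    t tests, repeated-measures ANOVA with Bonferroni pairwise comparisons,
    repeated-measures effect sizes, and a-priori power analysis via the
    noncentral t distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
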