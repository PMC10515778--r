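Package: SyllableSeq
Title: Sequence Statistics for Behavioral Syllables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream statistics for behavioral syllable label streams
    produced by unsupervised pose-dynamics segmentation (e.g. motion
    sequencing of depth video). Provides run-length representations of
    frame-level syllable labels, usage fractions, group-pooled bigram and
    trigram transition-probability tables, animal-level bootstrap inference
    (usage z-tests with Benjamini-Hochberg FDR, confidence-interval overlap
    comparisons), Monte Carlo randomization detection of above-chance
    n-grams, and a scaled summed-difference statistic quantifying
    dose-dependent pharmacological rescue of mutant transition structure.
    Also implements the classical behavioral endpoints used alongside
    syllable analysis (novel-object discrimination indices with exclusion
    rules, freezing percentages, open-field binning, two-way type-III ANOVA
    with Welch/Holm-Sidak post-hoc tests) and a semi-Markov cohort simulator
    with genotype perturbations and dose-dependent rescue for validating
    every inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    car,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
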