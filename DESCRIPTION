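Package: screenrank
Title: Rank-Sum Statistics for Pooled FACS-Reporter and Resistance CRISPR Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled sorted-gate reporter degradation screens and
    drug-resistance CRISPR screens: per-sample read normalization, per-replicate
    stable/unstable (or drug/DMSO) enrichment ratios, median-of-median gene fold
    changes, summed-rank statistics, and two-sided empirical p-values from a
    simulated random-rank null. Includes the alanine-scanning variant of the
    pipeline (sub-library concatenation, one feature per variant), reporter
    dose-response quantification (four-parameter log-logistic fits yielding DC50
    and Dmax, LOESS display curves), closed-form biochemical assay metrics
    (TR-FRET 520/490 ratio with hook-peak localization, intact-MS labeling
    efficiency), and seeded synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
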