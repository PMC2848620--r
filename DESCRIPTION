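Package: regsync
Title: Regional Gene Synchrony Analysis for Paired-Tissue Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Genewise cross-region correlation ("gene synchrony") analysis for
    expression matrices measured in two tissues of the same subjects.
    Implements bootstrapped Pearson correlation with percentile confidence
    intervals, a permutation null that scrambles the subject linkage across
    regions, per-resample linear age detrending, and detection of group-wise
    gains and losses of synchrony with percentile-bootstrap p-values and
    Benjamini-Hochberg false discovery rate control. Includes a synthetic
    paired-cohort generator with known per-gene correlation structure, age
    confounding and group-specific rewiring, so every inferential stage can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
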