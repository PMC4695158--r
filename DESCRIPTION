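Package: mirscreen
Title: Proteomics-Driven Screening of MicroRNA Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for SILAC-based quantitative proteomic screening of
    microRNA targets. Aggregates peptide-level light/heavy ion-chromatogram
    areas into per-protein log2 fold changes with outlier rejection and
    cross-algorithm concordance checks, merges replicate significance with a
    combined p-value and applies a candidate filter cascade, scans 3'UTR
    sequences for miRNA seed-complementary binding sites with surrogate or
    externally supplied site scores, mines miRNA target clusters by
    intersecting per-gene binder sets, and computes global pairwise
    alignments (affine gaps, free end gaps) for isoform-divergence analysis.
    A synthetic-data generator with known ground truth makes the whole
    pipeline testable without access to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
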