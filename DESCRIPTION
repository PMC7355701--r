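Package: tp53axis
Title: Case-Control Association and Gene-Gene Interaction Analysis of
    TP53-Axis Variants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Association analysis of candidate variants in the p53
    regulatory axis (TP53, MDM2, MDM4) in a case-control design: logistic
    regression under the codominant, dominant, recessive and overdominant
    inheritance codings with Benjamini-Hochberg correction across codings;
    Hardy-Weinberg testing and two-locus linkage disequilibrium (D') via an
    EM haplotype-frequency estimator for unphased genotypes; pairwise
    epistasis likelihood-ratio matrices; a from-scratch model-based
    multifactor dimensionality reduction (MB-MDR) procedure for binary
    outcomes with max-Wald permutation correction; categorical clinical-
    feature testing with post-hoc contrasts; and a synthetic case-control
    cohort generator (haplotype-level linkage disequilibrium,
    inbreeding-coefficient departures from Hardy-Weinberg equilibrium, and
    a logistic disease model with main-effect and interaction terms) so the
    whole pipeline is testable without individual-level patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
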