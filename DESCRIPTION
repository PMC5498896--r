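Package: pgtqpcr
Title: PCR-Based Preimplantation Genotyping from Whole-Genome-Amplified Embryo Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for rapid PCR-based preimplantation genetic
    testing of whole-genome-amplified (WGA) single-cell embryo biopsies.
    Implements melting-curve sex determination from the Y-linked markers SRY
    and DYS14 (the GSD index, with logistic-regression category
    probabilities), amelogenin (AMELX/AMELY) fragment-length sex typing with
    peak-height and X/Y-ratio cutoffs, and delta-Ct calling of Trisomy 18 and
    Trisomy 21 from RPL17 and TTC3 with standard-curve quality control.
    Includes a synthetic single-cell WGA cohort simulator (allele drop-out,
    false alleles, copy-number-dependent Ct distortion) and a
    diagnostic-evaluation suite (confusion matrices, Cohen's kappa, odds
    ratios with Woolf intervals, Mann-Whitney AUC with Hanley-McNeil
    intervals, Youden-optimal cutoffs, and allele drop-out / false-allele
    rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
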