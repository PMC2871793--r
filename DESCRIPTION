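Package: castebias
Title: Dual-Omics Caste-Bias Analysis for Haplodiploid Wasp Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for detecting developmental caste
    bias in primitively eusocial wasp larvae from candidate-gene qPCR and
    label-free spectral-count proteomics. Provides haplodiploid microsatellite
    sexing; absolute qPCR quantification against a genomic standard curve with
    reference-gene normalization; exact and tie-corrected Mann-Whitney U,
    one-way ANOVA and Pearson correlation implemented from first principles;
    a resampling-based (min-p) family-wise error correction; correlation-based
    feature pruning with linear discriminant analysis and leave-one-out
    cross-validation; spike-in and total-count normalization of spectral
    counts with replicate-presence filtering and target-decoy FDR; and a
    synthetic-data generator emulating the statistical structure of the study
    design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
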