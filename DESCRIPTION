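Package: pipesim
Title: Ground-Truthed Simulation of the Label-Free LC-MS Proteomics Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A seedable, ground-truthed simulator of the label-free liquid
    chromatography mass spectrometry (LC-MS) proteomics workflow. Generates
    two-class protein concentration profiles with Gamma marginals and
    block-correlated Gaussian sample variation, digests proteins in silico
    into tryptic peptides, maps concentrations to peptide ion abundances with
    per-peptide efficiency, instrument response and detector saturation,
    corrupts them with signal-dependent Gaussian noise, and simulates MS1
    feature detection (SNR- and overlap-dependent true positive rate) and MS2
    identification (per-peptide Bernoulli identifiability with replicates).
    Observed peptides are rolled up to protein estimates through uniqueness,
    missing-value and correlation filters, and evaluated by quantification
    error, differential-expression recovery and KNN/LDA classification error.
    A configuration-driven driver reproduces parameter sweeps (efficiency,
    sample size, instrument response, saturation, noise, detection algorithm,
    mass resolution, MS2 replication) with replicate runs and tidy summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    class,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
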