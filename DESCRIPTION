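Package: lbqc
Title: Quality Control and In Silico Decontamination for Low-Biomass 16S rRNA Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control, denoising and negative-control-based
    decontamination of 16S rRNA gene OTU tables from low microbial biomass
    specimens (nasopharyngeal swabs, induced sputum, and similar). Implements
    spurious-OTU removal, a qPCR biomass gate, identification of potential
    contaminants by presence in no-template controls and by a frequency/
    prevalence statistical classifier, max-proportion subtraction, mock-community
    evaluation, technical-replicate reproducibility, compositional statistics
    (zero replacement, ilr pivot coordinates, ANOVA with Tukey intervals),
    Bray-Curtis/PCoA/PERMANOVA/complete-linkage beta diversity, and a
    truth-labelled synthetic cohort generator with biomass-dependent
    contamination, well-to-well spill-over, kit lysis bias and technical repeats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
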