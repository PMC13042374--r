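Package: freesv
Title: Fragmentomic and Epigenomic Examination of Somatic Variants in Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens candidate somatic variants from low-pass cell-free DNA
    (cfDNA) pileups without matched germline genotypes, quantifies
    tumor-associated mutational-signature contributions against a
    control-derived background panel by non-negative least-squares
    refitting, computes allele-aware fragmentomic and CpG-methylation
    statistics contrasting variant-carrying (Mut-DNA) against
    reference-carrying (Wt-DNA) fragments, and integrates the resulting
    features into a gradient-boosted cancer classifier evaluated under
    repeated nested cross-validation. A seeded synthetic-cohort generator
    produces toy genomes, nucleosome tracks, fragment sets and ground-truth
    manifests so the entire pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    readr,
    stringr,
    ggplot2,
    Biostrings,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
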