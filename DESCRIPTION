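Package: synwheat
Title: Multi-Breed Genetic Evaluation for Synthetic Hexaploid Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pedigree-based prediction of breeding values in synthetic
    hexaploid wheat (SHW) and its backcross derivatives, where crosses
    involve parents of variable ploidy (diploid Aegilops tauschii,
    tetraploid Triticum turgidum, hexaploid T. aestivum).  Partitions
    additive genetic variance by breed of origin using partial numerator
    relationship matrices built by a ploidy-aware tabular method,
    including segregation variance components, and estimates variance
    components and breeding values with a conjugate Gibbs sampler for a
    hierarchical Bayesian mixed model with fixed environment effects and
    iid genotype-by-environment interaction.  Includes a synthetic-data
    generator emulating multi-location wheat yield trials and a
    gene-dropping Monte-Carlo oracle for relationship coefficients.
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
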