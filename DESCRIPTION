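Package: crossvc
Title: Variance Components and Single-Step Genomic Evaluation for Composite Cattle Populations
Version: 0.1.0
Authors@R: person("GMAB", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Tools for genetic evaluation of composite (multi-breed) beef cattle
    populations: pedigree relationship-matrix algebra (numerator relationship
    matrix, its sparse inverse, inbreeding by the Meuwissen-Luo algorithm),
    Dickerson crossbreeding covariates (combined and specific heterosis and
    recombination), SNP quality control and VanRaden genomic relationship
    matrices with single-step H-inverse assembly, average-information REML for
    single-trait animal models under five fixed-effect parameterisations,
    model comparison by AIC/BIC/likelihood-ratio tests, and forward validation
    with the Legarra-Reverter LR method (accuracy, dispersion, bias).  Includes
    a gene-dropping simulator of composite populations so the whole pipeline is
    testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
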