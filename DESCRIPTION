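Package: gxesim
Title: Simulation of Two-Locus Gene-Gene and Gene-Environment
    Interactions in Case-Control Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates case-control populations in which the risk of a
    complex disease is driven by two bi-allelic disease-predisposing
    loci and one continuous environmental exposure.  Disease risk is
    modelled with a multi-logistic model (one logistic risk curve in
    exposure per combined two-locus genotype) whose coefficients are
    derived from standard epidemiological inputs: disease prevalence,
    genotypic relative risks, dominance weights, and the per-unit odds
    ratio of the environmental factor.  Epistasis is expressed as
    percentage deformations of the combined-genotype penetrance matrix
    under constraints that preserve single-locus marginal risks and
    overall prevalence.  Includes a block-structured haplotype
    generator with tunable linkage disequilibrium, case-control
    subsampling, tabular writers for phased and genotype-coded output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
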