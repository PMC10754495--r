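Package: ednaident
Title: Individual Identification from Environmental DNA Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies which individuals of an intensively monitored wild
    population contributed DNA to an environmental sample. Soil-derived phased
    variant calls are matched exactly, by position and alleles, against a
    population-wide variant callset; phase blocks are assembled into haplotypes,
    retained only when carried by at least one reference individual, and scored
    as per-individual haplotype agreement percentages. Individual contributions
    are then quantified two ways: a Dirichlet-categorical mixture fitted by
    Gibbs sampling yields posterior mixing proportions and per-haplotype
    assignment probabilities, and a combinatorial maximum-likelihood search over
    individual combinations estimates how many (and which) individuals
    contributed. A synthetic-data generator simulates population callsets (minor
    allele frequency spectrum, genotype missingness, parent-offspring relatives)
    and soil samples drawn from weighted contributor mixtures with per-site
    error and alien haplotypes, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
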