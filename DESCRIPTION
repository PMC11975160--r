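Package: herdsim
Title: Stochastic Simulation of Sheep Breeding Programmes with Genomic Selection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of a herdbook sheep
    breeding nucleus with a two-trait additive breeding goal (a low-heritability
    health trait and a moderately heritable production trait). Founder genomes
    with a realistic allele-frequency spectrum and linkage-disequilibrium
    structure are built by mosaic copying of ancestral haplotypes; breeding
    cycles include reproduction with age-structured culling, two-stage
    truncation selection and genetic evaluation by multi-trait pedigree BLUP or
    single-step GBLUP (H-matrix) mixed-model equations. An experiment layer
    runs genotyping-strategy scenarios with common random numbers and
    summarises genetic gain, estimated-breeding-value accuracy, pedigree
    kinship and marker heterozygosity with paired significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
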