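Package: hybridmap
Title: Sex-Specific Recombination Maps from Low-Coverage Sequencing of
    Hybrid F2 Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds sex-specific genetic linkage maps from shallow
    whole-genome sequencing of F2 progeny of a three-strain nematode
    double cross (CA/WA male x CA/LR hermaphrodite F1 hybrids).
    Selects strain-diagnostic biallelic sites from parental genotype
    tables, calls four-way genotypes in non-overlapping 100 kb blocks
    from diagnostic-allele depth fractions, phases crossovers to the
    male or hermaphrodite F1 parent, assembles Marey maps with
    selectable mapping functions, and tests blocks for segregation
    distortion with gradient and inheritance-bias diagnostics.  A
    parameterised meiosis simulator (obligate crossover, arm-biased
    crossover placement, XX/XO sex chromosomes, viability selection,
    Poisson read sampling) generates complete synthetic inputs so the
    pipeline can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
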