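Package: culexkdr
Title: Dual-Probe RT-qPCR Genotyping and Resistance Statistics for the
    Culex kdr L1014F Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for allelic-discrimination RT-qPCR genotyping of the
    L1014F knockdown-resistance (kdr) mutation in the voltage-gated sodium
    channel of Culex mosquitoes, and for the downstream resistance
    statistics used in insecticide-resistance surveillance. Includes the
    delta-CT statistic with final-cycle fallback, one-dimensional k-means
    and species-specific threshold-band genotype calling, in-silico
    evaluation of primers and probes against cDNA templates, resistance
    allele frequencies with binomial standard errors, exact and Monte-Carlo
    Fisher tests on r x c tables, a proportional-odds (cumulative-logit)
    ordinal regression fitted by maximum likelihood with Wald odds ratios,
    CDC bottle-bioassay knockdown metrics, haversine-based merging of trap
    sites, and a seeded synthetic-data generator that emulates the
    statistical structure of plate, survey and bioassay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    geosphere,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    MASS,
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
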