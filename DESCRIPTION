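Package: snpcore
Title: Minimal SNP Marker Panels for Germplasm Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects a minimal core set of biallelic SNP markers from a
    genome-wide genotype matrix such that every pair of samples is
    distinguished, using a greedy Shannon-diversity search with a
    haplotype-count skip rule, linked- and monomorphic-marker exclusion,
    and a missing-data recovery pass that guarantees a configurable
    minimum number of observed marker differences per sample pair.
    Includes the population-genetic summaries used to characterise core
    sets (minor allele frequency, polymorphism information content,
    Shannon index, identity-by-state, pairwise linkage-disequilibrium
    r-squared), evaluation tools (discrimination saturation curves, a
    random-selection baseline, Mantel tests between distance matrices),
    a synthetic genotype generator for testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
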