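Package: sweepOrigins
Title: Coalescent Tests of Selection, Parallel Mutational Origins, and
    Linkage Signatures of Herbicide-Resistance Alleles
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying repeated evolution of target-site
    herbicide-resistance mutations from genealogies and phased
    haplotypes. Implements order-of-coalescence tests of non-neutral
    allele-frequency change with a hypergeometric descendant-count null,
    clustering of carrier haplotypes into independent mutational
    origins with monophyly support and allele-age estimation across
    genealogy samples, effective-population-size trajectory summaries
    and allele-age rescaling, signed linkage-disequilibrium scans with
    matched-pair and individual-label permutation nulls, haplotype-based
    sweep statistics (EHH, XPEHH, pairwise diversity, H12), and seeded
    coalescent simulators (neutral, selective sweep, multi-origin) that
    generate every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phytools,
    vcfR,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
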