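Package: bsmethyl
Title: Bisulfite Methylome Simulation, Mapping and Anchored Motif Discovery
Version: 0.1.0
Authors@R:
    person("bsmethyl", "developers", email = "bsmethyl@example.org",
           role = c("aut", "cre"))
Description: Tools for bacterial 5-methylcytosine (m5C) methylome analysis by
    bisulfite sequencing, built around GC-rich linear chromosomes such as that
    of Streptomyces coelicolor. Includes an in-silico bisulfite read simulator
    with full per-site ground truth (planted, motif-anchored methylation in
    gene upstream regions plus configurable background methylation by
    CG/CHG/CHH context), a reduced-alphabet seeded bisulfite read mapper, a
    binomial non-conversion methylation caller with FDR control and cytosine
    context classification, fixed-window chromosome methylation profiles,
    strand-aware upstream-region intersection, and methylation-anchored
    consensus-motif discovery. A single-command pipeline ties the stages
    together with reproducible seeding and a checksum manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
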