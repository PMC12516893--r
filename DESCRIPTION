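Package: tillseq
Title: TILLING-by-Sequencing Mutation Discovery in Tridimensional Amplicon Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reverse-genetics mutation discovery for TILLING-by-sequencing
    (TbyS) screens of EMS-mutagenized populations pooled on a tridimensional
    (row/column/depth) grid. Provides the pooling-scheme constructor and
    pool-intersection deconvolution, a pooled amplicon read simulator with a
    dual-haplotype reference generator and spiked EMS mutations, a
    dual-reference seed-anchored read assigner with per-pool allele-count
    pileups, a low allele-fraction exact-binomial mutation caller restricted
    to the EMS G:C>A:T spectrum, codon-level effect annotation and
    platform-level statistics (mutation frequency, detection accuracy),
    and conversion of confirmed SNPs to allele-specific PCR (PACE/KASP)
    marker designs with segregation-ratio testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
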