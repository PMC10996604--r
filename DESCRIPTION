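Package: endosym
Title: Endosymbiont Titer, Strain Competition, and Recombination Analysis
    from Sequencing Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying intracellular symbiont (e.g. Wolbachia)
    dynamics in host cell culture from whole-genome sequencing. Computes
    exact k-mer mappability tracks over composite host+symbiont reference
    genomes, estimates per-sample genomic titer from mean read depth at
    uniquely mappable sites, fits the haploid chemostat selection model to
    strain-frequency time series by log-ratio regression, detects candidate
    inter-strain recombinant read pairs, estimates host-cell growth rates
    and weekly titer fold changes by log-linear regression, and plans
    mixed-culture experiments. Ships a synthetic-data generator (composite
    genomes, tiling or random read alignments, competition trajectories,
    titer and cell-count series) with known ground truth so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
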