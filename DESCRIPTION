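Package: rtscan
Title: Genome-Wide Detection of Ribosome Termination Structures from mRNA
    Folding-Energy Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans bacterial genomes for ribosome termination structures
    (RTS): stable mRNA secondary structures immediately downstream of stop
    codons that insulate operonic genes against translation re-initiation.
    Computes sliding-window minimum-free-energy landscapes around stop
    codons, a local folding-bias statistic (delta-LFE) against a
    synonymous-codon-shuffle null model, a rule-based RTS caller with
    gene-pair and operon topology stratification, synthetic-operon
    reporter-library calculations, exact small-n Spearman rank statistics,
    and a synthetic-genome generator with planted hairpins for ground-truth
    benchmarking. Folding energies come from ViennaRNA's RNAfold when
    available, with a built-in base-pair-maximization fallback engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
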