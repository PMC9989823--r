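Package: oriRT
Title: Replication Timing Profiling and Locus Proteomics of Yeast
    Replication Origins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for early-efficient versus late-inefficient
    DNA replication origins in budding yeast. Provides degenerate (IUPAC)
    consensus motif scanning of origin sequences under a mismatch budget;
    copy-number based replication-timing profiling from binned G1- and
    S-phase read counts (total-count normalisation, rolling-mean smoothing,
    low-percentile filtering, log2 S/G1 ratios); per-bin Welch differential
    replication-timing calling with region merging and centromere/origin/
    inter-origin classification; spike-in normalised qPCR recovery,
    fold-enrichment and purity arithmetic; label-free proteomic enrichment
    scoring against control purifications; and an origin-firing /
    fork-progression simulator that generates all of these inputs with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    zoo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotations-io.R'
    'binning.R'
    'differential.R'
    'motifs.R'
    'oriRT-package.R'
    'simulate.R'
    'pipeline.R'
    'proteome.R'
    'qpcr.R'
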