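Package: mitomosaic
Title: Structural Analysis of Mosaic Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the mosaic structure of plant
    mitochondrial genomes from assembly-level evidence. Provides a repeat
    census for circular genomes (direct and inverted repeats with a mismatch
    budget), depth-based classification of contigs against nuclear-encoded
    mitochondrial copies, reconstruction of a master circle by a minimal
    closed covering walk over the oriented contig graph, detection of
    repeat-mediated rearrangements from split local alignments with
    breakpoint repeat footprints and gene-proximity annotation, calling of
    chimeric fusion ORFs at rearrangement junctions (the cytoplasmic male
    sterility candidate-transcript logic), and C-to-U RNA-editing calling
    from paired genomic/RNA pileups across samples. A synthetic-genome
    simulator with machine-readable truth files generates the test
    substrate: planted repeats, recombination-derived variants,
    fragmented contigs with low-depth decoys, and planted editing sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    withr,
    generics,
    ggplot2,
    jsonlite,
    igraph,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
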