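# mitomosaic

Structural analysis of mosaic plant mitochondrial genomes in R.

Plant mitochondrial genomes are not a single tidy circle: they are riddled
with direct and inverted repeats that mediate homologous recombination,
splitting the "master circle" into coexisting subgenomic circles. In a
cytoplasmic male sterile (CMS) cytotype this mosaicism matters: a
recombination junction can fuse a novel reading frame onto the tail of an
essential gene (classically *atp9*) and produce the chimeric transcript
that sterilizes pollen. `mitomosaic` implements the assembly-level
analyses a researcher needs to characterize such a genome:

* **Repeat census** — all maximal direct/inverted repeat pairs on a
  circular genome under a mismatch budget (`find_repeats()`), summarized
  into the conventional 20–40 / 41–60 / … / >200 bp size bins
  (`summarize_repeats()`).
* **Contig classification and master-circle traversal** — depth-based
  separation of true organellar contigs from nuclear-encoded copies
  (a contig is a decoy when its depth is `< 0.10 ×` the iterated median,
  `classify_contigs()`), construction of the oriented 3′/5′ scaffold
  graph (`build_contig_graph()`), and reconstruction of the master circle
  as the minimum-length closed walk that uses every contig at least once
  (`traverse_master_circle()`, `stitch_walk()`).
* **Rearrangement detection** — per-query chaining of split local
  alignments (BLAST-outfmt-6-like tables or the built-in exact aligner):
  a query is *rearranged* when consecutive segments switch strand, invert
  subject order, or jump more than 1 kb in the subject
  (`chain_alignments()`). Each breakpoint carries its repeat footprint
  — the overlap of the two query intervals,
  `max(0, min(qe1, qe2) − max(qs1, qs2) + 1)` — gene-proximity
  annotation (`annotate_breakpoints()`), and cross-sample
  presence/absence (`compare_breakpoint_presence()`).
* **Fusion-ORF calling** — ORFs spanning a breakpoint whose peptide
  shares a long identical block with a known gene product
  (`find_orfs()`, `call_fusions()`), the CMS candidate-transcript logic.
* **C→U RNA-editing calling** — genomic-C/RNA-T sites (strand-aware:
  genomic G / RNA A inside minus-strand genes) from paired pileups across
  samples, with codon consequences, amino-acid change spectra, and
  sample-differential sites (`call_editing_sites()`,
  `annotate_editing_consequence()`, `summarize_editing()`,
  `differential_editing()`).
* **Synthetic mitogenome simulator** — circular genomes with planted
  repeats, repeat-mediated recombination (`apply_recombination()`),
  contig fragmentation with low-depth decoys, planted editing sites, and
  machine-readable truth (`simulate_master_circle()` and friends), used
  throughout the test suite.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` / `autoplot()` methods on the result objects.

## Worked example

The package ships a transcription of a published BLAST comparison between
the mitochondrial contigs of a fertile rubber tree cultivar and the master
circle of the CMS cultivar (28 alignment records, 11 query contigs):

```r
library(mitomosaic)

tab <- read_alignment_table(system.file(
  "extdata", "rrim600_vs_bpm24_blast.tsv", package = "mitomosaic"))
calls <- chain_alignments(tab)
glance(calls)
#> # A tibble: 1 × 5
#>   n_queries n_rearranged n_colinear n_unaligned n_breakpoints
#>       <int>        <int>      <int>       <int>         <int>
#> 1        11           11          0           0            13
```

All 11 contigs align to the CMS master circle in a disjointed manner —
each is a rearrangement candidate. The breakpoint of contig
AJJZ010142287.1 shows the hallmark of repeat-mediated recombination, a
101 bp repeat footprint (the two segments' query intervals [1, 612] and
[512, 1096] overlap by 101 bp):

```r
bp <- tidy(calls)
bp[bp$query_id == "AJJZ010142287.1",
   c("footprint_length", "insertion_length", "subject_left", "subject_right")]
#> # A tibble: 1 × 4
#>   footprint_length insertion_length subject_left subject_right
#>              <int>            <int>        <int>         <int>
#> 1              101                0       339054        854280
```

Annotating breakpoints against the *atp1* locus (156716–158245, minus
strand) places one junction 45 bp upstream of the start codon and the
other 28 bp before the gene end — close enough to disturb the transcript:

```r
genes <- tibble::tibble(gene_id = "atp1", start = 156716L,
                        end = 158245L, strand = "-")
ann <- tidy(annotate_breakpoints(calls, genes))
ann[which(ann$nearest_gene == "atp1")[1],
    c("query_id", "nearest_gene", "dist_to_start", "dist_to_end")]
#> # A tibble: 1 × 4
#>   query_id        nearest_gene dist_to_start dist_to_end
#>   <chr>           <chr>                <int>       <int>
#> 1 AJJZ010174367.1 atp1                    45          28
```

The simulator closes the loop: plant a repeat, recombine through it,
fragment the variant into contigs, and the pipeline recovers the planted
junctions, rebuilds the circle, and calls the planted fusion ORF and
editing sites — see the methods vignette (`vignettes/`) and
`tests/testthat/test-acceptance.R`.

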