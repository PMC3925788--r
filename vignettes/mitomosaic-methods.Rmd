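---
title: "Methods: repeat-mediated structure of plant mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-mediated structure of plant mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomosaic)
```

## The problem

Plant mitochondrial genomes recombine through their own repeats. A
"master circle" assembly is a bookkeeping device — a single circular
sequence that uses every contig at least once — while the molecule in
vivo is a mosaic of subgenomic circles at varying stoichiometry. Three
observable consequences drive the analyses in this package:

1. the scaffold graph of an assembly is not a simple cycle but a set of
   loops joined by repeat contigs;
2. a cultivar-specific recombination shows up as a *split alignment*: a
   contig from one cultivar aligning to another cultivar's master circle
   in two or more non-colinear pieces, with a copy of the recombining
   repeat (the *footprint*) at each junction;
3. junctions near or inside genes can create chimeric transcripts, the
   canonical cause of cytoplasmic male sterility (CMS), and transcripts
   are further reshaped by C→U RNA editing.

This vignette records the models, parameter choices, and numerical
decisions behind each module, and what the simulation-based tests do and
do not establish.

## Repeat census

`find_repeats()` reports every *maximal repeated pair*: two occurrences
(the second reverse-complemented for inverted pairs) matching with at
most `max_mismatches` substitutions such that extending the pair one base
in either direction would exceed the budget. Consequences of taking this
definition literally:

* With a budget of *k*, a window may begin or end immediately inside a
  blocking mismatch run; windows that *contain* a boundary mismatch but
  cannot extend are maximal and are reported. A planted exact pair with
  blocked flanks is reported exactly once with its planted coordinates.
* A pair with one interior mismatch (the classic 101 bp junction repeat
  with 1 mismatch) is one pair at `max_mismatches = 1` and two shorter
  exact pairs at `max_mismatches = 0`, whose lengths sum to 100.
* Each *unordered occurrence pair* counts once, so a three-copy repeat
  yields three pairs. A window that maps onto itself under the inverted
  mapping (a perfect palindrome) is one locus, not two occurrences, and
  is dropped.

The search seeds on exact shared k-mers and enumerates maximal
mismatch-bounded windows only on seeded (anti-)diagonals. The seed length
`max(4, min(20, floor((min_length − k) / (k + 1))))` makes the seeding
lossless by pigeonhole: any window of length ≥ `min_length` with ≤ k
mismatches contains an exact run at least that long. One code path serves
all genome sizes; the exhaustive all-diagonals enumeration exists only as
the independent oracle in the test suite, which checks set equality on
hundreds of small random genomes with planted pairs.

`summarize_repeats()` bins pairs at 20–40, 41–60, 61–80, 81–100, 101–200
and >200 bp. Percent-genome counts each pair's length once (one copy per
pair, overlaps not collapsed); this is one of several defensible
conventions, so the pair list itself is always returned for recomputation.
Circularity is honoured throughout: matches may run through the origin,
and coordinates beyond the genome length wrap.

## Contig classification and the master circle

Nuclear-encoded copies of mitochondrial sequence assemble at a small
fraction of the organellar read depth but similar GC content, so depth is
the sole classifier. The reference depth is the median over all contigs,
re-computed once after discarding contigs below `threshold × median`;
a contig is a `nuclear_copy` when its depth is *strictly* below
`threshold × reference` (default threshold 0.10). GC content is recorded
but never used.

The master circle is formalized as the **minimum-length closed covering
walk** on the oriented contig graph: nodes are contigs with 3′ and 5′
ends, edges join specific ends, a `+` step enters at 5′ and exits at 3′.
"Use every contig at least once" does not determine a unique objective,
so minimality plus a deterministic tie-break (lexicographically smallest
contig-id/orientation sequence, starting from the smallest id in `+`)
was chosen for testability. The search is iterative-deepening DFS with
memoized dead ends, adequate for graphs of tens of nodes; a search cap of
`2 × n + 4` steps bounds pathological inputs. An independent validator
(`validate_walk()`), sharing no code with the search, re-checks coverage
and edge consistency of every emitted walk. A disconnected graph is
reported as its components — biologically, independent subgenomic
circles — rather than forced into one walk.

`count_configurations()` counts distinct minimal closed covering walks up
to rotation and reflection, with an early stop at a cap. This is one
precise reading of "how many configurations does the graph admit"; walks
that differ only in the traversal direction of a reversible loop count
separately, since they stitch different molecules.

## Rearrangement detection

Split alignments come either from the 7-column tabular dialect (query id,
percent identity, alignment length, query start/end, subject start/end,
optional e-value; minus strand encoded by subject start > end) or from
the built-in exact seed-and-extend aligner on circular subjects.
E-values are accepted on input but never computed; the internal aligner
filters by length instead.

`chain_alignments()` sorts each query's segments by query start and calls
the query **rearranged** if any consecutive pair switches strand, inverts
subject order, or jumps more than `max_colinear_gap = 1000` bases in the
subject. The 1 kb default matches the gene-proximity window used
downstream; there is no natural threshold in between desk-scale cases,
which sit either below ~1 kb (colinear gaps) or in the hundreds of kb
(true rearrangements). Two filters precede chaining: segments shorter
than 50 bp are ignored (real split alignments at this scale are ≥ 88 bp
aligned; 50 leaves headroom), and segments whose query interval is
contained in another's are dropped as repeat-induced secondary matches —
without this, each recombination footprint would spawn spurious
duplicate segments.

Each breakpoint records the query-interval overlap of its two segments
(`footprint_length`) or gap (`insertion_length`); exactly one can be
positive. On a simulated recombinant the footprint equals the length of
the recombining repeat, which is the hallmark the analysis looks for.
`annotate_breakpoints()` reports, for the nearest gene within 1 kb,
strand-aware distances: `dist_to_start` is how far the flanking segment
extends upstream of the start codon in gene orientation, `dist_to_end`
how far short of the gene end it stops. Cross-sample matching merges
breakpoints whose junction coordinates agree within 50 bp — footprints of
up to ~100 bp blur exact positions, and simulated junctions land well
inside this radius.

## Fusion ORFs

`find_orfs()` scans all six frames for ATG-initiated ORFs closed by a
stop codon (TAA/TAG/TGA, standard code — plant mitochondria use the
standard code for these), one ORF per stop anchored at its 5′-most ATG.
`call_fusions()` extracts ±500 bp around each breakpoint, keeps ORFs that
span the junction, and compares their peptides to known gene products by
*ungapped exact-block* matching: a recombination-derived chimera is
identical to its donor over the retained region by construction, so a
substitution matrix would only add noise. The longest identical block
must reach 15 residues (shorter blocks are dominated by chance at desk
scale); its position in the gene peptide classifies the call as
amino-terminal, carboxyl-terminal, internal, or complete.

## RNA editing

A site is called from paired pileups when the genomic consensus is a
cytidine — at least 90% of ≥ 10 genomic reads — and the RNA shows the
edited base at fraction ≥ 0.1 with depth ≥ 10 in at least one sample.
Inside annotated minus-strand genes the same event reads as genomic G /
RNA A on the reference strand; positions outside genes are tested on the
plus strand only. These thresholds are pragmatic defaults, not published
constants, and all are arguments. Only C→U (and its strand mirror) is
ever called. Consequences substitute T at the edited codon position in
gene orientation and translate both codons; stop creation is flagged.
`differential_editing()` lists sites edited in every non-focal sample
but not the focal one — the pattern that singles out a sterile cytotype.

## The simulator and what the tests show

`simulate_master_circle()` and its companions generate the study
conditions the analyses assume, at desk scale:

* i.i.d. uniform background sequence (no base-composition model is
  targeted; repeat statistics are the only structural signal);
* planted repeat pairs — by default a 101 bp direct pair with one
  interior mismatch, a 300 bp inverted pair, and a 45 bp direct pair —
  with the single flanking base of each copy forced to mismatch, so
  planted truth equals maximal-repeat output exactly;
* non-overlapping single-exon genes (ATG + non-stop codons + stop) on
  random strands;
* per-contig depths uniform over 0.6–1.8 × the mean (a three-fold
  spread), decoy contigs re-emitted at 0.3–0.95 × the nuclear depth
  ratio (default 0.08) times the mitochondrial median, safely under the
  10% classification threshold;
* planted C→U sites on coding-strand cytidines, edited at a binomial
  fraction (default 0.8) per RNA sample, with optional per-sample
  omissions for differential designs;
* truth files for every planted feature; coordinates are 1-based
  inclusive and planted features never span the origin (analysis inputs
  may — only the truth is normalized, which keeps oracles simple).

One integer seed drives a single RNG stream; features are drawn in
documented order (background, repeats, genes, fragmentation, decoys,
pileups), and identical configurations produce byte-identical output.
The fusion-case generator writes an in-frame stop immediately before the
novel cassette's ATG so that the fusion ORF's start — and hence the
reported peptide length — is deterministic rather than dependent on
chance upstream ATGs.

Test problem sizes: oracle equivalence on 200 random genomes of 150–500
bp; 50 simulated recombinant genomes of 8 kb for walk reconstruction;
20 recombinants of 12 kb for junction recovery; 30 planted editing sites
at depth 50; 10 fusion seeds. These sizes exercise every code path while
keeping the whole suite in the minutes range.

What passing these tests does **not** show: performance on real
pyrosequencing assemblies (homopolymer errors, uneven coverage,
chimeric contigs), repeats with indels (the census is
substitution-only), genomes whose scaffold graphs are too tangled for
exact search, partial-editing quantification, or any property of the
specific organism the printed tables describe beyond those tables
themselves.

## Known limitations

* The aligner is exact and ungapped; diverged or gapped homology should
  come in through the tabular interface from an external aligner.
* Genes are modelled single-exon; trans-spliced and multi-exon genes
  must be pre-flattened to CDS intervals before consequence annotation.
* The walk search is exponential in the worst case; the cap and
  memoization make it practical for organellar-scale graphs only.
* `compare_breakpoint_presence()` uses greedy single-linkage clustering;
  pathological breakpoint clouds spaced just at the merge radius can
  chain sites that should stay separate.
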