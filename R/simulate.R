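#' Configuration for the synthetic mitogenome simulator
#'
#' Bundles and validates every knob of the simulator. The defaults emulate
#' the statistical structure the downstream analyses assume at desk scale:
#' a circular genome carrying planted direct/inverted repeats (one of them
#' the classic 101 bp pair with a single mismatch), ORF-bearing genes, a
#' roughly three-fold spread of contig read depths, low-depth
#' nuclear-encoded decoy contigs at well under 10% of the mitochondrial
#' depth, and heavily (but not completely) edited C-to-U sites.
#'
#' @param genome_length Circle length in bases.
#' @param repeats Tibble with `length`, `orientation`
#'   (`"direct"`/`"inverted"`) and `mismatches` per planted repeat pair.
#' @param n_genes Number of planted single-exon genes.
#' @param gene_length_range Min/max gene length in bases (rounded to whole
#'   codons including the stop).
#' @param contig_break_rate Per-base probability of a contig boundary.
#' @param nuclear_copy_fraction Fraction of contigs re-emitted as low-depth
#'   nuclear-copy decoys.
#' @param depth_mean Mean mitochondrial read depth.
#' @param nuclear_depth_ratio Decoy depth as a fraction of the
#'   mitochondrial median (must be < 1; default 0.08, under the 10%
#'   classification threshold).
#' @param editing_sites Number of planted C-to-U editing sites.
#' @param editing_fraction Fraction of RNA reads edited at a planted site.
#' @param rna_error_rate Uniform per-read substitution error rate in the
#'   pileups.
#' @param seed Integer seed; one stream drives all stochastic steps in
#'   documented order (background, repeats, genes, fragmentation, decoys,
#'   pileups).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 20000L,
                       repeats = tibble::tibble(
                         length = c(101L, 300L, 45L),
                         orientation = c("direct", "inverted", "direct"),
                         mismatches = c(1L, 0L, 0L)
                       ),
                       n_genes = 8L,
                       gene_length_range = c(300L, 900L),
                       contig_break_rate = 8e-4,
                       nuclear_copy_fraction = 0.15,
                       depth_mean = 50,
                       nuclear_depth_ratio = 0.08,
                       editing_sites = 30L,
                       editing_fraction = 0.8,
                       rna_error_rate = 0,
                       seed = 1L) {
  if (is.null(repeats)) {
    repeats <- tibble::tibble(length = integer(), orientation = character(),
                              mismatches = integer())
  }
  stopifnot(
    genome_length > 0,
    nrow(repeats) == 0 || genome_length > 2 * max(repeats$length),
    all(repeats$orientation %in% c("direct", "inverted")),
    all(repeats$mismatches >= 0),
    n_genes >= 0,
    length(gene_length_range) == 2, gene_length_range[1] >= 9,
    gene_length_range[1] <= gene_length_range[2],
    contig_break_rate >= 0, contig_break_rate <= 1,
    nuclear_copy_fraction >= 0, nuclear_copy_fraction <= 1,
    depth_mean > 0,
    nuclear_depth_ratio >= 0, nuclear_depth_ratio < 1,
    editing_sites >= 0,
    editing_fraction >= 0, editing_fraction <= 1,
    rna_error_rate >= 0, rna_error_rate <= 1
  )
  structure(list(
    genome_length = as.integer(genome_length), repeats = repeats,
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    contig_break_rate = contig_break_rate,
    nuclear_copy_fraction = nuclear_copy_fraction,
    depth_mean = depth_mean, nuclear_depth_ratio = nuclear_depth_ratio,
    editing_sites = as.integer(editing_sites),
    editing_fraction = editing_fraction,
    rna_error_rate = rna_error_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# sample a start for a feature of given length, avoiding occupied intervals
# (2 bp margin keeps extension-blocking flanks clear of other features);
# truth coordinates never span the origin
place_feature <- function(len, n, occupied, tries = 1000L) {
  for (i in seq_len(tries)) {
    start <- sample.int(n - len - 4L, 1L) + 2L
    end <- start + len - 1L
    clash <- any(start - 2L <= occupied$end + 2L &
                   end + 2L >= occupied$start - 2L)
    if (!clash) return(start)
  }
  stop("simulate_master_circle: could not place a ", len,
       " bp feature without overlap (placement failure)", call. = FALSE)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# force s[pos] to differ from `avoid` (blocks repeat extension past a flank)
block_base <- function(chars, pos, avoid) {
  if (chars[pos] == avoid) {
    chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
  }
  chars
}

NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA")
)

#' Generate a master circle with planted repeats and genes
#'
#' Builds a circular genome of i.i.d. uniform background sequence, writes
#' in the configured repeat pairs (the second copy reverse-complemented for
#' inverted pairs, with the configured number of interior substitutions)
#' and non-overlapping ORF-bearing genes on random strands, and records the
#' ground truth. The single base flanking each repeat copy is set to break
#' the match, so a planted pair is also the maximal repeat at its locus.
#' Output is byte-identical for a fixed config (including seed).
#'
#' @param config A [sim_config()].
#' @return A `sim_mitogenome` list: `genome` ([circular_genome()]), `genes`
#'   (tibble `gene_id`, `start`, `end`, `strand`, `peptide`), and `truth`
#'   (list with `planted_repeats`, `planted_junctions`, `planted_editing`,
#'   `contig_origins`).
#' @export
simulate_master_circle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$genome_length
  withr::with_seed(config$seed, {
    chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    occupied <- tibble::tibble(start = integer(), end = integer())

    planted <- config$repeats
    planted$start1 <- NA_integer_
    planted$start2 <- NA_integer_
    if (nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        L <- planted$length[i]
        unit <- strsplit(random_dna(L), "", fixed = TRUE)[[1]]
        copy2 <- if (planted$orientation[i] == "inverted") {
          strsplit(revcomp(paste(unit, collapse = "")), "", fixed = TRUE)[[1]]
        } else {
          unit
        }
        m <- planted$mismatches[i]
        if (m > 0L) {
          at <- sample(seq.int(2L, L - 1L), m)
          for (p in at) {
            copy2[p] <- sample(setdiff(c("A", "C", "G", "T"), copy2[p]), 1L)
          }
        }
        p1 <- place_feature(L, n, occupied)
        occupied <- dplyr::bind_rows(occupied,
                                     tibble::tibble(start = p1, end = p1 + L - 1L))
        p2 <- place_feature(L, n, occupied)
        occupied <- dplyr::bind_rows(occupied,
                                     tibble::tibble(start = p2, end = p2 + L - 1L))
        if (p2 < p1) { tmp <- p1; p1 <- p2; p2 <- tmp }
        chars[seq.int(p1, p1 + L - 1L)] <- unit
        chars[seq.int(p2, p2 + L - 1L)] <- copy2
        if (planted$orientation[i] == "direct") {
          chars <- block_base(chars, p2 - 1L, chars[p1 - 1L])
          chars <- block_base(chars, p2 + L, chars[p1 + L])
        } else {
          comp1 <- chartr("ACGT", "TGCA", chars[p1 - 1L])
          chars <- block_base(chars, p2 + L, comp1)
          comp2 <- chartr("ACGT", "TGCA", chars[p1 + L])
          chars <- block_base(chars, p2 - 1L, comp2)
        }
        planted$start1[i] <- p1
        planted$start2[i] <- p2
      }
    }

    genes <- tibble::tibble(gene_id = character(), start = integer(),
                            end = integer(), strand = character(),
                            peptide = character())
    if (config$n_genes > 0L) {
      for (i in seq_len(config$n_genes)) {
        lo_aa <- max(2L, config$gene_length_range[1] %/% 3L - 1L)
        hi_aa <- max(lo_aa, config$gene_length_range[2] %/% 3L - 1L)
        n_aa <- sample(seq.int(lo_aa, hi_aa), 1L)
        len <- 3L * (n_aa + 1L)
        body <- sample(NON_STOP_CODONS, n_aa - 1L, replace = TRUE)
        cds <- paste0("ATG", paste(body, collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L))
        strand <- sample(c("+", "-"), 1L)
        start <- place_feature(len, n, occupied)
        occupied <- dplyr::bind_rows(occupied,
                                     tibble::tibble(start = start,
                                                    end = start + len - 1L))
        written <- if (strand == "+") cds else revcomp(cds)
        chars[seq.int(start, start + len - 1L)] <-
          strsplit(written, "", fixed = TRUE)[[1]]
        genes <- dplyr::bind_rows(genes, tibble::tibble(
          gene_id = sprintf("gene%02d", i), start = start,
          end = start + len - 1L, strand = strand,
          peptide = translate_dna(substr(cds, 1L, 3L * n_aa))
        ))
      }
    }

    genome <- circular_genome(paste(chars, collapse = ""), id = "sim_master")
    structure(list(
      genome = genome,
      genes = genes,
      truth = list(
        planted_repeats = planted[, c("start1", "start2", "length",
                                      "orientation", "mismatches")],
        planted_junctions = tibble::tibble(ref_start = integer(),
                                           ref_end = integer(),
                                           footprint_length = integer()),
        planted_editing = tibble::tibble(),
        contig_origins = tibble::tibble()
      ),
      config = config
    ), class = "sim_mitogenome")
  })
}

#' Apply a repeat-mediated homologous recombination
#'
#' Models a crossover between the two copies of a repeat. For an inverted
#' pair the intervening segment is reverse-complemented in place, leaving
#' one full repeat copy at each junction (the recombination footprint) and
#' the genome length unchanged; applying the same recombination twice
#' restores the original molecule. For a direct pair the circle resolves
#' into two smaller circles whose lengths sum to the original, each
#' carrying one repeat copy.
#'
#' @param genome A [circular_genome()].
#' @param rpt One-row tibble (or list) with `start1`, `start2`, `length`,
#'   `orientation` and optionally `mismatches`, as in the truth of
#'   [simulate_master_circle()] or the output of [find_repeats()].
#' @param truth Optional truth list to extend with the new junctions.
#' @return List: `genomes` (one genome for inverted pairs, two for
#'   direct), `junctions` (tibble `ref_start`, `ref_end`,
#'   `footprint_length` of each junction's repeat copy, identical in
#'   reference and, for inverted pairs, variant coordinates), and the
#'   updated `truth`.
#' @export
apply_recombination <- function(genome, rpt, truth = NULL) {
  stopifnot(inherits(genome, "circular_genome"))
  s1 <- rpt$start1; s2 <- rpt$start2; L <- rpt$length
  tol <- rpt$mismatches %||% 0L
  n <- genome_length(genome)
  e1 <- s1 + L - 1L; e2 <- s2 + L - 1L
  if (e1 >= s2 || e2 > n) {
    stop("apply_recombination: repeat copies overlap or extend past the ",
         "origin; rejected", call. = FALSE)
  }
  copy1 <- substr(genome$sequence, s1, e1)
  copy2 <- substr(genome$sequence, s2, e2)
  target <- if (rpt$orientation == "inverted") revcomp(copy1) else copy1
  mism <- sum(strsplit(target, "")[[1]] != strsplit(copy2, "")[[1]])
  if (mism > tol) {
    stop("apply_recombination: repeat not present at the stated positions (",
         mism, " mismatches, tolerance ", tol, ")", call. = FALSE)
  }
  junctions <- tibble::tibble(
    ref_start = c(s1, s2), ref_end = c(e1, e2),
    footprint_length = c(L, L)
  )
  if (!is.null(truth)) {
    truth$planted_junctions <- dplyr::bind_rows(truth$planted_junctions,
                                                junctions)
  }
  seq <- genome$sequence
  if (rpt$orientation == "inverted") {
    mid <- if (s2 - e1 > 1L) revcomp(substr(seq, e1 + 1L, s2 - 1L)) else ""
    variant <- paste0(substr(seq, 1L, e1), mid, substr(seq, s2, n))
    genomes <- list(circular_genome(variant,
                                    id = paste0(genome$id, "_inv")))
  } else {
    circ1 <- substr(seq, s1, s2 - 1L)             # copy1 + intervening
    circ2 <- paste0(substr(seq, s2, n),
                    if (s1 > 1L) substr(seq, 1L, s1 - 1L) else "")
    genomes <- list(
      circular_genome(circ1, id = paste0(genome$id, "_circleA")),
      circular_genome(circ2, id = paste0(genome$id, "_circleB"))
    )
  }
  list(genomes = genomes, junctions = junctions, truth = truth)
}

gc_fraction <- function(seq) {
  vapply(seq, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    mean(v %in% c("G", "C"))
  }, 1, USE.NAMES = FALSE)
}

#' Fragment a circular genome into contigs with scaffold links
#'
#' Cuts the circle at random positions into contigs that tile it exactly,
#' emits the 3'-to-5' scaffold links between consecutive contigs, draws
#' per-contig read depths over roughly a three-fold range, and re-emits a
#' configured fraction of contigs as nuclear-copy decoys under new ids at
#' a small fraction of the mitochondrial depth. Decoys carry no scaffold
#' links.
#'
#' @param genome A [circular_genome()].
#' @param config A [sim_config()] (break rate, depths, decoy settings).
#' @param truth Optional truth list; gains `contig_origins`.
#' @param seed Optional seed applied just for this step.
#' @return List: `contigs` (tibble `contig_id`, `sequence`, `length`,
#'   `depth`, `gc`), `links` (tibble `contig_a`, `end_a`, `contig_b`,
#'   `end_b`, `support`), and `truth`.
#' @export
fragment_to_contigs <- function(genome, config, truth = NULL, seed = NULL) {
  stopifnot(inherits(genome, "circular_genome"))
  run <- function() {
    n <- genome_length(genome)
    cuts <- which(stats::runif(n) < config$contig_break_rate)
    if (length(cuts) < 3L) cuts <- sort(sample.int(n, 3L))
    m <- length(cuts)
    starts <- cuts
    lens <- c(diff(cuts), n - cuts[m] + cuts[1])
    ids <- sprintf("ctg%03d", seq_len(m))
    seqs <- vapply(seq_len(m), function(i) {
      subseq_circular(genome, starts[i], length = lens[i])
    }, "")
    depths <- config$depth_mean * stats::runif(m, 0.6, 1.8)
    contigs <- tibble::tibble(
      contig_id = ids, sequence = seqs, length = lens,
      depth = depths, gc = gc_fraction(seqs)
    )
    links <- tibble::tibble(
      contig_a = ids, end_a = "3'",
      contig_b = ids[c(seq_len(m)[-1], 1L)], end_b = "5'",
      support = sample.int(50L, m, replace = TRUE) + 9L
    )
    origins <- tibble::tibble(
      contig_id = ids, start = starts,
      end = ((starts + lens - 2L) %% n) + 1L,
      class = "mito", source_id = NA_character_
    )
    n_decoy <- round(config$nuclear_copy_fraction * m)
    if (n_decoy > 0L) {
      pick <- sample.int(m, n_decoy)
      decoy_depth <- stats::median(depths) * config$nuclear_depth_ratio *
        stats::runif(n_decoy, 0.3, 0.95)
      decoys <- tibble::tibble(
        contig_id = sprintf("numt%02d", seq_len(n_decoy)),
        sequence = seqs[pick], length = lens[pick],
        depth = decoy_depth, gc = gc_fraction(seqs[pick])
      )
      contigs <- dplyr::bind_rows(contigs, decoys)
      origins <- dplyr::bind_rows(origins, tibble::tibble(
        contig_id = decoys$contig_id, start = starts[pick],
        end = ((starts[pick] + lens[pick] - 2L) %% n) + 1L,
        class = "nuclear_copy", source_id = ids[pick]
      ))
    }
    if (!is.null(truth)) truth$contig_origins <- origins
    else truth <- list(contig_origins = origins)
    list(contigs = contigs, links = links, truth = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# codon consequence of editing a coding-strand C to T, written directly from
# the genetic code (kept separate from the analysis-side annotator so truth
# and call are computed through different code)
sim_edit_consequence <- function(genome, gene, position) {
  offset <- if (gene$strand == "+") position - gene$start
    else gene$end - position
  codon_index <- offset %/% 3L + 1L
  codon_pos <- offset %% 3L + 1L
  cds <- substr(genome$sequence, gene$start, gene$end)
  if (gene$strand == "-") cds <- revcomp(cds)
  codon <- substr(cds, 3L * codon_index - 2L, 3L * codon_index)
  edited <- codon
  substr(edited, codon_pos, codon_pos) <- "T"
  aa1 <- unname(Biostrings::GENETIC_CODE[codon])
  aa2 <- unname(Biostrings::GENETIC_CODE[edited])
  tibble::tibble(
    codon_index = codon_index, codon_pos = codon_pos,
    ref_aa = aa1, edited_aa = aa2,
    consequence = if (aa1 == aa2) "synonymous"
      else if (aa2 == "*") "stop_gained" else "nonsynonymous"
  )
}

#' Simulate genomic and per-sample RNA pileups with planted editing sites
#'
#' Plants `config$editing_sites` C-to-U editing sites on coding-strand
#' cytidines inside genes (reference-strand G positions for minus-strand
#' genes) and emits one genomic pileup plus one RNA pileup per sample. At a
#' planted site the RNA edited-base fraction is binomial around
#' `config$editing_fraction`; everywhere else RNA matches the genome up to
#' the uniform error rate. Sites can be withheld from chosen samples to
#' model differential editing.
#'
#' @param genome A [circular_genome()].
#' @param genes Gene tibble as from [simulate_master_circle()].
#' @param config A [sim_config()].
#' @param samples Character vector of sample names.
#' @param omit Named list: `sample -> positions` at which that sample is
#'   left unedited.
#' @param seed Optional seed applied just for this step.
#' @return List: `genomic` (pileup tibble `position`, `ref_base`, `A`,
#'   `C`, `G`, `T`), `rna` (named list of pileup tibbles), and
#'   `truth_editing` (tibble of planted sites with codon consequences and
#'   an `edited_in` list-column of sample names).
#' @export
simulate_pileups <- function(genome, genes, config,
                             samples = paste0("sample", 1:6),
                             omit = list(), seed = NULL) {
  stopifnot(inherits(genome, "circular_genome"), nrow(genes) >= 1)
  run <- function() {
    n <- genome_length(genome)
    bases <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]

    cand <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      span <- seq.int(g$start, g$end)
      want <- if (g$strand == "+") "C" else "G"
      hit <- span[bases[span] == want]
      if (!length(hit)) return(NULL)
      tibble::tibble(position = hit, gene_id = g$gene_id, strand = g$strand)
    })
    if (nrow(cand) < config$editing_sites) {
      stop("simulate_pileups: requested ", config$editing_sites,
           " editing sites but only ", nrow(cand),
           " coding-strand C positions are available", call. = FALSE)
    }
    sites <- cand[sort(sample.int(nrow(cand), config$editing_sites)), ]

    make_pileup <- function(edited_positions = integer(0)) {
      depth <- stats::rpois(n, config$depth_mean)
      counts <- matrix(0L, nrow = n, ncol = 4L,
                       dimnames = list(NULL, c("A", "C", "G", "T")))
      base_col <- match(bases, c("A", "C", "G", "T"))
      counts[cbind(seq_len(n), base_col)] <- depth
      if (length(edited_positions)) {
        for (p in edited_positions) {
          k <- stats::rbinom(1L, depth[p], config$editing_fraction)
          st <- sites$strand[match(p, sites$position)]
          to <- if (st == "-") "A" else "T"
          counts[p, bases[p]] <- depth[p] - k
          counts[p, to] <- k
        }
      }
      if (config$rna_error_rate > 0) {
        errs <- stats::rbinom(n, depth, config$rna_error_rate)
        for (p in which(errs > 0L)) {
          others <- setdiff(c("A", "C", "G", "T"), bases[p])
          split_err <- stats::rmultinom(1L, errs[p], rep(1 / 3, 3))[, 1]
          counts[p, others] <- counts[p, others] + split_err
          counts[p, bases[p]] <- pmax(0L, counts[p, bases[p]] - errs[p])
        }
      }
      tibble::tibble(position = seq_len(n), ref_base = bases,
                     A = counts[, "A"], C = counts[, "C"],
                     G = counts[, "G"], T = counts[, "T"])
    }

    genomic <- make_pileup()
    rna <- purrr::map(stats::setNames(samples, samples), function(sm) {
      skip <- omit[[sm]] %||% integer(0)
      make_pileup(setdiff(sites$position, skip))
    })

    consequences <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
      sim_edit_consequence(genome,
                           genes[genes$gene_id == sites$gene_id[i], ],
                           sites$position[i])
    })
    truth <- dplyr::bind_cols(sites, consequences)
    truth$edited_in <- purrr::map(truth$position, function(p) {
      samples[!vapply(samples, function(sm) p %in% (omit[[sm]] %||%
                                                      integer(0)), TRUE)]
    })
    list(genomic = genomic, rna = rna, truth_editing = truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a gene-tail fusion at a recombination junction
#'
#' Builds a reference genome carrying one complete gene, and a variant in
#' which a junction fuses a novel in-frame cassette (ATG plus `novel_aa`
#' codons) to the last `tail_aa` codons of that gene plus its stop --
#' the structure a repeat-mediated recombination through the 3' end of a
#' gene produces, and the template for a candidate CMS fusion transcript.
#' The cassette codon abutting the junction is chosen to encode a
#' different residue than the gene's corresponding position, so the
#' identical block between the fusion peptide and the gene peptide is
#' exactly `tail_aa` residues.
#'
#' @param seed Integer seed.
#' @param genome_length Reference length in bases.
#' @param gene_aa Gene peptide length in residues.
#' @param tail_aa Retained carboxyl-terminal residues.
#' @param novel_aa Novel residues after the cassette ATG.
#' @return List: `reference` and `variant` ([circular_genome()]s), `gene`
#'   (tibble with peptide), `breakpoint` (tibble `position` on the
#'   variant), and `truth` (`tail_aa`, `fusion_peptide_aa`).
#' @export
simulate_fusion_case <- function(seed = 1L, genome_length = 6000L,
                                 gene_aa = 80L, tail_aa = 33L,
                                 novel_aa = 17L) {
  stopifnot(tail_aa < gene_aa, novel_aa >= 1, genome_length >= 5000)
  withr::with_seed(seed, {
    n <- genome_length
    ref_chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)

    body <- sample(NON_STOP_CODONS, gene_aa - 1L, replace = TRUE)
    cds <- paste0("ATG", paste(body, collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    gene_start <- 1200L
    gene_end <- gene_start + nchar(cds) - 1L
    ref_chars[seq.int(gene_start, gene_end)] <-
      strsplit(cds, "", fixed = TRUE)[[1]]
    peptide <- translate_dna(substr(cds, 1L, 3L * gene_aa))

    # cassette: ATG + novel codons; the final codon must not encode the
    # gene residue just upstream of the retained tail
    upstream_aa <- substr(peptide, gene_aa - tail_aa, gene_aa - tail_aa)
    repeat_codon <- function() sample(NON_STOP_CODONS, 1L)
    cassette_codons <- sample(NON_STOP_CODONS, novel_aa, replace = TRUE)
    while (unname(Biostrings::GENETIC_CODE[
      cassette_codons[novel_aa]]) == upstream_aa) {
      cassette_codons[novel_aa] <- repeat_codon()
    }
    # the in-frame TAA directly before the cassette ATG pins the ORF start:
    # without it a chance upstream in-frame ATG would extend the peptide
    cassette <- paste0("TAA", "ATG", paste(cassette_codons, collapse = ""))
    tail_nt <- substr(cds, 3L * (gene_aa - tail_aa) + 1L, nchar(cds))

    insert_at <- 4200L
    reference <- circular_genome(paste(ref_chars, collapse = ""),
                                 id = "fusion_ref")
    variant_seq <- paste0(
      substr(reference$sequence, 1L, insert_at - 1L),
      cassette, tail_nt,
      substr(reference$sequence, insert_at, n)
    )
    variant <- circular_genome(variant_seq, id = "fusion_variant")
    junction <- insert_at - 1L + nchar(cassette)  # last novel base

    list(
      reference = reference, variant = variant,
      gene = tibble::tibble(gene_id = "geneA", start = gene_start,
                            end = gene_end, strand = "+",
                            peptide = peptide),
      breakpoint = tibble::tibble(position = junction),
      truth = list(tail_aa = tail_aa,
                   fusion_peptide_aa = 1L + novel_aa + tail_aa)
    )
  })
}
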