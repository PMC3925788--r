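test_that("simulation is byte-identical for a fixed config", {
  cfg <- sim_config(genome_length = 6000L, n_genes = 4L, seed = 21L)
  a <- simulate_master_circle(cfg)
  b <- simulate_master_circle(cfg)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$truth$planted_repeats, b$truth$planted_repeats)
  expect_identical(a$genes, b$genes)
  c2 <- simulate_master_circle(sim_config(genome_length = 6000L, n_genes = 4L,
                                          seed = 22L))
  expect_false(identical(a$genome$sequence, c2$genome$sequence))
})

test_that("an empty feature spec gives an empty truth", {
  cfg <- sim_config(genome_length = 2000L, repeats = NULL, n_genes = 0L,
                    seed = 1L)
  sim <- simulate_master_circle(cfg)
  expect_equal(nrow(sim$truth$planted_repeats), 0L)
  expect_equal(nrow(sim$genes), 0L)
  expect_equal(genome_length(sim$genome), 2000L)
})

test_that("infeasible feature placement raises a placement-failure error", {
  cfg <- sim_config(
    genome_length = 450L,
    repeats = tibble::tibble(length = rep(100L, 3), orientation = "direct",
                             mismatches = 0L),
    n_genes = 0L, seed = 1L
  )
  expect_error(simulate_master_circle(cfg), "placement failure")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(genome_length = 150L,
                          repeats = tibble::tibble(length = 101L,
                                                   orientation = "direct",
                                                   mismatches = 0L)))
  expect_error(sim_config(nuclear_depth_ratio = 1.2))
  expect_error(sim_config(editing_fraction = -0.1))
})

test_that("planted genes carry valid ORFs", {
  sim <- simulate_master_circle(sim_config(genome_length = 8000L,
                                           n_genes = 5L, seed = 33L))
  for (i in seq_len(nrow(sim$genes))) {
    g <- sim$genes[i, ]
    cds <- substr(sim$genome$sequence, g$start, g$end)
    if (g$strand == "-") cds <- revcomp(cds)
    expect_equal(substr(cds, 1, 3), "ATG")
    pep <- translate_dna(cds)
    expect_equal(substr(pep, nchar(pep), nchar(pep)), "*")
    expect_false(grepl("\\*", substr(pep, 1, nchar(pep) - 1L)))
    expect_equal(substr(pep, 1, nchar(pep) - 1L), g$peptide)
  }
})

test_that("inverted recombination inverts the intervening segment and is an involution", {
  withr::with_seed(3, {
    g <- plant_repeat_genome(1000, 100, 500, 25, "inverted")
    rpt <- tibble::tibble(start1 = 100L, start2 = 500L, length = 25L,
                          orientation = "inverted", mismatches = 0L)
    rec <- apply_recombination(g, rpt)
    v <- rec$genomes[[1]]
    expect_equal(genome_length(v), 1000L)
    # independent string surgery: A + R1 + revcomp(X) + R2 + B
    s <- g$sequence
    expected <- paste0(substr(s, 1, 124), revcomp(substr(s, 125, 499)),
                       substr(s, 500, 1000))
    expect_identical(v$sequence, expected)
    # both junctions carry a full repeat copy
    expect_identical(substr(v$sequence, 100, 124), substr(s, 100, 124))
    expect_identical(substr(v$sequence, 500, 524), substr(s, 500, 524))
    expect_equal(rec$junctions$footprint_length, c(25L, 25L))
    # applying the identical recombination again restores the original
    back <- apply_recombination(v, rpt)
    expect_identical(back$genomes[[1]]$sequence, s)
  })
})

test_that("direct recombination resolves the circle into two summing circles", {
  withr::with_seed(4, {
    g <- plant_repeat_genome(1200, 150, 700, 30, "direct")
    rpt <- tibble::tibble(start1 = 150L, start2 = 700L, length = 30L,
                          orientation = "direct", mismatches = 0L)
    rec <- apply_recombination(g, rpt)
    expect_length(rec$genomes, 2L)
    lens <- vapply(rec$genomes, genome_length, 1L)
    expect_equal(sum(lens), 1200L)
    expect_equal(lens[1], 700L - 150L)  # copy1 + intervening segment
    # each product circle carries one full repeat copy
    unit <- substr(g$sequence, 150, 179)
    expect_true(grepl(unit, paste0(rec$genomes[[1]]$sequence,
                                   rec$genomes[[1]]$sequence), fixed = TRUE))
    expect_true(grepl(unit, paste0(rec$genomes[[2]]$sequence,
                                   rec$genomes[[2]]$sequence), fixed = TRUE))
  })
})

test_that("overlapping repeat copies are rejected", {
  g <- circular_genome(strrep("ACGT", 100))
  rpt <- tibble::tibble(start1 = 10L, start2 = 20L, length = 50L,
                        orientation = "direct", mismatches = 0L)
  expect_error(apply_recombination(g, rpt), "overlap")
})

test_that("recombination refuses a repeat that is not present", {
  withr::with_seed(8, {
    g <- random_genome(500)
    rpt <- tibble::tibble(start1 = 50L, start2 = 300L, length = 40L,
                          orientation = "direct", mismatches = 0L)
    expect_error(apply_recombination(g, rpt), "not present")
  })
})

test_that("contig fragmentation tiles the circle with a single link cycle", {
  cfg <- sim_config(genome_length = 9000L, contig_break_rate = 1e-3,
                    nuclear_copy_fraction = 0, seed = 6L)
  sim <- simulate_master_circle(cfg)
  fr <- fragment_to_contigs(sim$genome, cfg, seed = 61L)
  mito <- fr$contigs
  expect_true(all(startsWith(mito$contig_id, "ctg")))
  expect_equal(sum(mito$length), 9000L)
  # stitched in emitted order the contigs reproduce the circle
  stitched <- paste(mito$sequence, collapse = "")
  expect_true(same_circle_sequence(sim$genome$sequence, stitched))
  # links: one cycle over all contigs
  expect_equal(nrow(fr$links), nrow(mito))
  expect_equal(sort(fr$links$contig_a), sort(mito$contig_id))
  expect_equal(sort(fr$links$contig_b), sort(mito$contig_id))
  # depth spread stays within the intended three-fold band
  expect_lt(max(mito$depth) / min(mito$depth), 3.01)
})

test_that("nuclear-copy decoys sit far below the mitochondrial depth", {
  cfg <- sim_config(genome_length = 9000L, contig_break_rate = 1.5e-3,
                    nuclear_copy_fraction = 0.3, nuclear_depth_ratio = 0.08,
                    n_genes = 3L, gene_length_range = c(150L, 400L),
                    seed = 7L)
  sim <- simulate_master_circle(cfg)
  fr <- fragment_to_contigs(sim$genome, cfg, seed = 71L)
  decoys <- fr$contigs[startsWith(fr$contigs$contig_id, "numt"), ]
  mito <- fr$contigs[startsWith(fr$contigs$contig_id, "ctg"), ]
  expect_gt(nrow(decoys), 0L)
  expect_true(all(decoys$depth / median(mito$depth) < 0.08 + 0.01))
  expect_equal(nrow(fr$truth$contig_origins), nrow(fr$contigs))
  expect_setequal(
    fr$truth$contig_origins$class[match(decoys$contig_id,
                                        fr$truth$contig_origins$contig_id)],
    "nuclear_copy"
  )
})

test_that("fully edited error-free pileups are pure T at planted sites", {
  cfg <- sim_config(genome_length = 4000L, n_genes = 3L,
                    gene_length_range = c(150L, 400L), editing_sites = 10L,
                    editing_fraction = 1, rna_error_rate = 0, seed = 9L)
  sim <- simulate_master_circle(cfg)
  pl <- simulate_pileups(sim$genome, sim$genes, cfg, samples = c("s1", "s2"),
                         seed = 91L)
  expect_equal(nrow(pl$truth_editing), 10L)
  for (i in seq_len(nrow(pl$truth_editing))) {
    site <- pl$truth_editing[i, ]
    row <- pl$rna$s1[pl$rna$s1$position == site$position, ]
    edited_base <- if (site$strand == "-") row$A else row$T
    depth <- row$A + row$C + row$G + row$T
    expect_equal(edited_base, depth)
  }
  # genomic pileup is unedited everywhere
  grow <- pl$genomic[pl$genomic$position %in% pl$truth_editing$position, ]
  expect_true(all(ifelse(grow$ref_base == "G", grow$G, grow$C) ==
                    grow$A + grow$C + grow$G + grow$T))
})

test_that("sample-specific omissions are recorded in the truth", {
  cfg <- sim_config(genome_length = 4000L, n_genes = 3L,
                    gene_length_range = c(150L, 400L), editing_sites = 8L,
                    editing_fraction = 0.9, seed = 10L)
  sim <- simulate_master_circle(cfg)
  pl0 <- simulate_pileups(sim$genome, sim$genes, cfg,
                          samples = c("s1", "s2", "s3"), seed = 101L)
  skip_pos <- pl0$truth_editing$position[1:2]
  pl <- simulate_pileups(sim$genome, sim$genes, cfg,
                         samples = c("s1", "s2", "s3"),
                         omit = list(s1 = skip_pos), seed = 101L)
  for (i in seq_len(nrow(pl$truth_editing))) {
    site <- pl$truth_editing[i, ]
    if (site$position %in% skip_pos) {
      expect_false("s1" %in% site$edited_in[[1]])
      row <- pl$rna$s1[pl$rna$s1$position == site$position, ]
      edited_base <- if (site$strand == "-") row$A else row$T
      expect_equal(edited_base, 0)
    } else {
      expect_true("s1" %in% site$edited_in[[1]])
    }
  }
})

test_that("asking for more editing sites than available cytidines errors", {
  cfg <- sim_config(genome_length = 2000L, n_genes = 1L,
                    gene_length_range = c(60L, 90L), editing_sites = 500L,
                    seed = 11L)
  sim <- simulate_master_circle(cfg)
  expect_error(simulate_pileups(sim$genome, sim$genes, cfg, samples = "s1",
                                seed = 1L),
               "available")
})
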