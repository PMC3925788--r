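test_that("the alignment table dialect round-trips with strand inference", {
  tab <- read_alignment_table(table3_path())
  expect_equal(nrow(tab), 28L)
  expect_equal(length(unique(tab$query_id)), 11L)
  # plus strand when subject coordinates ascend
  r1 <- tab[tab$query_id == "AJJZ010142287.1" & tab$q_start == 1, ]
  expect_equal(r1$strand, "+")
  expect_equal(c(r1$q_start, r1$q_end), c(1L, 612L))
  # minus strand when subject start exceeds subject end
  r2 <- tab[tab$query_id == "AJJZ011005166.1" & tab$q_start == 241, ]
  expect_equal(r2$strand, "-")
  expect_equal(c(r2$s_start, r2$s_end), c(21535L, 20459L))
})

test_that("malformed alignment rows are reported with their line", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query_id\tpct_identity\talign_length\tq_start\tq_end\ts_start\ts_end\tevalue",
               "q1\t99.0\t100\t1\t100\t500\t599\t0",
               "q1\tnot_a_number\t100\t1\t100\t500\t599\t0"), p)
  expect_error(read_alignment_table(p), "line 3")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("query_id\tpct_identity\talign_length\tq_start\tq_end\ts_start\ts_end\tevalue", p2)
  expect_equal(nrow(read_alignment_table(p2)), 0L)
})

test_that("blank continuation query ids fill down", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query_id\tpct_identity\talign_length\tq_start\tq_end\ts_start\ts_end\tevalue",
               "q1\t99.0\t100\t1\t100\t500\t599\t0",
               "\t98.0\t100\t200\t299\t5000\t5099\t0"), p)
  tab <- read_alignment_table(p)
  expect_equal(tab$query_id, c("q1", "q1"))
})

test_that("breakpoint footprint and insertion are mutually exclusive overlap arithmetic", {
  expect_equal(breakpoint_footprint(1, 612, 512, 1096)$footprint_length, 101L)
  expect_equal(breakpoint_footprint(1, 7965, 7733, 9596)$footprint_length, 233L)
  gap <- breakpoint_footprint(1, 100, 200, 300)
  expect_equal(gap$footprint_length, 0L)
  expect_equal(gap$insertion_length, 99L)
  # symmetric in its arguments and never both positive
  withr::with_seed(13, {
    for (i in 1:50) {
      a <- sort(sample(1000, 2)); b <- sort(sample(1000, 2))
      f1 <- breakpoint_footprint(a[1], a[2], b[1], b[2])
      f2 <- breakpoint_footprint(b[1], b[2], a[1], a[2])
      expect_identical(f1, f2)
      expect_true(f1$footprint_length >= 0 && f1$insertion_length >= 0)
      expect_equal(f1$footprint_length * f1$insertion_length, 0L)
    }
  })
})

test_that("a single segment is colinear and zero segments are unaligned", {
  one <- tibble::tibble(query_id = "q", pct_identity = 100,
                        align_length = 300L, q_start = 1L, q_end = 300L,
                        s_start = 1000L, s_end = 1299L, evalue = 0)
  cc <- chain_alignments(one)
  expect_equal(cc$calls$classification, "colinear")
  short <- dplyr::mutate(one, align_length = 30L)
  cc2 <- chain_alignments(short)  # only segment is below min_segment
  expect_equal(cc2$calls$classification, "unaligned")
})

test_that("colinearity tolerates small same-strand subject gaps on both strands", {
  plus <- tibble::tibble(
    query_id = "p", pct_identity = 100,
    align_length = c(200L, 200L),
    q_start = c(1L, 210L), q_end = c(200L, 409L),
    s_start = c(1000L, 1600L), s_end = c(1199L, 1799L), evalue = 0
  )
  expect_equal(chain_alignments(plus)$calls$classification, "colinear")
  minus <- tibble::tibble(
    query_id = "m", pct_identity = 100,
    align_length = c(200L, 200L),
    q_start = c(1L, 210L), q_end = c(200L, 409L),
    s_start = c(5000L, 4400L), s_end = c(4801L, 4201L), evalue = 0
  )
  expect_equal(chain_alignments(minus)$calls$classification, "colinear")
  # the same minus pair with a > 1 kb subject jump is rearranged
  far <- dplyr::mutate(minus, s_start = c(5000L, 2000L),
                       s_end = c(4801L, 1801L))
  expect_equal(chain_alignments(far)$calls$classification, "rearranged")
})

test_that("strand switches and subject order inversions are rearrangements", {
  switch_ <- tibble::tibble(
    query_id = "s", pct_identity = 100, align_length = c(200L, 200L),
    q_start = c(1L, 150L), q_end = c(200L, 349L),
    s_start = c(1000L, 3399L), s_end = c(1199L, 3200L), evalue = 0
  )
  cc <- chain_alignments(switch_)
  expect_equal(cc$calls$classification, "rearranged")
  expect_equal(tidy(cc)$reason, "strand_switch")
  expect_equal(tidy(cc)$footprint_length, 51L)
  inv <- tibble::tibble(
    query_id = "i", pct_identity = 100, align_length = c(200L, 200L),
    q_start = c(1L, 210L), q_end = c(200L, 409L),
    s_start = c(5000L, 1000L), s_end = c(5199L, 1199L), evalue = 0
  )
  expect_equal(chain_alignments(inv)$calls$classification, "rearranged")
})

test_that("query-contained secondary segments are dropped before chaining", {
  recs <- tibble::tibble(
    query_id = "q", pct_identity = 100,
    align_length = c(400L, 90L, 300L),
    q_start = c(1L, 50L, 500L), q_end = c(400L, 139L, 799L),
    s_start = c(1000L, 9000L, 1450L), s_end = c(1399L, 9089L, 1749L),
    evalue = 0
  )
  cc <- chain_alignments(recs)
  expect_equal(cc$calls$n_segments, 2L)
  expect_equal(cc$calls$classification, "colinear")
  cc2 <- chain_alignments(recs, drop_contained = FALSE)
  expect_equal(cc2$calls$n_segments, 3L)
  expect_equal(cc2$calls$classification, "rearranged")
})

test_that("the internal aligner finds exact substrings on both strands", {
  withr::with_seed(17, {
    subject <- random_genome(3000, id = "ref")
    q1 <- subseq_circular(subject, 500, length = 400)
    a1 <- align_seed_extend(q1, subject, min_segment = 50, query_id = "q1")
    expect_equal(nrow(a1), 1L)
    expect_equal(c(a1$q_start, a1$q_end, a1$s_start, a1$s_end, a1$strand),
                 c("1", "400", "500", "899", "+"))
    # reverse-complement query maps to one minus-strand segment
    a2 <- align_seed_extend(revcomp(q1), subject, min_segment = 50)
    expect_equal(nrow(a2), 1L)
    expect_equal(a2$strand, "-")
    expect_equal(c(a2$s_start, a2$s_end), c(899L, 500L))
    # concatenation of two distant substrings gives both segments,
    # verified against a plain string-search oracle
    q3 <- paste0(subseq_circular(subject, 100, length = 300),
                 subseq_circular(subject, 2000, length = 250))
    a3 <- align_seed_extend(q3, subject, min_segment = 50)
    a3 <- a3[order(a3$q_start), ]
    expect_equal(nrow(a3), 2L)
    oracle1 <- as.integer(regexpr(substr(q3, 1, 300), subject$sequence,
                                  fixed = TRUE))
    oracle2 <- as.integer(regexpr(substr(q3, 301, 550), subject$sequence,
                                  fixed = TRUE))
    expect_equal(a3$s_start, c(oracle1, oracle2))
    expect_equal(a3$s_end, c(oracle1 + 299L, oracle2 + 249L))
  })
})

test_that("the aligner honours subject circularity", {
  withr::with_seed(18, {
    subject <- random_genome(2000, id = "ref")
    # query spans the subject origin
    q <- subseq_circular(subject, 1900, length = 300)
    a <- align_seed_extend(q, subject, min_segment = 50)
    expect_equal(nrow(a), 1L)
    expect_equal(a$s_start, 1900L)
    expect_equal(a$s_end, 2199L)  # wraps past the origin
  })
})

test_that("queries cut straight from the reference are all colinear", {
  withr::with_seed(19, {
    subject <- random_genome(5000, id = "ref")
    for (i in 1:5) {
      st <- sample(4000, 1)
      q <- subseq_circular(subject, st, length = sample(300:900, 1))
      cc <- chain_alignments(align_seed_extend(q, subject, min_segment = 50,
                                               query_id = paste0("q", i)))
      expect_equal(cc$calls$classification, "colinear")
    }
  })
})

test_that("strand-aware gene distances reproduce on both strands", {
  d <- gene_segment_distances(156744, 158290, 156716, 158245, "-")
  expect_equal(d$dist_to_start, 45)
  expect_equal(d$dist_to_end, 28)
  # coordinate reflection: mirror everything through C = 300000
  C <- 300000
  dm <- gene_segment_distances(C - 158290, C - 156744,
                               C - 158245, C - 156716, "+")
  expect_equal(dm$dist_to_start, 45)
  expect_equal(dm$dist_to_end, 28)
})

test_that("breakpoints gain the nearest gene within the window only", {
  recs <- tibble::tibble(
    query_id = "q", pct_identity = 100, align_length = c(1548L, 1096L),
    q_start = c(5871L, 9138L), q_end = c(7413L, 10223L),
    s_start = c(156744L, 529298L), s_end = c(158290L, 528203L), evalue = 0
  )
  genes <- tibble::tibble(gene_id = "atp1", start = 156716L, end = 158245L,
                          strand = "-")
  cc <- annotate_breakpoints(chain_alignments(recs), genes, window = 1000L)
  bp <- tidy(cc)
  expect_equal(bp$nearest_gene, "atp1")
  expect_equal(bp$dist_to_start, 45)
  expect_equal(bp$dist_to_end, 28)
  far_genes <- tibble::tibble(gene_id = "g", start = 600000L, end = 601000L,
                              strand = "+")
  cc2 <- annotate_breakpoints(chain_alignments(recs), far_genes,
                              window = 1000L)
  expect_true(is.na(tidy(cc2)$nearest_gene))
})

test_that("cross-sample presence flags breakpoints unique to one sample", {
  mk <- function(left, right) tibble::tibble(
    subject_left = left, subject_right = right
  )
  shared <- mk(10000L, 50000L)
  samples <- list(
    s1 = dplyr::bind_rows(shared, mk(70010L, 90005L)),
    s2 = shared, s3 = shared, s4 = shared, s5 = shared, s6 = shared
  )
  long <- purrr::imap_dfr(samples, ~ dplyr::mutate(.x, sample = .y))
  mat <- compare_breakpoint_presence(long)
  expect_equal(nrow(mat), 2L)
  shared_row <- mat[mat$subject_left == 10000L, ]
  expect_true(is.na(shared_row$unique_to))
  uniq_row <- mat[mat$subject_left == 70010L, ]
  expect_equal(uniq_row$unique_to, "s1")
  # positions within the merge radius collapse to one site
  jitter <- dplyr::mutate(shared, subject_left = subject_left + 30L,
                          sample = "s2")
  mat2 <- compare_breakpoint_presence(dplyr::bind_rows(
    dplyr::mutate(shared, sample = "s1"), jitter
  ))
  expect_equal(nrow(mat2), 1L)
})

test_that("the split-alignment plot renders", {
  tab <- read_alignment_table(table3_path())
  p <- ggplot2::autoplot(chain_alignments(tab))
  expect_s3_class(p, "ggplot")
})
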