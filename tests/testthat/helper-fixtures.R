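# Shared fixture builders (all constructed in code).

table3_path <- function() {
  system.file("extdata", "rrim600_vs_bpm24_blast.tsv", package = "mitomosaic")
}

make_graph <- function(ids, edge_df, lengths = NULL) {
  contigs <- tibble::tibble(
    contig_id = ids,
    length = if (is.null(lengths)) rep(1000L, length(ids)) else lengths,
    depth = 50
  )
  build_contig_graph(contigs, edge_df)
}

# simple directed cycle c1 -> c2 -> ... -> c1 via 3'->5' links
cycle_links <- function(ids) {
  tibble::tibble(
    contig_a = ids, end_a = "3'",
    contig_b = ids[c(seq_along(ids)[-1], 1L)], end_b = "5'",
    support = 10L
  )
}

# two loops sharing contig "S": S-A-B-S and S-C-D-S
two_loop_graph <- function() {
  edges <- tibble::tibble(
    contig_a = c("S", "A", "B", "S", "C", "D"), end_a = "3'",
    contig_b = c("A", "B", "S", "C", "D", "S"), end_b = "5'",
    support = 10L
  )
  make_graph(c("S", "A", "B", "C", "D"), edges)
}

# a genome with one planted repeat whose flanks block extension, so the
# planted pair is exactly the maximal repeat
plant_repeat_genome <- function(n, start1, start2, len, orientation = "direct",
                                mismatch_at = integer(0)) {
  bases <- c("A", "C", "G", "T")
  chars <- sample(bases, n, replace = TRUE)
  unit <- sample(bases, len, replace = TRUE)
  copy2 <- if (orientation == "inverted") {
    rev(chartr("ACGT", "TGCA", unit))
  } else {
    unit
  }
  for (p in mismatch_at) {
    copy2[p] <- sample(setdiff(bases, copy2[p]), 1L)
  }
  chars[seq.int(start1, start1 + len - 1L)] <- unit
  chars[seq.int(start2, start2 + len - 1L)] <- copy2
  block <- function(pos, avoid) {
    chars[pos] <<- sample(setdiff(bases, avoid), 1L)
  }
  if (orientation == "direct") {
    block(start2 - 1L, chars[start1 - 1L])
    block(start2 + len, chars[start1 + len])
  } else {
    block(start2 + len, chartr("ACGT", "TGCA", chars[start1 - 1L]))
    block(start2 - 1L, chartr("ACGT", "TGCA", chars[start1 + len]))
  }
  circular_genome(paste(chars, collapse = ""), id = "planted")
}

# per-bin repeat pair list shaped like a published size-bin census
pairs_from_bins <- function(bin_specs) {
  purrr::map_dfr(bin_specs, function(b) {
    n <- b$n_direct + b$n_inverted
    if (n == 0L) return(NULL)
    tibble::tibble(
      start1 = seq_len(n), start2 = seq_len(n) + 10000L,
      length = rep_len(b$lengths, n),
      orientation = rep(c("direct", "inverted"), c(b$n_direct, b$n_inverted)),
      mismatches = 0L
    )
  })
}

# figure-eight with a reversible inner loop: S-A-B-S plus S-C-S attachable
# in either direction, so two distinct minimal configurations exist
reversible_loop_graph <- function() {
  edges <- tibble::tibble(
    contig_a = c("S", "A", "B", "S", "C", "S", "C"),
    end_a    = c("3'", "3'", "3'", "3'", "3'", "3'", "5'"),
    contig_b = c("A", "B", "S", "C", "S", "C", "S"),
    end_b    = c("5'", "5'", "5'", "5'", "5'", "3'", "5'"),
    support = 10L
  )
  make_graph(c("S", "A", "B", "C"), edges)
}
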