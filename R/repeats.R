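#' Find maximal direct and inverted repeats on a circular genome
#'
#' Enumerates every maximal repeated pair: two occurrences (direct, or
#' reverse-complemented for inverted pairs) that match with at most
#' `max_mismatches` substitutions and cannot be extended in either direction
#' without exceeding that budget. Circular topology is honoured, so matches
#' may run through the origin. Each unordered occurrence pair is reported
#' once; a repeat present in three copies therefore yields three pairs.
#'
#' The search seeds on exact shared k-mers and then enumerates maximal
#' mismatch-bounded windows along each seeded (anti-)diagonal. The seed
#' length is derived from `min_length` and the mismatch budget so that, by
#' pigeonhole, every qualifying repeat contains at least one exact seed:
#' a window of length `L >= min_length` with at most `m` mismatches always
#' contains an exact run of at least `floor((min_length - m) / (m + 1))`
#' bases.
#'
#' @param genome A [circular_genome()].
#' @param min_length Minimum repeat length in bases (>= 8; shorter cutoffs
#'   saturate a DNA alphabet with chance matches).
#' @param max_mismatches Maximum substitutions tolerated within one pair.
#'
#' @return A tibble with one row per pair: `start1`, `start2` (1-based
#'   starts of the two occurrences, `start1 < start2`), `length`,
#'   `orientation` (`"direct"` or `"inverted"`), `mismatches`. For inverted
#'   pairs `start2` is the start of the occurrence whose reverse complement
#'   matches the first. Occurrences may wrap past the origin, in which case
#'   `start + length - 1` exceeds the genome length.
#' @export
#' @examples
#' set.seed(1)
#' g <- random_genome(300)
#' g <- overwrite_segment(g, 200, subseq_circular(g, 20, length = 30))
#' find_repeats(g, min_length = 25)
find_repeats <- function(genome, min_length = 20L, max_mismatches = 0L) {
  stopifnot(inherits(genome, "circular_genome"))
  if (min_length < 8L) {
    stop("find_repeats: min_length must be >= 8", call. = FALSE)
  }
  stopifnot(max_mismatches >= 0L)
  n <- genome_length(genome)
  empty <- tibble::tibble(
    start1 = integer(), start2 = integer(), length = integer(),
    orientation = character(), mismatches = integer()
  )
  if (n < min_length) return(empty)

  s <- genome$sequence
  ints <- utf8ToInt(s)
  comp_ints <- utf8ToInt(chartr("ACGT", "TGCA", s))
  k <- as.integer(max_mismatches)

  seed_len <- max(4L, min(20L, (min_length - k) %/% (k + 1L)))
  seed_len <- min(seed_len, n)

  doubled <- paste0(s, s)
  kmers <- substring(doubled, seq_len(n), seq_len(n) + seed_len - 1L)

  ## --- direct pairs: seeded diagonals -----------------------------------
  groups <- split(seq_len(n), kmers)
  groups <- groups[lengths(groups) > 1L]
  diags <- unique(unlist(lapply(groups, function(v) {
    d <- as.vector(outer(v, v, "-"))
    d <- d[d > 0L]
    pmin(d, n - d)
  }), use.names = FALSE))
  diags <- diags[diags > 0L]

  direct <- purrr::map_dfr(diags, function(d) {
    shifted <- ((seq_len(n) + d - 1L) %% n) + 1L
    win <- maximal_match_windows(ints == ints[shifted], k, n, min_length)
    if (nrow(win) == 0L) return(NULL)
    a <- ((win$start - 1L) %% n) + 1L
    b <- ((win$start + d - 1L) %% n) + 1L
    tibble::tibble(
      start1 = pmin(a, b), start2 = pmax(a, b), length = win$len,
      orientation = "direct", mismatches = win$mism
    )
  })

  ## --- inverted pairs: seeded anti-diagonals ----------------------------
  rc <- revcomp(s)
  rc_kmers <- substring(paste0(rc, rc), seq_len(n), seq_len(n) + seed_len - 1L)
  shared <- intersect(unique(kmers), unique(rc_kmers))
  antis <- integer(0)
  if (length(shared)) {
    fwd_pos <- split(seq_len(n), kmers)[shared]
    rev_pos <- split(seq_len(n), rc_kmers)[shared]
    antis <- unique(unlist(purrr::map2(fwd_pos, rev_pos, function(iv, uv) {
      cc <- as.vector(outer(iv, -uv, "+")) + n + 1L
      ((cc - 1L) %% n) + 1L
    }), use.names = FALSE))
  }

  inverted <- purrr::map_dfr(antis, function(cc) {
    partner <- ((cc - seq_len(n) - 1L) %% n) + 1L
    win <- maximal_match_windows(ints == comp_ints[partner], k, n, min_length)
    if (nrow(win) == 0L) return(NULL)
    a <- ((win$start - 1L) %% n) + 1L
    b <- ((cc - (win$start + win$len - 1L) - 1L) %% n) + 1L
    keep <- a != b  # a fully self-mirrored window is one palindromic locus,
                    # not two occurrences
    tibble::tibble(
      start1 = pmin(a, b)[keep], start2 = pmax(a, b)[keep],
      length = win$len[keep], orientation = "inverted",
      mismatches = win$mism[keep]
    )
  })

  out <- dplyr::bind_rows(direct, inverted)
  if (nrow(out) == 0L) return(empty)
  out |>
    dplyr::distinct(.data$start1, .data$start2, .data$length,
                    .data$orientation, .keep_all = TRUE) |>
    dplyr::arrange(.data$start1, .data$start2, .data$orientation)
}

# Maximal windows with <= k mismatches on a circular logical match vector.
# Returns start (may exceed n before normalisation), circular length, and the
# number of mismatching positions inside the window. Windows are bounded on
# both sides by a blocking mismatch (or cover the whole circle when the total
# mismatch count is within budget).
maximal_match_windows <- function(m, k, n, min_length) {
  mism <- which(!m)
  t <- length(mism)
  if (t <= k) {
    if (n < min_length) {
      return(tibble::tibble(start = integer(), len = integer(), mism = integer()))
    }
    return(tibble::tibble(start = 1L, len = n, mism = t))
  }
  # window i is bounded by mism[i] on the left and mism[i + k + 1] on the
  # right (circularly); its length is the positions strictly between them
  nxt <- mism[((seq_len(t) + k) %% t) + 1L]
  start <- mism + 1L
  len <- (nxt - mism - 1L) %% n
  keep <- len >= min_length
  tibble::tibble(start = start[keep], len = len[keep],
                 mism = rep.int(k, sum(keep)))
}

#' Summarize a repeat list into size bins
#'
#' Tallies repeat pairs into the conventional size bins for plant
#' mitochondrial repeat censuses (20-40, 41-60, 61-80, 81-100, 101-200,
#' >200 bp), split by orientation, with the percent of the genome occupied
#' by each bin and a totals row. Percent genome counts each pair's length
#' once (one copy per pair, overlaps not collapsed); alternative
#' conventions can be recomputed from the pair list itself.
#'
#' @param pairs Tibble from [find_repeats()] (columns `length`,
#'   `orientation` suffice).
#' @param genome_length Genome length in bases, for the percent column.
#' @param bin_breaks Lower edges of the bins; bin `i` covers
#'   `[bin_breaks[i], bin_breaks[i+1] - 1]` and the last bin is open-ended.
#' @return A tibble of class `repeat_summary`: `bin`, `n_repeats`,
#'   `pct_genome`, `n_direct`, `n_inverted`, with a final `Total` row.
#'   Pairs shorter than the smallest bin edge are dropped with a warning.
#' @export
summarize_repeats <- function(pairs, genome_length,
                              bin_breaks = c(20L, 41L, 61L, 81L, 101L, 201L)) {
  stopifnot(genome_length > 0, length(bin_breaks) >= 1, !is.unsorted(bin_breaks))
  too_short <- pairs$length < bin_breaks[1]
  if (any(too_short)) {
    warning(sprintf("summarize_repeats: dropping %d pair(s) shorter than %d bp",
                    sum(too_short), bin_breaks[1]), call. = FALSE)
    pairs <- pairs[!too_short, , drop = FALSE]
  }
  labels <- c(
    paste0(bin_breaks[-length(bin_breaks)], "-", bin_breaks[-1] - 1L),
    paste0(">", bin_breaks[length(bin_breaks)] - 1L)
  )
  idx <- findInterval(pairs$length, bin_breaks)
  per_bin <- tibble::tibble(
    bin = factor(labels[idx], levels = labels),
    length = pairs$length,
    orientation = pairs$orientation
  ) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(
      n_repeats = dplyr::n(),
      pct_genome = sum(.data$length) / genome_length * 100,
      n_direct = sum(.data$orientation == "direct"),
      n_inverted = sum(.data$orientation == "inverted"),
      .groups = "drop"
    ) |>
    dplyr::mutate(bin = as.character(.data$bin))
  total <- tibble::tibble(
    bin = "Total",
    n_repeats = sum(per_bin$n_repeats),
    pct_genome = sum(per_bin$pct_genome),
    n_direct = sum(per_bin$n_direct),
    n_inverted = sum(per_bin$n_inverted)
  )
  out <- dplyr::bind_rows(per_bin, total)
  class(out) <- c("repeat_summary", class(out))
  out
}

#' Plot a repeat size-bin summary
#'
#' @param object A `repeat_summary` from [summarize_repeats()].
#' @param ... Unused.
#' @return A ggplot: pair counts per size bin, split by orientation.
#' @method autoplot repeat_summary
#' @export
autoplot.repeat_summary <- function(object, ...) {
  df <- object |>
    dplyr::filter(.data$bin != "Total") |>
    tidyr::pivot_longer(c("n_direct", "n_inverted"),
                        names_to = "orientation", values_to = "n") |>
    dplyr::mutate(
      orientation = ifelse(.data$orientation == "n_direct", "direct", "inverted"),
      bin = factor(.data$bin, levels = unique(.data$bin))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$n,
                                   fill = .data$orientation)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Repeat length (bp)", y = "Repeat pairs",
                  fill = "Orientation") +
    ggplot2::theme_minimal()
}
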