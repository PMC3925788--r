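#' Read a 7-column tabular alignment file
#'
#' Reads local-alignment records in the BLAST-outfmt-6-like dialect used
#' for contig-versus-master-circle comparisons: query id, percent identity,
#' alignment length, query start/end, subject start/end, and an optional
#' e-value. Query ids may be blank on continuation rows (filled down).
#' Minus-strand alignments are encoded by `s_start > s_end`.
#'
#' @param path Path to a TSV file with a header row.
#' @return Tibble of alignment records with an added `strand` column.
#'   Malformed rows raise an error naming the line.
#' @export
read_alignment_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 7L) {
    stop("read_alignment_table: expected >= 7 columns, got ", ncol(raw),
         call. = FALSE)
  }
  names(raw)[1:7] <- c("query_id", "pct_identity", "align_length",
                       "q_start", "q_end", "s_start", "s_end")
  if (ncol(raw) >= 8L) names(raw)[8] <- "evalue" else raw$evalue <- NA_character_
  raw <- tidyr::fill(raw, "query_id")
  out <- tibble::tibble(
    query_id = raw$query_id,
    pct_identity = suppressWarnings(as.numeric(raw$pct_identity)),
    align_length = suppressWarnings(as.integer(raw$align_length)),
    q_start = suppressWarnings(as.integer(raw$q_start)),
    q_end = suppressWarnings(as.integer(raw$q_end)),
    s_start = suppressWarnings(as.integer(raw$s_start)),
    s_end = suppressWarnings(as.integer(raw$s_end)),
    evalue = suppressWarnings(as.numeric(raw$evalue))
  )
  bad <- which(
    is.na(out$query_id) | is.na(out$pct_identity) | is.na(out$align_length) |
      is.na(out$q_start) | is.na(out$q_end) | is.na(out$s_start) |
      is.na(out$s_end) | out$q_start > out$q_end | out$align_length < 1L |
      out$pct_identity <= 0 | out$pct_identity > 100
  )
  if (length(bad)) {
    stop("read_alignment_table: malformed record at line ", bad[1] + 1L,
         " of ", path, call. = FALSE)
  }
  out$strand <- ifelse(out$s_start > out$s_end, "-", "+")
  out
}

#' Align a query against a circular subject by exact seed-and-extend
#'
#' Internal ungapped aligner for synthetic analyses: reports every maximal
#' exact local match of at least `min_segment` bases between the query and
#' either strand of the circular subject, in the same record layout as
#' [read_alignment_table()]. Matches may run through the subject origin, in
#' which case subject coordinates beyond the genome length wrap.
#'
#' @param query Character scalar (query sequence) or `circular_genome`.
#' @param subject A [circular_genome()].
#' @param min_segment Minimum reported match length in bases.
#' @param query_id Id recorded in the output.
#' @param seed_length Exact seed k-mer length (shorter seeds cost time, find
#'   nothing extra for exact matching as long as `seed_length <=
#'   min_segment`).
#' @return Tibble of alignment records (`pct_identity` is always 100).
#' @export
align_seed_extend <- function(query, subject, min_segment = 50L,
                              query_id = "query", seed_length = 18L) {
  if (inherits(query, "circular_genome")) {
    if (query_id == "query") query_id <- query$id
    query <- query$sequence
  }
  stopifnot(inherits(subject, "circular_genome"))
  seed_length <- min(seed_length, min_segment, nchar(query))
  n <- genome_length(subject)
  qn <- nchar(query)
  q_ints <- utf8ToInt(toupper(query))

  one_strand <- function(subj_seq, strand) {
    s_ints <- utf8ToInt(subj_seq)
    subj_kmers <- substring(paste0(subj_seq, subj_seq),
                            seq_len(n), seq_len(n) + seed_length - 1L)
    q_starts <- seq_len(qn - seed_length + 1L)
    q_kmers <- substring(query, q_starts, q_starts + seed_length - 1L)
    shared <- intersect(unique(q_kmers), unique(subj_kmers))
    if (!length(shared)) return(NULL)
    qpos <- split(q_starts, q_kmers)[shared]
    spos <- split(seq_len(n), subj_kmers)[shared]
    offs <- unique(unlist(purrr::map2(qpos, spos, function(qv, sv) {
      ((as.vector(outer(sv, qv, "-")) %% n) + n) %% n
    }), use.names = FALSE))
    purrr::map_dfr(offs, function(off) {
      sidx <- ((seq_len(qn) + off - 1L) %% n) + 1L
      m <- q_ints == s_ints[sidx]
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_segment
      if (!any(keep)) return(NULL)
      tibble::tibble(q_start = starts[keep], q_end = ends[keep],
                     off = off, strand = strand)
    })
  }

  plus <- one_strand(subject$sequence, "+")
  minus <- one_strand(revcomp(subject$sequence), "-")

  rows <- list()
  if (!is.null(plus) && nrow(plus)) {
    s1 <- ((plus$q_start + plus$off - 1L) %% n) + 1L
    rows$plus <- tibble::tibble(
      query_id = query_id, pct_identity = 100,
      align_length = plus$q_end - plus$q_start + 1L,
      q_start = plus$q_start, q_end = plus$q_end,
      s_start = s1, s_end = s1 + (plus$q_end - plus$q_start),
      evalue = NA_real_, strand = "+"
    )
  }
  if (!is.null(minus) && nrow(minus)) {
    # coordinates in reverse-complement space back to subject space
    u1 <- ((minus$q_start + minus$off - 1L) %% n) + 1L
    len <- minus$q_end - minus$q_start + 1L
    rows$minus <- tibble::tibble(
      query_id = query_id, pct_identity = 100,
      align_length = len,
      q_start = minus$q_start, q_end = minus$q_end,
      s_start = n + 1L - u1, s_end = n + 1L - u1 - (len - 1L),
      evalue = NA_real_, strand = "-"
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(
      query_id = character(), pct_identity = double(),
      align_length = integer(), q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer(), evalue = double(),
      strand = character()
    ))
  }
  dplyr::bind_rows(rows) |>
    dplyr::distinct(.data$q_start, .data$q_end, .data$s_start, .data$s_end,
                    .data$strand, .keep_all = TRUE) |>
    dplyr::arrange(.data$q_start, .data$s_start)
}

#' Query-interval overlap and gap between two alignment segments
#'
#' The breakpoint repeat footprint of a split alignment is the overlap of
#' the two segments' query intervals: after homologous recombination each
#' junction carries one full copy of the recombining repeat, so the query
#' aligns that copy in both segments. A gap between the intervals is
#' instead an insertion at the junction. Exactly one of the two can be
#' positive.
#'
#' @param q_start1,q_end1,q_start2,q_end2 Query intervals of the two
#'   segments (vectors recycle).
#' @return Tibble with `footprint_length` and `insertion_length`.
#' @export
#' @examples
#' breakpoint_footprint(1, 612, 512, 1096)  # the 101 bp repeat footprint
breakpoint_footprint <- function(q_start1, q_end1, q_start2, q_end2) {
  tibble::tibble(
    footprint_length = pmax(0L, pmin(q_end1, q_end2) - pmax(q_start1, q_start2) + 1L),
    insertion_length = pmax(0L, pmax(q_start1, q_start2) - pmin(q_end1, q_end2) - 1L)
  )
}

#' Chain split alignments per query and classify rearrangements
#'
#' Sorts each query's alignment segments by query start and tests every
#' consecutive pair for colinearity: same strand, subject order consistent
#' with query order, and subject gap at most `max_colinear_gap`. A query
#' whose segments all chain colinearly matches the reference as-is; any
#' strand switch, order inversion, or long-range subject jump marks the
#' query as rearranged, with one breakpoint per offending pair carrying the
#' query-overlap footprint (or insertion) and the junction-side subject
#' coordinates.
#'
#' Segments shorter than `min_segment` are ignored. Segments whose query
#' interval lies inside another segment's are redundant
#' (repeat-induced secondary matches) and are dropped before chaining
#' unless `drop_contained = FALSE`.
#'
#' @param records Alignment tibble from [read_alignment_table()] or
#'   [align_seed_extend()]; may hold many queries.
#' @param max_colinear_gap Largest subject gap (bases) still considered
#'   colinear. Default 1000.
#' @param min_segment Minimum aligned length for a segment to participate.
#' @param drop_contained Drop query-interval-contained segments.
#' @return A `rearrangement_calls` object: list of tibbles `calls`
#'   (`query_id`, `classification`, `n_segments`), `segments` (the chained
#'   segments), and `breakpoints` (one row per non-colinear junction with
#'   `footprint_length`, `insertion_length`, `subject_left`,
#'   `subject_right`, `reason`). Queries with no usable segments are
#'   classified `unaligned`.
#' @export
chain_alignments <- function(records, max_colinear_gap = 1000L,
                             min_segment = 50L, drop_contained = TRUE) {
  if (!"strand" %in% names(records)) {
    records$strand <- ifelse(records$s_start > records$s_end, "-", "+")
  }
  all_queries <- unique(records$query_id)
  records <- dplyr::filter(records, .data$align_length >= min_segment)

  per_query <- function(df) {
    df <- dplyr::arrange(df, dplyr::desc(.data$q_end - .data$q_start),
                         .data$q_start, .data$s_start)
    if (drop_contained && nrow(df) > 1L) {
      keep <- rep(TRUE, nrow(df))
      for (i in seq_len(nrow(df))[-1]) {
        prior <- which(keep[seq_len(i - 1L)])
        contained <- any(df$q_start[prior] <= df$q_start[i] &
                           df$q_end[prior] >= df$q_end[i])
        if (contained) keep[i] <- FALSE
      }
      df <- df[keep, , drop = FALSE]
    }
    df <- dplyr::arrange(df, .data$q_start, .data$q_end, .data$s_start)
    if (nrow(df) < 2L) {
      return(list(segments = df, classification = "colinear",
                  breakpoints = NULL))
    }
    l <- df[-nrow(df), ]
    r <- df[-1, ]
    same_strand <- l$strand == r$strand
    plus_ok <- l$strand == "+" & r$s_start >= l$s_start &
      (r$s_start - l$s_end - 1L) <= max_colinear_gap
    minus_ok <- l$strand == "-" & r$s_start <= l$s_start &
      (l$s_end - r$s_start - 1L) <= max_colinear_gap
    colinear_pair <- same_strand & (plus_ok | minus_ok)
    if (all(colinear_pair)) {
      return(list(segments = df, classification = "colinear",
                  breakpoints = NULL))
    }
    bad <- which(!colinear_pair)
    fp <- breakpoint_footprint(l$q_start[bad], l$q_end[bad],
                               r$q_start[bad], r$q_end[bad])
    bp <- tibble::tibble(
      query_id = df$query_id[1],
      left_q_start = l$q_start[bad], left_q_end = l$q_end[bad],
      right_q_start = r$q_start[bad], right_q_end = r$q_end[bad],
      footprint_length = fp$footprint_length,
      insertion_length = fp$insertion_length,
      subject_left = l$s_end[bad], subject_right = r$s_start[bad],
      left_s_start = l$s_start[bad], left_s_end = l$s_end[bad],
      right_s_start = r$s_start[bad], right_s_end = r$s_end[bad],
      reason = ifelse(!same_strand[bad], "strand_switch",
                      "subject_jump")
    )
    list(segments = df, classification = "rearranged", breakpoints = bp)
  }

  parts <- records |>
    dplyr::group_by(.data$query_id) |>
    dplyr::group_map(~ per_query(dplyr::mutate(.x, query_id = .y$query_id)),
                     .keep = TRUE)
  names(parts) <- vapply(parts, function(p) p$segments$query_id[1] %||%
                           NA_character_, "")

  segments <- purrr::map_dfr(parts, "segments")
  breakpoints <- purrr::map_dfr(parts, "breakpoints")
  calls <- tibble::tibble(
    query_id = unname(vapply(parts, function(p) p$segments$query_id[1], "")),
    classification = unname(vapply(parts, function(p) p$classification, "")),
    n_segments = unname(vapply(parts, function(p) nrow(p$segments), 0L))
  )
  lost <- setdiff(all_queries, calls$query_id)
  if (length(lost)) {
    calls <- dplyr::bind_rows(calls, tibble::tibble(
      query_id = lost, classification = "unaligned", n_segments = 0L
    ))
  }
  calls <- dplyr::arrange(calls, .data$query_id)
  structure(list(calls = calls, segments = segments,
                 breakpoints = breakpoints),
            class = "rearrangement_calls")
}

#' @export
print.rearrangement_calls <- function(x, ...) {
  tab <- table(x$calls$classification)
  cat(sprintf("<rearrangement_calls> %d queries (%s); %d breakpoint(s)\n",
              nrow(x$calls),
              paste(names(tab), tab, sep = ": ", collapse = ", "),
              nrow(x$breakpoints)))
  invisible(x)
}

#' @rdname chain_alignments
#' @param x A `rearrangement_calls` object.
#' @param ... Unused.
#' @method tidy rearrangement_calls
#' @export
tidy.rearrangement_calls <- function(x, ...) {
  if (is.null(x$breakpoints) || nrow(x$breakpoints) == 0L) {
    return(tibble::tibble())
  }
  tibble::as_tibble(x$breakpoints)
}

#' @rdname chain_alignments
#' @method glance rearrangement_calls
#' @export
glance.rearrangement_calls <- function(x, ...) {
  tibble::tibble(
    n_queries = nrow(x$calls),
    n_rearranged = sum(x$calls$classification == "rearranged"),
    n_colinear = sum(x$calls$classification == "colinear"),
    n_unaligned = sum(x$calls$classification == "unaligned"),
    n_breakpoints = if (is.null(x$breakpoints)) 0L else nrow(x$breakpoints)
  )
}

#' Strand-aware distances from an alignment segment to a gene
#'
#' `dist_to_start` is how far the segment extends upstream of the start
#' codon, in gene orientation; `dist_to_end` is how far short of the gene
#' end the segment stops (positive when the segment boundary lies inside
#' the gene, before its end). Both can be negative when the segment does
#' not reach the corresponding gene boundary.
#'
#' @param seg_lo,seg_hi Segment subject interval (lo <= hi).
#' @param gene_start,gene_end Gene interval, 1-based inclusive.
#' @param gene_strand `"+"` or `"-"`.
#' @return Tibble with `dist_to_start`, `dist_to_end`.
#' @export
gene_segment_distances <- function(seg_lo, seg_hi, gene_start, gene_end,
                                   gene_strand) {
  plus <- gene_strand == "+"
  tibble::tibble(
    dist_to_start = ifelse(plus, gene_start - seg_lo, seg_hi - gene_end),
    dist_to_end = ifelse(plus, gene_end - seg_hi, seg_lo - gene_start)
  )
}

#' Annotate breakpoints with the nearest gene within a window
#'
#' For each breakpoint, the subject intervals of its two flanking segments
#' are compared against the gene annotation; the closest gene within
#' `window` bases is recorded along with strand-aware distances from the
#' nearer segment ([gene_segment_distances()]). Breakpoints with no gene in
#' range are left unannotated.
#'
#' @param calls A `rearrangement_calls` object from [chain_alignments()].
#' @param genes Tibble with `gene_id`, `start`, `end`, `strand`.
#' @param window Maximum gene distance in bases (default 1000).
#' @return The `rearrangement_calls` object with `nearest_gene`,
#'   `gene_distance`, `dist_to_start` and `dist_to_end` columns added to
#'   its breakpoints.
#' @export
annotate_breakpoints <- function(calls, genes, window = 1000L) {
  stopifnot(inherits(calls, "rearrangement_calls"))
  bp <- calls$breakpoints
  if (is.null(bp) || nrow(bp) == 0L) return(calls)

  annotate_one <- function(i) {
    segs <- tibble::tibble(
      lo = c(min(bp$left_s_start[i], bp$left_s_end[i]),
             min(bp$right_s_start[i], bp$right_s_end[i])),
      hi = c(max(bp$left_s_start[i], bp$left_s_end[i]),
             max(bp$right_s_start[i], bp$right_s_end[i]))
    )
    best <- NULL
    for (s in seq_len(nrow(segs))) {
      gap <- pmax(0L, genes$start - segs$hi[s], segs$lo[s] - genes$end)
      j <- which.min(gap)
      if (length(j) && (is.null(best) || gap[j] < best$gap)) {
        best <- list(gap = gap[j], gene = j, seg = s)
      }
    }
    if (is.null(best) || best$gap > window) {
      return(tibble::tibble(nearest_gene = NA_character_,
                            gene_distance = NA_integer_,
                            dist_to_start = NA_integer_,
                            dist_to_end = NA_integer_))
    }
    g <- genes[best$gene, ]
    d <- gene_segment_distances(segs$lo[best$seg], segs$hi[best$seg],
                                g$start, g$end, g$strand)
    tibble::tibble(nearest_gene = g$gene_id, gene_distance = best$gap,
                   dist_to_start = d$dist_to_start,
                   dist_to_end = d$dist_to_end)
  }

  ann <- purrr::map_dfr(seq_len(nrow(bp)), annotate_one)
  calls$breakpoints <- dplyr::bind_cols(
    bp[, setdiff(names(bp), names(ann))], ann
  )
  calls
}

#' Cross-sample breakpoint presence/absence
#'
#' Matches breakpoints across samples (two breakpoints are the same site
#' when both junction-side subject coordinates agree within `radius`
#' bases), and builds a site-by-sample presence matrix, flagging sites seen
#' in exactly one sample.
#'
#' @param calls_by_sample Named list of `rearrangement_calls` (one per
#'   sample), or a tibble of breakpoints with a `sample` column.
#' @param radius Merge radius in bases (default 50; repeat footprints blur
#'   exact junction positions).
#' @return Tibble: `site_id`, representative `subject_left`/`subject_right`,
#'   one logical column per sample, and `unique_to` (sample name or `NA`).
#' @export
compare_breakpoint_presence <- function(calls_by_sample, radius = 50L) {
  if (is.data.frame(calls_by_sample)) {
    bp <- calls_by_sample
    stopifnot(all(c("sample", "subject_left", "subject_right") %in% names(bp)))
  } else {
    bp <- purrr::imap_dfr(calls_by_sample, function(cl, nm) {
      b <- if (inherits(cl, "rearrangement_calls")) cl$breakpoints else cl
      if (is.null(b) || nrow(b) == 0L) return(NULL)
      dplyr::mutate(b, sample = nm)
    })
  }
  samples <- if (is.data.frame(calls_by_sample)) unique(bp$sample) else
    names(calls_by_sample)
  if (nrow(bp) == 0L) {
    return(tibble::tibble(site_id = integer(), subject_left = integer(),
                          subject_right = integer(), unique_to = character()))
  }
  # unordered coordinate pair, so mirrored junction reports match
  bp$lo <- pmin(bp$subject_left, bp$subject_right)
  bp$hi <- pmax(bp$subject_left, bp$subject_right)
  bp <- dplyr::arrange(bp, .data$lo, .data$hi)
  site <- integer(nrow(bp))
  reps <- list()
  for (i in seq_len(nrow(bp))) {
    assigned <- FALSE
    for (s in seq_along(reps)) {
      if (abs(bp$lo[i] - reps[[s]]$lo) <= radius &&
          abs(bp$hi[i] - reps[[s]]$hi) <= radius) {
        site[i] <- s; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      reps[[length(reps) + 1L]] <- list(lo = bp$lo[i], hi = bp$hi[i])
      site[i] <- length(reps)
    }
  }
  bp$site_id <- site
  pres <- bp |>
    dplyr::distinct(.data$site_id, .data$sample) |>
    dplyr::mutate(present = TRUE) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "present",
                       values_fill = FALSE)
  missing_samples <- setdiff(samples, names(pres))
  for (ms in missing_samples) pres[[ms]] <- FALSE
  counts <- rowSums(as.matrix(pres[, samples, drop = FALSE]))
  pres$unique_to <- ifelse(
    counts == 1L,
    samples[apply(as.matrix(pres[, samples, drop = FALSE]), 1L, which.max)],
    NA_character_
  )
  rep_tbl <- tibble::tibble(
    site_id = seq_along(reps),
    subject_left = vapply(reps, function(r) as.integer(r$lo), 1L),
    subject_right = vapply(reps, function(r) as.integer(r$hi), 1L)
  )
  dplyr::left_join(rep_tbl, pres, by = "site_id")
}
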