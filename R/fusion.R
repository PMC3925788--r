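#' Find open reading frames in a DNA sequence
#'
#' Scans all six frames of both strands for ORFs under the standard genetic
#' code: an ATG start, no internal stop, and a terminal stop codon (TAA,
#' TAG or TGA) within the sequence. One ORF is reported per stop codon and
#' frame, anchored at its 5'-most ATG. Coordinates are 1-based inclusive on
#' the input sequence and include the stop codon, so the nucleotide span is
#' `3 * (n_aa + 1)` long.
#'
#' @param x Character scalar or [circular_genome()] (scanned as a linear
#'   sequence; origin-spanning ORFs are not searched).
#' @param min_aa Minimum peptide length in amino acids (excluding the
#'   stop). Default 30.
#' @return Tibble: `start`, `end`, `strand`, `frame` (1-3 within strand),
#'   `n_aa`, `peptide`.
#' @export
#' @examples
#' find_orfs("ATGAAATAA", min_aa = 2)  # peptide "MK"
find_orfs <- function(x, min_aa = 30L) {
  if (inherits(x, "circular_genome")) x <- x$sequence
  x <- toupper(x)
  len <- nchar(x)
  stops <- c("TAA", "TAG", "TGA")

  scan_strand <- function(s, strand) {
    out <- list()
    for (frame in 1:3) {
      n_codons <- (nchar(s) - frame + 1L) %/% 3L
      if (n_codons < 2L) next
      starts_nt <- frame + 3L * (seq_len(n_codons) - 1L)
      codons <- substring(s, starts_nt, starts_nt + 2L)
      is_stop <- codons %in% stops
      is_atg <- codons == "ATG"
      prev_stop <- 0L
      for (sidx in which(is_stop)) {
        region <- if (sidx > prev_stop + 1L) {
          seq.int(prev_stop + 1L, sidx - 1L)
        } else {
          integer(0)
        }
        atg <- region[is_atg[region]][1]
        prev_stop <- sidx
        if (is.na(atg)) next
        n_aa <- sidx - atg
        if (n_aa < min_aa) next
        nt_start <- starts_nt[atg]
        nt_end <- starts_nt[sidx] + 2L
        pep <- paste(unname(
          Biostrings::GENETIC_CODE[codons[seq.int(atg, sidx - 1L)]]),
          collapse = "")
        out[[length(out) + 1L]] <- tibble::tibble(
          start = if (strand == "+") nt_start else len - nt_end + 1L,
          end = if (strand == "+") nt_end else len - nt_start + 1L,
          strand = strand, frame = frame, n_aa = n_aa, peptide = pep
        )
      }
    }
    out
  }

  rows <- c(scan_strand(x, "+"), scan_strand(revcomp(x), "-"))
  if (!length(rows)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), frame = integer(),
                          n_aa = integer(), peptide = character()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$start, .data$strand)
}

# Longest identically matching ungapped block between two peptides.
# Returns its length and 1-based positions in each peptide.
longest_common_block <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(av); lb <- length(bv)
  best <- list(len = 0L, a_start = NA_integer_, b_start = NA_integer_)
  for (off in seq.int(-(la - 1L), lb - 1L)) {
    ai <- seq.int(max(1L, 1L - off), min(la, lb - off))
    if (!length(ai)) next
    bi <- ai + off
    r <- rle(av[ai] == bv[bi])
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    runs <- which(r$values)
    j <- runs[which.max(r$lengths[runs])]
    if (r$lengths[j] > best$len) {
      pos <- ends[j] - r$lengths[j] + 1L
      best <- list(len = r$lengths[j],
                   a_start = ai[pos], b_start = bi[pos])
    }
  }
  best
}

#' Call candidate fusion transcripts at rearrangement breakpoints
#'
#' The cytoplasmic-male-sterility candidate logic: an ORF that spans a
#' rearrangement junction and whose peptide shares a long identical block
#' with a known gene product is a candidate chimeric (fusion) transcript --
#' for example a novel ORF incorporating the carboxyl-terminal tail of
#' atp9. Peptides are compared by ungapped exact-block matching
#' (recombination-derived chimeras are identical by construction over the
#' retained region), and a call is emitted when the longest identical
#' block reaches `min_identical` residues.
#'
#' @param breakpoints Tibble with a `position` column: junction coordinates
#'   on `genome` (the molecule carrying the novel junctions).
#' @param genome A [circular_genome()].
#' @param gene_peptides Tibble with `gene_id` and `peptide`.
#' @param flank Bases examined on each side of a breakpoint (default 500).
#' @param min_aa Minimum ORF peptide length (see [find_orfs()]).
#' @param min_identical Minimum identical block length in residues
#'   (default 15; shorter blocks are dominated by chance matches).
#' @return Tibble of fusion calls: `position`, ORF genome coordinates and
#'   strand, `n_aa`, `peptide`, `matched_gene`, `n_identical_aa`,
#'   `n_extra_aa`, `matched_region` (`amino-terminal`, `carboxyl-terminal`,
#'   `internal` or `complete`). Errors if a breakpoint lies outside the
#'   genome.
#' @export
call_fusions <- function(breakpoints, genome, gene_peptides, flank = 500L,
                         min_aa = 30L, min_identical = 15L) {
  stopifnot(inherits(genome, "circular_genome"),
            all(c("gene_id", "peptide") %in% names(gene_peptides)))
  n <- genome_length(genome)
  if (any(breakpoints$position < 1L | breakpoints$position > n)) {
    stop("call_fusions: breakpoint outside genome bounds", call. = FALSE)
  }
  flank <- min(flank, (n - 1L) %/% 2L)

  call_one <- function(pos) {
    win_start <- pos - flank
    win <- subseq_circular(genome, win_start + n, length = 2L * flank + 1L)
    orfs <- find_orfs(win, min_aa = min_aa)
    junction <- flank + 1L  # breakpoint position within the window
    orfs <- dplyr::filter(orfs, .data$start <= junction, .data$end >= junction)
    if (nrow(orfs) == 0L) return(NULL)
    purrr::map_dfr(seq_len(nrow(orfs)), function(i) {
      blocks <- purrr::map(gene_peptides$peptide, longest_common_block,
                           a = orfs$peptide[i])
      lens <- vapply(blocks, function(b) b$len, 1L)
      j <- which.max(lens)
      if (lens[j] < min_identical) return(NULL)
      b <- blocks[[j]]
      gene_len <- nchar(gene_peptides$peptide[j])
      at_start <- b$b_start == 1L
      at_end <- b$b_start + b$len - 1L == gene_len
      region <- if (at_start && at_end) "complete"
        else if (at_end) "carboxyl-terminal"
        else if (at_start) "amino-terminal"
        else "internal"
      g_start <- ((win_start + orfs$start[i] - 2L) %% n) + 1L
      g_end <- ((win_start + orfs$end[i] - 2L) %% n) + 1L
      tibble::tibble(
        position = pos,
        orf_start = g_start, orf_end = g_end, strand = orfs$strand[i],
        n_aa = orfs$n_aa[i], peptide = orfs$peptide[i],
        matched_gene = gene_peptides$gene_id[j],
        n_identical_aa = b$len,
        n_extra_aa = orfs$n_aa[i] - b$len,
        matched_region = region
      )
    })
  }

  out <- purrr::map_dfr(unique(breakpoints$position), call_one)
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble::tibble(
      position = integer(), orf_start = integer(), orf_end = integer(),
      strand = character(), n_aa = integer(), peptide = character(),
      matched_gene = character(), n_identical_aa = integer(),
      n_extra_aa = integer(), matched_region = character()
    ))
  }
  out
}
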