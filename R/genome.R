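#' Construct a circular genome object
#'
#' The coordinate frame for the whole package: a single DNA sequence with
#' circular topology. All coordinates reported against it are 1-based and
#' inclusive; features are allowed to wrap past the origin.
#'
#' @param sequence Character scalar over the alphabet A/C/G/T.
#' @param id Sequence identifier.
#' @param circular Logical; almost always `TRUE` (plant mitochondrial master
#'   circles and subgenomic circles are circular molecules).
#'
#' @return An object of class `circular_genome` with fields `id`, `sequence`
#'   and `circular`.
#' @export
#' @examples
#' g <- circular_genome("ACGTACGT", id = "toy")
#' genome_length(g)
circular_genome <- function(sequence, id = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) {
    stop("circular_genome: sequence must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("circular_genome: sequence must be over {A,C,G,T}", call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, circular = isTRUE(circular)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  n <- genome_length(x)
  head_seq <- substr(x$sequence, 1L, min(40L, n))
  cat(sprintf(
    "<circular_genome> %s: %s bp%s\n  %s%s\n",
    x$id, format(n, big.mark = ","),
    if (x$circular) " (circular)" else " (linear)",
    head_seq, if (n > 40L) "..." else ""
  ))
  invisible(x)
}

#' Genome length in bases
#' @param genome A `circular_genome`.
#' @return Integer length.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "circular_genome"))
  nchar(genome$sequence)
}

#' Extract a (possibly origin-spanning) subsequence
#'
#' On a circular genome `start` may exceed `end + 1` positions past the
#' origin: `subseq_circular(g, n - 1, 4)` returns the last two bases joined
#' to the first four. `length` may be given instead of `end`.
#'
#' @param genome A `circular_genome`.
#' @param start,end 1-based inclusive coordinates.
#' @param length Alternative to `end`.
#' @return Character scalar.
#' @export
subseq_circular <- function(genome, start, end = NULL, length = NULL) {
  n <- genome_length(genome)
  if (is.null(end)) {
    stopifnot(!is.null(length))
    end <- start + length - 1L
  }
  stopifnot(start >= 1L)
  if (end <= n && start <= n) {
    return(substr(genome$sequence, start, end))
  }
  if (!genome$circular) {
    stop("subseq_circular: coordinates beyond the end of a linear sequence",
         call. = FALSE)
  }
  idx <- ((seq.int(start, end) - 1L) %% n) + 1L
  paste(strsplit(genome$sequence, "", fixed = TRUE)[[1]][idx], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] that keeps plain
#' character vectors in and out.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a DNA string with the standard genetic code
#'
#' Plant mitochondria use the standard code for the codons handled here, so
#' translation goes through [Biostrings::GENETIC_CODE]. Stop codons
#' translate to `*`.
#'
#' @param x Character scalar, length divisible by 3.
#' @return Character scalar peptide.
#' @export
translate_dna <- function(x) {
  stopifnot(nchar(x) %% 3L == 0L)
  if (nchar(x) == 0L) return("")
  codons <- substring(x, seq(1L, nchar(x), by = 3L), seq(3L, nchar(x), by = 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Generate a random genome with i.i.d. uniform base composition
#'
#' @param length Genome length in bases.
#' @param id Sequence identifier.
#' @param circular Logical.
#' @return A `circular_genome`.
#' @export
random_genome <- function(length, id = "sim", circular = TRUE) {
  circular_genome(
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""),
    id = id, circular = circular
  )
}

#' Replace genome bases in place
#'
#' Overwrites the bases from `start` for the length of `piece` (wrapping
#' past the origin on a circular genome). Used to plant features.
#'
#' @param genome A `circular_genome`.
#' @param start 1-based start position.
#' @param piece Replacement sequence.
#' @return The modified `circular_genome`.
#' @export
overwrite_segment <- function(genome, start, piece) {
  n <- genome_length(genome)
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  idx <- ((seq.int(start, start + nchar(piece) - 1L) - 1L) %% n) + 1L
  chars[idx] <- strsplit(piece, "", fixed = TRUE)[[1]]
  genome$sequence <- paste(chars, collapse = "")
  genome
}

#' Are two sequences the same circular molecule?
#'
#' `TRUE` when `b` is a rotation, or a reverse-complement rotation, of `a`
#' -- the equivalence that matters when comparing reconstructed circles.
#'
#' @param a,b Character scalars.
#' @return Logical.
#' @export
same_circle_sequence <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  doubled <- paste0(a, a)
  grepl(b, doubled, fixed = TRUE) || grepl(revcomp(b), doubled, fixed = TRUE)
}
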