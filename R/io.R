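#' Read and write the package's file formats
#'
#' FASTA goes through Biostrings, GFF3 through rtracklayer, tabular
#' formats through readr, truth files through jsonlite. All coordinates on
#' disk are 1-based inclusive.
#'
#' @name mitomosaic-io
NULL

#' @describeIn mitomosaic-io Write one or more genomes/contigs to FASTA.
#' @param x A [circular_genome()], a list of them, or a tibble with
#'   `contig_id` and `sequence`.
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "circular_genome")) x <- list(x)
  if (is.data.frame(x)) {
    set <- Biostrings::DNAStringSet(stats::setNames(x$sequence, x$contig_id))
  } else {
    set <- Biostrings::DNAStringSet(stats::setNames(
      vapply(x, function(g) g$sequence, ""),
      vapply(x, function(g) g$id, "")
    ))
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @describeIn mitomosaic-io Read a FASTA file; one record becomes a
#'   `circular_genome`, several become a contig tibble.
#' @param circular Treat a single record as circular.
#' @export
read_fasta <- function(path, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 1L) {
    return(circular_genome(as.character(set[[1]]), id = names(set)[1],
                           circular = circular))
  }
  tibble::tibble(
    contig_id = names(set),
    sequence = unname(as.character(set)),
    length = Biostrings::width(set)
  )
}

#' @describeIn mitomosaic-io Write gene annotations as GFF3.
#' @param genes Tibble `gene_id`, `start`, `end`, `strand` (plus optional
#'   `type`).
#' @param seqname Sequence name recorded in column 1.
#' @export
write_genes_gff3 <- function(genes, path, seqname = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    type = if ("type" %in% names(genes)) genes$type else "gene",
    ID = genes$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @describeIn mitomosaic-io Read a GFF3 gene annotation into the tibble
#'   layout used across the package.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble::tibble(
    gene_id = if (!is.null(gr$ID)) as.character(gr$ID)
      else sprintf("gene%02d", seq_along(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = if (!is.null(gr$type)) as.character(gr$type) else "gene"
  )
}

#' @describeIn mitomosaic-io Write scaffold links (`contig_a`, `end_a`,
#'   `contig_b`, `end_b`, `support`) as TSV.
#' @param links Links tibble.
#' @export
write_links_tsv <- function(links, path) {
  readr::write_tsv(links, path)
  invisible(path)
}

#' @describeIn mitomosaic-io Read a scaffold-links TSV.
#' @export
read_links_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @describeIn mitomosaic-io Write per-contig depths as TSV.
#' @param contigs Contig tibble (columns besides `sequence` are written).
#' @export
write_depths_tsv <- function(contigs, path) {
  readr::write_tsv(contigs[, setdiff(names(contigs), "sequence")], path)
  invisible(path)
}

#' @describeIn mitomosaic-io Write a pileup tibble
#'   (`position`, `ref_base`, `A`, `C`, `G`, `T`) as TSV.
#' @param pileup Pileup tibble.
#' @export
write_pileup_tsv <- function(pileup, path) {
  readr::write_tsv(pileup, path)
  invisible(path)
}

#' @describeIn mitomosaic-io Read a pileup TSV.
#' @export
read_pileup_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    position = readr::col_integer(),
                    ref_base = readr::col_character(),
                    .default = readr::col_integer()
                  ))
}

#' @describeIn mitomosaic-io Write a repeat list as TSV.
#' @param pairs Repeat tibble from [find_repeats()].
#' @export
write_repeats_tsv <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' @describeIn mitomosaic-io Write an alignment table in the 7-column
#'   dialect read by [read_alignment_table()].
#' @param records Alignment tibble.
#' @export
write_alignment_table <- function(records, path) {
  cols <- c("query_id", "pct_identity", "align_length", "q_start", "q_end",
            "s_start", "s_end", "evalue")
  readr::write_tsv(records[, intersect(cols, names(records))], path)
  invisible(path)
}

#' @describeIn mitomosaic-io Write a simulation truth list as JSON.
#' @param truth Truth list from the simulator.
#' @export
write_truth_json <- function(truth, path) {
  truth <- purrr::map(truth, function(x) {
    if (is.data.frame(x)) x[, !vapply(x, is.list, TRUE), drop = FALSE] else x
  })
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @describeIn mitomosaic-io Read a truth JSON back into tibbles.
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::map(raw, function(x) {
    if (is.data.frame(x)) tibble::as_tibble(x) else x
  })
}
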