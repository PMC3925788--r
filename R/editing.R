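#' Call C-to-U RNA-editing sites from paired genomic and RNA pileups
#'
#' A site is an editing candidate when the genomic consensus is a cytidine
#' (a guanine on the reference strand for positions inside annotated
#' minus-strand genes: the edit is then read as genomic G / RNA A) and the
#' RNA shows the edited base (T, or A on the minus strand) at a fraction
#' passing `min_edit_fraction` in at least one sample. Per-sample edit
#' fractions are recorded for every called site so that differential
#' editing between samples can be read off directly.
#'
#' Positions outside annotated genes are tested on the plus strand only.
#'
#' @param genomic Tibble pileup of the genomic DNA: `position`, `ref_base`,
#'   `A`, `C`, `G`, `T` read counts.
#' @param rna Named list of RNA pileup tibbles in the same layout, one per
#'   sample, covering the same positions as `genomic`.
#' @param genes Optional tibble `gene_id`, `start`, `end`, `strand` used
#'   for strand-aware calling (and carried through to consequences).
#' @param min_genomic_depth,min_rna_depth Minimum read depths (default 10).
#' @param min_c_purity Minimum fraction of genomic reads supporting the
#'   cytidine consensus (default 0.9).
#' @param min_edit_fraction Minimum RNA edited-base fraction in at least
#'   one sample (default 0.1).
#' @return Tibble with one row per called site: `position`, `strand`,
#'   `gene_id` (`NA` outside genes), `genomic_depth`, `c_purity`, and a
#'   nested `per_sample` tibble (`sample`, `depth`, `edit_fraction`).
#' @export
call_editing_sites <- function(genomic, rna, genes = NULL,
                               min_genomic_depth = 10L, min_rna_depth = 10L,
                               min_c_purity = 0.9, min_edit_fraction = 0.1) {
  stopifnot(is.list(rna), length(rna) >= 1, !is.null(names(rna)))
  for (nm in names(rna)) {
    if (nrow(rna[[nm]]) != nrow(genomic) ||
        !identical(rna[[nm]]$position, genomic$position)) {
      stop("call_editing_sites: pileup positions for sample '", nm,
           "' do not match the genomic pileup", call. = FALSE)
    }
  }

  pos <- genomic$position
  strand <- rep("+", length(pos))
  gene_id <- rep(NA_character_, length(pos))
  if (!is.null(genes) && nrow(genes)) {
    for (i in seq_len(nrow(genes))) {
      inside <- pos >= genes$start[i] & pos <= genes$end[i]
      strand[inside] <- genes$strand[i]
      gene_id[inside] <- genes$gene_id[i]
    }
  }

  gdepth <- genomic$A + genomic$C + genomic$G + genomic$T
  ref_count <- ifelse(strand == "-", genomic$G, genomic$C)
  purity <- ifelse(gdepth > 0, ref_count / gdepth, 0)
  genomic_ok <- gdepth >= min_genomic_depth & purity >= min_c_purity

  frac_by_sample <- purrr::map(rna, function(p) {
    depth <- p$A + p$C + p$G + p$T
    edited <- ifelse(strand == "-", p$A, p$T)
    list(depth = depth,
         frac = ifelse(depth > 0, edited / depth, 0))
  })
  passes <- purrr::map(frac_by_sample, function(f) {
    f$depth >= min_rna_depth & f$frac >= min_edit_fraction
  })
  any_pass <- Reduce(`|`, passes)
  called <- which(genomic_ok & any_pass)
  if (!length(called)) {
    return(tibble::tibble(position = integer(), strand = character(),
                          gene_id = character(), genomic_depth = integer(),
                          c_purity = double(), per_sample = list()))
  }

  per_sample <- purrr::map(called, function(i) {
    tibble::tibble(
      sample = names(rna),
      depth = unname(vapply(frac_by_sample, function(f) f$depth[i], 1)),
      edit_fraction = unname(vapply(frac_by_sample, function(f) f$frac[i], 1))
    )
  })
  tibble::tibble(
    position = pos[called],
    strand = strand[called],
    gene_id = gene_id[called],
    genomic_depth = gdepth[called],
    c_purity = purity[called],
    per_sample = per_sample
  )
}

#' Annotate editing sites with their codon consequence
#'
#' Locates each site's codon in gene orientation, substitutes the edited
#' base (C to T on the coding strand) and translates both codons with the
#' standard genetic code. Sites outside annotated genes are left
#' unannotated. Genes whose length is not divisible into codons raise an
#' error.
#'
#' @param sites Tibble from [call_editing_sites()].
#' @param genes Tibble `gene_id`, `start`, `end`, `strand` of single-exon
#'   coding regions.
#' @param genome The [circular_genome()] the pileups were computed on.
#' @return `sites` with `codon_index`, `codon_pos`, `ref_aa`, `edited_aa`
#'   and `consequence` (`synonymous`, `nonsynonymous`, `stop_gained`)
#'   columns added.
#' @export
annotate_editing_consequence <- function(sites, genes, genome) {
  stopifnot(inherits(genome, "circular_genome"))
  ann <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    blank <- tibble::tibble(codon_index = NA_integer_, codon_pos = NA_integer_,
                            ref_aa = NA_character_, edited_aa = NA_character_,
                            consequence = NA_character_)
    gid <- sites$gene_id[i]
    if (is.na(gid)) return(blank)
    g <- genes[genes$gene_id == gid, ]
    glen <- g$end - g$start + 1L
    if (glen %% 3L != 0L) {
      stop("annotate_editing_consequence: gene ", gid,
           " length is not divisible into codons", call. = FALSE)
    }
    offset <- if (g$strand == "+") sites$position[i] - g$start
      else g$end - sites$position[i]
    codon_index <- offset %/% 3L + 1L
    codon_pos <- offset %% 3L + 1L
    cds <- substr(genome$sequence, g$start, g$end)
    if (g$strand == "-") cds <- revcomp(cds)
    codon <- substr(cds, 3L * codon_index - 2L, 3L * codon_index)
    if (substr(codon, codon_pos, codon_pos) != "C") {
      return(blank)  # not a coding-strand cytidine; no C-to-U consequence
    }
    edited <- codon
    substr(edited, codon_pos, codon_pos) <- "T"
    ref_aa <- unname(Biostrings::GENETIC_CODE[codon])
    edited_aa <- unname(Biostrings::GENETIC_CODE[edited])
    consequence <- if (edited_aa == ref_aa) "synonymous"
      else if (edited_aa == "*") "stop_gained"
      else "nonsynonymous"
    tibble::tibble(codon_index = codon_index, codon_pos = codon_pos,
                   ref_aa = ref_aa, edited_aa = edited_aa,
                   consequence = consequence)
  })
  dplyr::bind_cols(sites[, setdiff(names(sites), names(ann))], ann)
}

#' Summarize annotated editing sites
#'
#' Tallies amino-acid change classes across annotated sites, the way
#' editing surveys report their spectra (e.g. serine-to-leucine as the
#' most common class), and counts nonsynonymous and stop-creating events.
#'
#' @param sites Tibble from [annotate_editing_consequence()].
#' @return An `editing_summary` object; [generics::tidy()] returns the
#'   per-class tally, [generics::glance()] the one-row totals.
#' @export
summarize_editing <- function(sites) {
  annotated <- sites[!is.na(sites$consequence), , drop = FALSE]
  tally <- annotated |>
    dplyr::filter(.data$consequence != "synonymous") |>
    dplyr::count(.data$ref_aa, .data$edited_aa, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  out <- list(
    n_sites = nrow(sites),
    n_annotated = nrow(annotated),
    n_synonymous = sum(annotated$consequence == "synonymous"),
    n_nonsynonymous = sum(annotated$consequence == "nonsynonymous"),
    n_stop_created = sum(annotated$consequence == "stop_gained"),
    tally = tally
  )
  class(out) <- "editing_summary"
  out
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf(
    "<editing_summary> %d sites (%d annotated): %d nonsynonymous, %d synonymous, %d stop-creating\n",
    x$n_sites, x$n_annotated, x$n_nonsynonymous, x$n_synonymous,
    x$n_stop_created))
  if (nrow(x$tally)) {
    top <- utils::head(x$tally, 3L)
    cat("  top classes:",
        paste(sprintf("%s->%s (%d)", top$ref_aa, top$edited_aa, top$n),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname summarize_editing
#' @param x An `editing_summary`.
#' @param ... Unused.
#' @method tidy editing_summary
#' @export
tidy.editing_summary <- function(x, ...) x$tally

#' @rdname summarize_editing
#' @method glance editing_summary
#' @export
glance.editing_summary <- function(x, ...) {
  tibble::tibble(
    n_sites = x$n_sites, n_annotated = x$n_annotated,
    n_synonymous = x$n_synonymous, n_nonsynonymous = x$n_nonsynonymous,
    n_stop_created = x$n_stop_created
  )
}

#' Sites edited in every sample except one
#'
#' Reports the sites where the focal sample lacks editing that all other
#' samples show -- the pattern that singles out a sterile cytotype against
#' its fertile relatives.
#'
#' @param sites Tibble from [call_editing_sites()] (the nested `per_sample`
#'   fractions are used).
#' @param focal_sample Sample name to contrast against the rest.
#' @param threshold Edit fraction at or above which a sample counts as
#'   edited (default 0.1).
#' @param min_depth Minimum RNA depth for a sample's fraction to be
#'   trusted.
#' @return The subset of `sites` edited (fraction >= threshold) in every
#'   non-focal sample and unedited (fraction < threshold) in the focal
#'   sample. Errors if the focal sample is absent.
#' @export
differential_editing <- function(sites, focal_sample, threshold = 0.1,
                                 min_depth = 10L) {
  if (nrow(sites) == 0L) return(sites)
  samples <- sites$per_sample[[1]]$sample
  if (!focal_sample %in% samples) {
    stop("differential_editing: focal sample '", focal_sample,
         "' not present", call. = FALSE)
  }
  if (length(samples) < 2L) {
    stop("differential_editing: need at least two samples", call. = FALSE)
  }
  keep <- vapply(sites$per_sample, function(ps) {
    focal <- ps[ps$sample == focal_sample, ]
    others <- ps[ps$sample != focal_sample, ]
    all(others$depth >= min_depth & others$edit_fraction >= threshold) &&
      focal$depth >= min_depth && focal$edit_fraction < threshold
  }, TRUE)
  sites[keep, , drop = FALSE]
}

#' Plot the amino-acid change spectrum of an editing summary
#'
#' @param object An `editing_summary`.
#' @param ... Unused.
#' @return A ggplot bar chart of change-class counts.
#' @method autoplot editing_summary
#' @export
autoplot.editing_summary <- function(object, ...) {
  df <- dplyr::mutate(object$tally,
                      class = paste0(.data$ref_aa, "→", .data$edited_aa))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$class, -.data$n), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Amino-acid change", y = "Sites") +
    ggplot2::theme_minimal()
}
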