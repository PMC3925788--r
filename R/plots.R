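#' Plot split alignments per query
#'
#' Draws each query's alignment segments as query-versus-subject diagonal
#' lines, the standard dot-plot view in which a colinear contig is one
#' staircase and a rearranged contig jumps between distant subject loci or
#' switches strand.
#'
#' @param object A `rearrangement_calls` object from [chain_alignments()].
#' @param ... Unused.
#' @return A ggplot, faceted by query (free scales).
#' @method autoplot rearrangement_calls
#' @export
autoplot.rearrangement_calls <- function(object, ...) {
  seg <- object$segments
  if (is.null(seg) || nrow(seg) == 0L) {
    stop("autoplot: no segments to plot", call. = FALSE)
  }
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$q_start, xend = .data$q_end,
      y = .data$s_start, yend = .data$s_end,
      colour = .data$strand
    ), linewidth = 1) +
    ggplot2::facet_wrap(~query_id, scales = "free") +
    ggplot2::labs(x = "Query position (bp)", y = "Subject position (bp)",
                  colour = "Strand") +
    ggplot2::theme_minimal()
}

#' Plot contig depths with the nuclear-copy classification
#'
#' @param contigs Classified contig tibble from [classify_contigs()].
#' @return A ggplot of per-contig depth on a log scale, coloured by class,
#'   with the reference depth drawn as a dashed line.
#' @export
plot_contig_depths <- function(contigs) {
  stopifnot("class" %in% names(contigs))
  ref <- attr(contigs, "ref_depth")
  p <- ggplot2::ggplot(contigs, ggplot2::aes(
    x = stats::reorder(.data$contig_id, -.data$depth),
    y = .data$depth, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Contig", y = "Mean read depth", fill = "Class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(ref)) {
    p <- p + ggplot2::geom_hline(yintercept = ref, linetype = "dashed")
  }
  p
}
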