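#' Classify contigs as mitochondrial or nuclear-encoded copies by read depth
#'
#' Nuclear insertions of mitochondrial sequence (NUMT-like contigs) assemble
#' alongside the true organellar contigs but at a small fraction of their
#' read depth, despite similar GC content. Classification is therefore by
#' depth alone: a contig is a `nuclear_copy` when its mean depth falls below
#' `depth_ratio_threshold` times a reference depth. The reference is the
#' median depth of the mitochondrial set, computed iteratively: first over
#' all contigs, then once more after removing the low-depth outliers.
#'
#' @param contigs Tibble with at least `contig_id` and `depth` (mean read
#'   depth) columns.
#' @param depth_ratio_threshold Fraction of the reference depth below which
#'   (strictly) a contig is called a nuclear copy. Default 0.10.
#' @return The input tibble with a `class` column (`"mito"` or
#'   `"nuclear_copy"`) and a `ref_depth` attribute. Errors if every contig
#'   would be classified as a nuclear copy (degenerate reference).
#' @export
classify_contigs <- function(contigs, depth_ratio_threshold = 0.10) {
  stopifnot(nrow(contigs) >= 1, all(c("contig_id", "depth") %in% names(contigs)))
  d <- contigs$depth
  ref <- stats::median(d)
  keep <- d >= depth_ratio_threshold * ref
  if (!any(keep)) {
    stop("classify_contigs: all contigs fall below the depth threshold",
         call. = FALSE)
  }
  ref2 <- stats::median(d[keep])
  cls <- ifelse(d < depth_ratio_threshold * ref2, "nuclear_copy", "mito")
  if (all(cls == "nuclear_copy")) {
    stop("classify_contigs: degenerate reference (no mitochondrial contigs)",
         call. = FALSE)
  }
  out <- dplyr::mutate(contigs, class = cls)
  attr(out, "ref_depth") <- ref2
  out
}

normalize_end <- function(x) {
  x <- as.character(x)
  x[x %in% c("3p", "3'", "3")] <- "3'"
  x[x %in% c("5p", "5'", "5")] <- "5'"
  if (!all(x %in% c("3'", "5'"))) {
    stop("contig ends must be 3' or 5'", call. = FALSE)
  }
  x
}

#' Build an oriented contig graph from scaffold links
#'
#' Nodes are contigs; edges join a specific end (3' or 5') of one contig to
#' a specific end of another, as reported by scaffold links. Duplicate link
#' records collapse to a single edge with summed support.
#'
#' @param contigs Tibble with `contig_id` and optionally `length`, `depth`,
#'   `gc`, `sequence`.
#' @param links Tibble with `contig_a`, `end_a`, `contig_b`, `end_b`,
#'   `support` (ends given as `3'`/`5'`, `3p`/`5p` also accepted).
#' @return A `contig_graph`: list with tibbles `nodes` and `edges`.
#' @export
build_contig_graph <- function(contigs, links) {
  stopifnot("contig_id" %in% names(contigs))
  needed <- c("contig_a", "end_a", "contig_b", "end_b")
  stopifnot(all(needed %in% names(links)))
  if (!"support" %in% names(links)) links$support <- 1L
  bad <- setdiff(c(links$contig_a, links$contig_b), contigs$contig_id)
  if (length(bad)) {
    offending <- links[links$contig_a %in% bad | links$contig_b %in% bad, ]
    stop("build_contig_graph: links reference unknown contig(s): ",
         paste(unique(bad), collapse = ", "), " (", nrow(offending),
         " record(s))", call. = FALSE)
  }
  links <- dplyr::mutate(links,
    end_a = normalize_end(.data$end_a),
    end_b = normalize_end(.data$end_b)
  )
  # canonical endpoint order so (a,ea)-(b,eb) and (b,eb)-(a,ea) collapse
  swap <- paste(links$contig_a, links$end_a) > paste(links$contig_b, links$end_b)
  edges <- tibble::tibble(
    contig_a = ifelse(swap, links$contig_b, links$contig_a),
    end_a = ifelse(swap, links$end_b, links$end_a),
    contig_b = ifelse(swap, links$contig_a, links$contig_b),
    end_b = ifelse(swap, links$end_a, links$end_b),
    support = links$support
  ) |>
    dplyr::group_by(.data$contig_a, .data$end_a, .data$contig_b, .data$end_b) |>
    dplyr::summarise(support = sum(.data$support), .groups = "drop")
  structure(list(nodes = tibble::as_tibble(contigs), edges = edges),
            class = "contig_graph")
}

#' @export
print.contig_graph <- function(x, ...) {
  cat(sprintf("<contig_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
glance.contig_graph <- function(x, ...) {
  prof <- degree_profile(x)
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_simple = sum(prof$n_contigs[prof$end_degree == 1L]),
    max_end_degree = max(prof$end_degree)
  )
}

#' Tally contigs by their maximum per-end edge multiplicity
#'
#' A contig whose 3' and 5' ends each carry a single edge sits in exactly
#' one place in the master circle; a contig with two or three edges on an
#' end is a repeat shared between loops and multiplies the number of
#' possible configurations.
#'
#' @param graph A `contig_graph`.
#' @return Tibble `end_degree`, `n_contigs`; the per-contig degrees are in
#'   attribute `per_contig`.
#' @export
degree_profile <- function(graph) {
  stopifnot(inherits(graph, "contig_graph"))
  ends <- c(paste(graph$edges$contig_a, graph$edges$end_a),
            paste(graph$edges$contig_b, graph$edges$end_b))
  per <- tibble::tibble(
    contig_id = graph$nodes$contig_id,
    deg_3p = as.integer(table(factor(ends,
      levels = paste(graph$nodes$contig_id, "3'")))[paste(graph$nodes$contig_id, "3'")]),
    deg_5p = as.integer(table(factor(ends,
      levels = paste(graph$nodes$contig_id, "5'")))[paste(graph$nodes$contig_id, "5'")])
  )
  per$end_degree <- pmax(per$deg_3p, per$deg_5p)
  out <- dplyr::count(per, .data$end_degree, name = "n_contigs")
  attr(out, "per_contig") <- per
  out
}

# exit/entry end of a contig traversed in a given orientation
exit_end <- function(orient) ifelse(orient == "+", "3'", "5'")
entry_end <- function(orient) ifelse(orient == "+", "5'", "3'")

# adjacency list: for each (contig, orientation) state, the states reachable
# through one edge, sorted for deterministic search order
walk_adjacency <- function(graph) {
  e <- graph$edges
  both <- dplyr::bind_rows(
    e,
    tibble::tibble(contig_a = e$contig_b, end_a = e$end_b,
                   contig_b = e$contig_a, end_b = e$end_a,
                   support = e$support)
  )
  states <- expand.grid(contig = sort(graph$nodes$contig_id),
                        orient = c("+", "-"), stringsAsFactors = FALSE)
  adj <- vector("list", nrow(states))
  names(adj) <- paste0(states$contig, states$orient)
  for (i in seq_len(nrow(states))) {
    cid <- states$contig[i]; o <- states$orient[i]
    out_edges <- both[both$contig_a == cid & both$end_a == exit_end(o), ]
    if (nrow(out_edges) == 0L) { adj[[i]] <- character(0); next }
    nxt <- c(
      paste0(out_edges$contig_b[out_edges$end_b == "5'"], "+"),
      paste0(out_edges$contig_b[out_edges$end_b == "3'"], "-")
    )
    adj[[i]] <- sort(unique(nxt))
  }
  adj
}

#' Traverse the contig graph into a master circle
#'
#' Finds a closed walk through the oriented contig graph that uses every
#' contig at least once -- the master-circle reconstruction. The walk is the
#' minimum-length such walk, found by iterative-deepening depth-first
#' search with memoized dead ends; ties are broken deterministically by
#' taking the lexicographically smallest contig-id/orientation sequence
#' starting from the smallest contig id in + orientation. Repeat contigs
#' may appear several times and in either orientation.
#'
#' @param graph A `contig_graph`. Must be connected when the two ends of
#'   each contig are merged; otherwise the graph represents independent
#'   subgenomic circles and an error lists the connected components.
#' @param max_steps Search cap on walk length (default `2 * n_nodes + 4`).
#' @return A `master_circle_walk`: tibble `step`, `contig_id`, `orientation`
#'   with attribute `closed = TRUE`.
#' @export
traverse_master_circle <- function(graph, max_steps = NULL) {
  stopifnot(inherits(graph, "contig_graph"))
  ids <- sort(graph$nodes$contig_id)
  n <- length(ids)
  if (is.null(max_steps)) max_steps <- 2L * n + 4L

  g_merged <- igraph::graph_from_data_frame(
    graph$edges[, c("contig_a", "contig_b")], directed = FALSE,
    vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g_merged)
  if (comp$no > 1L) {
    members <- split(names(comp$membership), comp$membership)
    stop("traverse_master_circle: graph is disconnected; no master circle. ",
         "Components: ",
         paste(vapply(members, function(m) paste(m, collapse = "+"), ""),
               collapse = " | "),
         call. = FALSE)
  }

  adj <- walk_adjacency(graph)
  start <- paste0(ids[1], "+")
  state_contig <- function(st) substr(st, 1L, nchar(st) - 1L)

  for (target_len in seq.int(n, max_steps)) {
    memo <- new.env(parent = emptyenv())
    result <- NULL
    dfs <- function(path, visited, remaining) {
      if (remaining == 0L) {
        # closed: an edge must join the last step back to the first
        if (start %in% adj[[path[length(path)]]] && length(visited) == n) {
          result <<- path
          return(TRUE)
        }
        return(FALSE)
      }
      if (length(setdiff(ids, visited)) > remaining) return(FALSE)
      key <- paste(path[length(path)], remaining,
                   paste(sort(visited), collapse = ","), sep = "|")
      if (exists(key, envir = memo, inherits = FALSE)) return(FALSE)
      for (nxt in adj[[path[length(path)]]]) {
        if (dfs(c(path, nxt), union(visited, state_contig(nxt)),
                remaining - 1L)) {
          return(TRUE)
        }
      }
      memo[[key]] <- TRUE
      FALSE
    }
    if (dfs(start, state_contig(start), target_len - 1L)) {
      steps <- result
      walk <- tibble::tibble(
        step = seq_along(steps),
        contig_id = vapply(steps, state_contig, ""),
        orientation = substr(steps, nchar(steps), nchar(steps))
      )
      attr(walk, "closed") <- TRUE
      class(walk) <- c("master_circle_walk", class(walk))
      return(walk)
    }
  }
  stop("traverse_master_circle: no closed covering walk within ", max_steps,
       " steps", call. = FALSE)
}

#' Validate a master-circle walk against its graph
#'
#' Independent check of the walk invariants, sharing no code with the
#' search: every contig must appear at least once, and every consecutive
#' step pair (including last back to first) must be joined by an edge whose
#' ends are consistent with the two orientations.
#'
#' @param walk A `master_circle_walk` (or tibble with `contig_id`,
#'   `orientation`).
#' @param graph The `contig_graph` the walk was found on.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_walk <- function(walk, graph) {
  ids <- graph$nodes$contig_id
  if (!setequal(intersect(ids, walk$contig_id), ids)) {
    stop("validate_walk: walk does not cover every contig", call. = FALSE)
  }
  m <- nrow(walk)
  edge_strings <- c(
    paste(graph$edges$contig_a, graph$edges$end_a,
          graph$edges$contig_b, graph$edges$end_b),
    paste(graph$edges$contig_b, graph$edges$end_b,
          graph$edges$contig_a, graph$edges$end_a)
  )
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    want <- paste(
      walk$contig_id[i], ifelse(walk$orientation[i] == "+", "3'", "5'"),
      walk$contig_id[j], ifelse(walk$orientation[j] == "+", "5'", "3'")
    )
    if (!want %in% edge_strings) {
      stop(sprintf("validate_walk: steps %d -> %d are not joined by an edge",
                   i, j), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Count distinct minimal master-circle configurations
#'
#' Enumerates the distinct minimum-length closed covering walks of the
#' graph, up to rotation and reflection, stopping early at `cap`. Complex
#' scaffold graphs with repeat contigs shared between loops admit many
#' configurations.
#'
#' @param graph A `contig_graph`.
#' @param cap Stop counting at this many distinct configurations.
#' @return Integer count; if the enumeration was capped the value equals
#'   `cap` and carries attribute `capped = TRUE`.
#' @export
count_configurations <- function(graph, cap = 1000L) {
  base <- traverse_master_circle(graph)
  target_len <- nrow(base)
  ids <- sort(graph$nodes$contig_id)
  n <- length(ids)
  adj <- walk_adjacency(graph)
  start <- paste0(ids[1], "+")
  state_contig <- function(st) substr(st, 1L, nchar(st) - 1L)

  canonical <- new.env(parent = emptyenv())
  capped <- FALSE

  flip <- function(states) {
    o <- substr(states, nchar(states), nchar(states))
    paste0(substr(states, 1L, nchar(states) - 1L), ifelse(o == "+", "-", "+"))
  }
  canon_key <- function(states) {
    variants <- character(0)
    for (seqv in list(states, rev(flip(states)))) {
      hits <- which(seqv == start)
      for (h in hits) {
        rot <- c(seqv[h:length(seqv)], seqv[seq_len(h - 1L)])
        variants <- c(variants, paste(rot, collapse = " "))
      }
    }
    min(variants)
  }

  dfs <- function(path, visited, remaining) {
    if (capped) return(invisible(NULL))
    if (remaining == 0L) {
      if (start %in% adj[[path[length(path)]]] && length(visited) == n) {
        canonical[[canon_key(path)]] <- TRUE
        if (length(ls(canonical)) >= cap) capped <<- TRUE
      }
      return(invisible(NULL))
    }
    if (length(setdiff(ids, visited)) > remaining) return(invisible(NULL))
    for (nxt in adj[[path[length(path)]]]) {
      dfs(c(path, nxt), union(visited, state_contig(nxt)), remaining - 1L)
      if (capped) break
    }
    invisible(NULL)
  }
  dfs(start, state_contig(start), target_len - 1L)
  out <- length(ls(canonical))
  if (capped) {
    out <- as.integer(cap)
    attr(out, "capped") <- TRUE
  }
  out
}

#' Stitch a master-circle walk into a genome sequence
#'
#' Concatenates contig sequences in walk order, reverse-complementing
#' minus-orientation steps. When the contigs tile the circle without
#' overlap the result is the reconstructed master circle (a rotation, or
#' reverse-complement rotation, of the original molecule).
#'
#' @param walk A `master_circle_walk`.
#' @param contigs Tibble with `contig_id` and `sequence`.
#' @param id Identifier for the stitched genome.
#' @return A [circular_genome()].
#' @export
stitch_walk <- function(walk, contigs, id = "master_circle") {
  seqs <- contigs$sequence[match(walk$contig_id, contigs$contig_id)]
  if (anyNA(seqs)) {
    stop("stitch_walk: walk references contigs without sequence", call. = FALSE)
  }
  oriented <- ifelse(walk$orientation == "+", seqs, revcomp(seqs))
  circular_genome(paste(oriented, collapse = ""), id = id)
}
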