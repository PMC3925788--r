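# Independent oracles, written directly from the definitions and sharing no
# code with the package implementations they check.

# --- maximal repeat pairs: exhaustive enumeration over every diagonal -----
# A maximal window on a circular match vector starts right after a blocking
# mismatch and runs as far as the mismatch budget allows (cumulative-sum /
# findInterval mechanics, unlike the package's mismatch-position indexing).
oracle_windows <- function(m, k, n, min_length) {
  t <- sum(!m)
  if (t <= k) {
    if (n >= min_length) return(data.frame(start = 1L, len = n))
    return(data.frame(start = integer(), len = integer()))
  }
  m2 <- rep(m, 2L)
  cs <- c(0L, cumsum(!m2))
  prev_idx <- ifelse(seq_len(n) == 1L, n, seq_len(n) - 1L)
  starts <- which(!m2[prev_idx])
  if (!length(starts)) return(data.frame(start = integer(), len = integer()))
  e <- findInterval(cs[starts] + k + 0.5, cs) - 1L
  len <- e - starts + 1L
  keep <- len >= min_length
  data.frame(start = starts[keep], len = len[keep])
}

oracle_repeats <- function(seq, min_length, max_mismatches) {
  n <- nchar(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  cv <- strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]
  norm <- function(x) ((x - 1L) %% n) + 1L
  rows <- list()
  for (d in seq_len(n - 1L)) {
    m <- v == v[norm(seq_len(n) + d)]
    w <- oracle_windows(m, max_mismatches, n, min_length)
    if (nrow(w)) {
      a <- norm(w$start); b <- norm(w$start + d)
      rows[[length(rows) + 1L]] <- data.frame(
        start1 = pmin(a, b), start2 = pmax(a, b), length = w$len,
        orientation = "direct"
      )
    }
  }
  for (cc in seq_len(n)) {
    m <- v == cv[norm(cc - seq_len(n))]
    w <- oracle_windows(m, max_mismatches, n, min_length)
    if (nrow(w)) {
      a <- norm(w$start)
      b <- norm(cc - (w$start + w$len - 1L))
      keep <- a != b
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          start1 = pmin(a, b)[keep], start2 = pmax(a, b)[keep],
          length = w$len[keep], orientation = "inverted"
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(start1 = integer(), start2 = integer(),
                      length = integer(), orientation = character()))
  }
  unique(out[order(out$start1, out$start2, out$orientation), ])
}

# normalise a repeat table (package or oracle) to a comparable key set
repeat_keys <- function(df) {
  sort(paste(df$start1, df$start2, df$length, df$orientation))
}

# --- ORFs: naive codon-by-codon walk --------------------------------------
oracle_orfs <- function(seq, min_aa) {
  seq <- toupper(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  len <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (frame in 1:3) {
      i <- frame
      current_start <- NA_integer_
      while (i + 2L <= nchar(s)) {
        codon <- substr(s, i, i + 2L)
        if (codon %in% c("TAA", "TAG", "TGA")) {
          if (!is.na(current_start)) {
            n_aa <- (i - current_start) %/% 3L
            if (n_aa >= min_aa) {
              st <- current_start; en <- i + 2L
              res[[length(res) + 1L]] <- data.frame(
                start = if (strand == "+") st else len - en + 1L,
                end = if (strand == "+") en else len - st + 1L,
                strand = strand, n_aa = n_aa
              )
            }
          }
          current_start <- NA_integer_
        } else if (is.na(current_start) && codon == "ATG") {
          current_start <- i
        }
        i <- i + 3L
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), n_aa = integer()))
  }
  out[order(out$start, out$strand), ]
}

# --- closed covering walks: brute-force enumeration on tiny graphs --------
# Enumerates every closed walk up to max_len that covers all contigs,
# working straight off the edge table at every step.
oracle_covering_walks <- function(graph, max_len) {
  edges <- graph$edges
  ids <- sort(graph$nodes$contig_id)
  connects <- function(c1, o1, c2, o2) {
    ea <- if (o1 == "+") "3'" else "5'"
    eb <- if (o2 == "+") "5'" else "3'"
    any((edges$contig_a == c1 & edges$end_a == ea &
           edges$contig_b == c2 & edges$end_b == eb) |
          (edges$contig_b == c1 & edges$end_b == ea &
             edges$contig_a == c2 & edges$end_a == eb))
  }
  states <- expand.grid(contig = ids, orient = c("+", "-"),
                        stringsAsFactors = FALSE)
  found <- list()
  recurse <- function(path_c, path_o) {
    L <- length(path_c)
    if (all(ids %in% path_c) &&
        connects(path_c[L], path_o[L], path_c[1], path_o[1])) {
      found[[length(found) + 1L]] <<- list(contig = path_c, orient = path_o)
    }
    if (L == max_len) return(invisible(NULL))
    for (j in seq_len(nrow(states))) {
      if (connects(path_c[L], path_o[L], states$contig[j], states$orient[j])) {
        recurse(c(path_c, states$contig[j]), c(path_o, states$orient[j]))
      }
    }
  }
  recurse(ids[1], "+")
  found
}

# shortest covering walk length among the enumerated walks
oracle_min_walk_length <- function(graph, max_len) {
  walks <- oracle_covering_walks(graph, max_len)
  if (!length(walks)) return(NA_integer_)
  min(vapply(walks, function(w) length(w$contig), 1L))
}
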