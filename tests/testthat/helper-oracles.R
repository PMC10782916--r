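# Independent brute-force oracles used to check the implementation.

# exhaustive dinucleotide scan for TA occurrences (0-based positions)
brute_ta_positions <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  which(chars[-n] == "T" & chars[-1L] == "A") - 1L
}

# per-position interval-membership test against every gene window
brute_annotate <- function(contig, pos, genes, window, mode = "upstream") {
  hits <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ws <- g$start; we <- g$end
    if (mode == "upstream") {
      if (g$strand == "+") ws <- max(0L, ws - window) else we <- we + window
    } else {
      ws <- max(0L, ws - window); we <- we + window
    }
    if (g$contig == contig && pos >= ws && pos < we)
      hits <- c(hits, g$gene_id)
  }
  hits
}

# double loop over cells and site pairs for the adjacency matrix
brute_adjacency <- function(cells) {
  sites <- sort(unique(paste(cells$contig, cells$pos, cells$orientation,
                             sep = ":")))
  M <- matrix(0L, length(sites), length(sites),
              dimnames = list(sites, sites))
  for (bc in unique(cells$barcode)) {
    own <- cells[cells$barcode == bc, ]
    keys <- paste(own$contig, own$pos, own$orientation, sep = ":")
    for (a in keys) for (b in keys)
      M[a, b] <- M[a, b] + 1L
  }
  M
}

# exhaustive enumeration of all bipartite matchings (max size)
enum_matching_size <- function(adj) {
  nl <- nrow(adj); nr <- ncol(adj)
  best <- 0L
  rec <- function(u, used_r, size) {
    if (size + (nl - u + 1L) <= best) return(invisible(NULL))
    if (u > nl) { best <<- max(best, size); return(invisible(NULL)) }
    rec(u + 1L, used_r, size)
    for (v in which(adj[u, , drop = TRUE])) if (!used_r[v]) {
      used_r[v] <- TRUE
      rec(u + 1L, used_r, size + 1L)
      used_r[v] <- FALSE
    }
  }
  if (nl > 0L && nr > 0L) rec(1L, logical(nr), 0L)
  best
}

# hand-written Benjamini-Hochberg step-up with monotonicity enforcement
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}
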