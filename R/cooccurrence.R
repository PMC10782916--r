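# Co-occurring gene-pair mutation analysis with a structure-preserving
# permutation null. Observed insertion sites are replaced by random genomic
# TA sites (a bijection, drawn without replacement per trial) while the
# cell-site incidence structure is kept intact, so the null preserves the
# clonal structure and relationships among cells. A co-occurrence event for
# a gene pair is an edge between one site of each gene sharing at least one
# cell, and each unique site may contribute to at most one event: the event
# count is a maximum bipartite matching.

#' Map genes to the sample's insertion sites
#'
#' For each gene in the annotation, the set of distinct sample sites
#' (orientation collapsed to one coordinate) lying in its body or promoter
#' window.
#'
#' @param sample An \code{"sb_sample"}.
#' @param annotation An \code{"sb_annotation"}.
#' @return Named list: gene_id -> character vector of collapsed site keys
#'   (\code{contig:pos}); genes without hits are absent.
#' @export
gene_site_map <- function(sample, annotation) {
  stopifnot(inherits(sample, "sb_sample"), inherits(annotation, "sb_annotation"))
  cs <- collapsed_sites(sample)
  hits <- annotate_hits(cs$contig, cs$pos, annotation)
  if (nrow(hits) == 0L) return(stats::setNames(list(), character(0)))
  lapply(split(cs$site[hits[, "site"]],
               annotation$genes$gene_id[hits[, "gene"]]),
         unique)
}

# Kuhn's augmenting-path maximum bipartite matching on a logical adjacency
# matrix (rows = left nodes, cols = right nodes). Sizes here are tiny (sites
# per gene), so the O(V*E) algorithm is ample.
#' @keywords internal
max_matching_size <- function(adj) {
  nl <- nrow(adj); nr <- ncol(adj)
  if (nl == 0L || nr == 0L || !any(adj)) return(0L)
  match_r <- rep(0L, nr)
  res <- 0L
  seen <- logical(nr)
  aug <- function(u) {
    for (v in which(adj[u, ])) {
      if (!seen[v]) {
        seen[v] <<- TRUE
        if (match_r[v] == 0L || aug(match_r[v])) {
          match_r[v] <<- u
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (u in seq_len(nl)) {
    seen[] <- FALSE
    if (aug(u)) res <- res + 1L
  }
  res
}

# Bipartite adjacency between two site sets: edge iff >=1 cell harbors both
# sites, with a site shared by both genes excluded from pairing with itself.
# M is the boolean collapsed-site co-membership matrix.
#' @keywords internal
pair_adjacency <- function(sites_a, sites_b, M) {
  adj <- as.matrix(M[sites_a, sites_b, drop = FALSE]) > 0
  shared <- intersect(sites_a, sites_b)
  if (length(shared)) adj[cbind(match(shared, sites_a), match(shared, sites_b))] <- FALSE
  adj
}

#' Count co-occurrence events for one gene pair
#'
#' Builds the bipartite graph between the two genes' site sets (edge when at
#' least one cell harbors both sites; a site annotated to both genes never
#' pairs with itself) and returns the size of a maximum matching — the
#' one-event-per-site rule that counts co-occurrence within a cluster of
#' related cells only once.
#'
#' @param sample An \code{"sb_sample"}.
#' @param gene_a,gene_b Distinct gene ids.
#' @param annotation An \code{"sb_annotation"}.
#' @param gsmap Optional precomputed \code{\link{gene_site_map}}.
#' @param method \code{"matching"} (maximum matching, default) or
#'   \code{"greedy"} (first-come pairing in site order, for sensitivity
#'   analysis).
#' @return Integer event count \code{k}.
#' @export
count_pair_events <- function(sample, gene_a, gene_b, annotation,
                              gsmap = NULL, method = c("matching", "greedy")) {
  method <- match.arg(method)
  if (identical(gene_a, gene_b)) stopf("gene_a and gene_b must differ")
  if (is.null(gsmap)) gsmap <- gene_site_map(sample, annotation)
  sa <- gsmap[[gene_a]]; sb <- gsmap[[gene_b]]
  if (is.null(sa) || is.null(sb)) return(0L)
  M <- Matrix::crossprod(site_incidence(sample, collapse_orientation = TRUE))
  if (method == "matching") {
    pair_event_count_idx(match(sa, colnames(M)), match(sb, colnames(M)), M)
  } else {
    greedy_match_size(pair_adjacency(sa, sb, M))
  }
}

#' @keywords internal
greedy_match_size <- function(adj) {
  k <- 0L
  while (any(adj)) {
    hit <- which(adj, arr.ind = TRUE)[1L, ]
    k <- k + 1L
    adj[hit[1L], ] <- FALSE
    adj[, hit[2L]] <- FALSE
  }
  k
}

#' Replace a sample's sites by random TA sites (one permutation draw)
#'
#' Draws a bijection from the sample's nonredundant sites to TA sites
#' sampled uniformly without replacement from the genome-wide TA index, and
#' rewrites every cell's site list through it. Cell count, per-cell site
#' multiplicities, read counts and the whole cell-site incidence structure
#' are exactly preserved (the permuted incidence graph is isomorphic to the
#' original).
#'
#' @param sample An \code{"sb_sample"}.
#' @param ta_index An \code{"sb_ta_index"} for the reference genome.
#' @param seed Integer seed for the draw.
#' @return A new \code{"sb_sample"} with replaced coordinates.
#' @export
permute_sample <- function(sample, ta_index, seed) {
  stopifnot(inherits(sample, "sb_sample"), inherits(ta_index, "sb_ta_index"))
  n_sites <- nrow(sample$sites)
  if (ta_index$total < n_sites)
    stopf("TA index has %d sites; %d needed", ta_index$total, n_sites)
  set.seed(as.integer(seed))
  ta <- ta_index_table(ta_index)
  pick <- ta[sample.int(nrow(ta), n_sites), , drop = FALSE]
  old <- sample$sites$site
  map_contig <- stats::setNames(pick$contig, old)
  map_pos <- stats::setNames(pick$pos, old)
  cells <- sample$cells
  cells$contig <- unname(map_contig[cells$site])
  cells$pos <- unname(map_pos[cells$site])
  cells$site <- site_key(cells$contig, cells$pos, cells$orientation)
  out <- build_sample(cells[, c("barcode", "contig", "pos", "orientation",
                                "reads")],
                      sample$sample_id)
  out$audit <- sample$audit
  out
}

#' Raw permutation p-value from a trial count
#'
#' The single co-occurrence rate: \code{c} trials showing at least one
#' co-occurrence event out of \code{n_iter} gives \code{p = c / n_iter}.
#' A zero count is reported at the resolution floor \code{1 / n_iter} and
#' flagged.
#'
#' @param c Number of co-occurrence-positive trials.
#' @param n_iter Number of permutation trials.
#' @return List with \code{p} and logical \code{floored}.
#' @export
single_cooccurrence_p <- function(c, n_iter) {
  if (n_iter < 1L) stopf("n_iter must be >= 1")
  if (any(c < 0 | c > n_iter)) stopf("c must be in [0, n_iter]")
  list(p = ifelse(c == 0L, 1 / n_iter, c / n_iter), floored = c == 0L)
}

#' Benjamini-Hochberg adjustment over a sample's pair family
#'
#' Standard step-up BH with monotonicity enforcement, preserving input
#' order. The family is all evaluated pairs within one sample.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Estimated p-value for k co-occurrence events
#'
#' Extends the BH-adjusted single-co-occurrence p-value to the observed
#' number of independent events: \code{p_est = p_adj ^ k}. With \code{k = 1}
#' this is the adjusted p itself.
#'
#' @param p_adj BH-adjusted single-co-occurrence p-value(s), in (0, 1].
#' @param k Observed event count(s), integer >= 1.
#' @return \code{p_adj ^ k}.
#' @examples
#' estimated_p(1.26e-3, 3)          # ~2.00e-09
#' signif(estimated_p(6.59e-4, 2), 3)
#' @export
estimated_p <- function(p_adj, k) {
  if (any(k < 1L) || any(k != as.integer(k))) stopf("k must be integer >= 1")
  if (any(p_adj <= 0 | p_adj > 1)) stopf("p_adj must be in (0, 1]")
  p_adj ^ k
}

#' Permutation test for co-occurring gene-pair mutations
#'
#' For each trial, every nonredundant site of the sample is replaced by a
#' random genomic TA site (without replacement within the trial), the
#' replaced sites are annotated against the same gene universe and promoter
#' window as the observed data, and each gene pair is checked for
#' co-occurrence events through the preserved cell-site structure. Reports,
#' per pair: the observed event count \code{k} (maximum matching), the
#' single-co-occurrence trial count \code{c}, \code{p_raw = c / n_iter},
#' the BH-adjusted \code{p_adj} over the sample's pair family,
#' \code{p_est = p_adj^k}, and the Monte-Carlo exceedance p-value
#' \code{p_obs} of the observed count (\code{= p_raw} when \code{k = 1}; 1
#' when \code{k = 0}), used for calibration diagnostics.
#'
#' @param sample An \code{"sb_sample"}.
#' @param annotation An \code{"sb_annotation"} over the gene universe of
#'   interest.
#' @param ta_index An \code{"sb_ta_index"} for the reference genome.
#' @param pairs Two-column data.frame (gene_a, gene_b); default \code{NULL}
#'   evaluates all gene pairs with at least one observed co-occurrence
#'   event.
#' @param n_iter Number of permutation trials (default 10000).
#' @param seed Master seed; per-trial draws use deterministically derived
#'   streams.
#' @return An object of class \code{"sb_cooccur"}: \code{results} data.frame
#'   (gene_a, gene_b, k, c, p_raw, floored, p_adj, p_est, p_obs),
#'   \code{n_iter}, \code{seed}, \code{sample_id}.
#' @export
cooccurrence_test <- function(sample, annotation, ta_index, pairs = NULL,
                              n_iter = 10000L, seed = 1L) {
  stopifnot(inherits(sample, "sb_sample"),
            inherits(annotation, "sb_annotation"),
            inherits(ta_index, "sb_ta_index"))
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stopf("n_iter must be >= 1")

  cs <- collapsed_sites(sample)
  n_s <- nrow(cs)
  if (ta_index$total < n_s)
    stopf("TA index has %d sites; %d needed", ta_index$total, n_s)
  X <- site_incidence(sample, collapse_orientation = TRUE)  # cells x sites
  Mb <- Matrix::crossprod(X)                                # site co-membership
  Mb@x[] <- 1                                               # boolean weights

  genes <- annotation$genes$gene_id
  n_g <- length(genes)

  # observed annotation and event counts
  obs_hits <- annotate_hits(cs$contig, cs$pos, annotation)
  Zobs <- Matrix::sparseMatrix(i = obs_hits[, "site"], j = obs_hits[, "gene"],
                               x = 1, dims = c(n_s, n_g))
  obs_sets <- lapply(seq_len(n_g), function(j) which(Zobs[, j] > 0))

  if (is.null(pairs)) {
    W <- Matrix::t(Zobs) %*% Mb %*% Zobs - Matrix::crossprod(Zobs)
    idx <- which(as.matrix(W) > 0 & upper.tri(matrix(0, n_g, n_g)),
                 arr.ind = TRUE)
    pairs <- data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
                        stringsAsFactors = FALSE)
  }
  if (nrow(pairs) == 0L) {
    res <- data.frame(gene_a = character(), gene_b = character(),
                      k = integer(), c = integer(), p_raw = numeric(),
                      floored = logical(), p_adj = numeric(),
                      p_est = numeric(), p_obs = numeric(),
                      stringsAsFactors = FALSE)
    return(structure(list(results = res, n_iter = n_iter,
                          seed = as.integer(seed),
                          sample_id = sample$sample_id),
                     class = "sb_cooccur"))
  }
  pa <- match(pairs[[1L]], genes)
  pb <- match(pairs[[2L]], genes)
  if (anyNA(pa) || anyNA(pb))
    stopf("pair gene(s) absent from annotation: %s",
          paste(unique(c(pairs[[1L]][is.na(pa)], pairs[[2L]][is.na(pb)])),
                collapse = ", "))
  if (any(pa == pb)) stopf("gene_a and gene_b must differ")
  n_p <- nrow(pairs)

  k_obs <- integer(n_p)
  for (j in seq_len(n_p))
    k_obs[j] <- pair_event_count_idx(obs_sets[[pa[j]]], obs_sets[[pb[j]]], Mb)

  # permutation trials; the TA universe is fixed, so all TA sites are
  # annotated once and each trial reduces to a sparse row subset
  ta <- ta_index_table(ta_index)
  ta_hits <- annotate_hits(ta$contig, ta$pos, annotation)
  A <- Matrix::sparseMatrix(i = ta_hits[, "site"], j = ta_hits[, "gene"],
                            x = 1, dims = c(nrow(ta), n_g))
  c_single <- integer(n_p)       # trials with >=1 event
  c_ge <- integer(n_p)           # trials with k_trial >= k_obs (k_obs >= 1)
  need_match <- which(k_obs >= 2L)
  set.seed(as.integer(seed))
  trial_seeds <- sample.int(2147483646L, n_iter)
  for (t in seq_len(n_iter)) {
    set.seed(trial_seeds[t])
    pick <- sample.int(nrow(ta), n_s)
    Z <- A[pick, , drop = FALSE]
    W <- as.matrix(Matrix::t(Z) %*% Mb %*% Z - Matrix::crossprod(Z))
    w <- W[cbind(pa, pb)]
    pos <- w > 0
    c_single[pos] <- c_single[pos] + 1L
    if (length(need_match)) {
      sets <- NULL
      for (j in need_match) {
        if (!pos[j] || w[j] < k_obs[j]) next
        if (is.null(sets))
          sets <- lapply(seq_len(n_g), function(g) which(Z[, g] > 0))
        sa <- sets[[pa[j]]]; sb <- sets[[pb[j]]]
        if (min(length(sa), length(sb)) < k_obs[j]) next
        kt <- pair_event_count_idx(sa, sb, Mb)
        if (kt >= k_obs[j]) c_ge[j] <- c_ge[j] + 1L
      }
    }
  }
  c_ge[k_obs == 1L] <- c_single[k_obs == 1L]

  pr <- single_cooccurrence_p(c_single, n_iter)
  p_adj <- bh_adjust(pr$p)
  p_est <- ifelse(k_obs >= 1L, estimated_p(p_adj, pmax(k_obs, 1L)), NA_real_)
  p_obs <- ifelse(k_obs == 0L, 1, c_ge / n_iter)
  res <- data.frame(gene_a = pairs[[1L]], gene_b = pairs[[2L]],
                    k = k_obs, c = c_single,
                    p_raw = pr$p, floored = pr$floored,
                    p_adj = p_adj, p_est = p_est, p_obs = p_obs,
                    stringsAsFactors = FALSE)
  structure(list(results = res, n_iter = n_iter, seed = as.integer(seed),
                 sample_id = sample$sample_id),
            class = "sb_cooccur")
}

# Event count for one pair given site index vectors. A site annotated to
# both genes (overlapping windows) is one unique site and may contribute to
# at most one event, so it is usable on one side only; the count maximizes
# over side assignments of the shared sites (rarely more than a couple).
#' @keywords internal
pair_event_count_idx <- function(ia, ib, Mb) {
  shared <- intersect(ia, ib)
  ns <- length(shared)
  if (ns == 0L) return(max_matching_size(pair_adj_idx(ia, ib, Mb)))
  if (ns > 8L) {
    # enumeration would explode; bipartite-with-self-exclusion upper bound
    return(max_matching_size(pair_adj_idx(ia, ib, Mb)))
  }
  best <- 0L
  for (mask in 0:(2L^ns - 1L)) {
    to_b <- shared[bitwAnd(mask, 2L^(seq_len(ns) - 1L)) > 0L]
    ia2 <- setdiff(ia, to_b)
    ib2 <- setdiff(ib, setdiff(shared, to_b))
    best <- max(best, max_matching_size(pair_adj_idx(ia2, ib2, Mb)))
  }
  best
}

# bipartite adjacency from site index vectors against boolean co-membership
#' @keywords internal
pair_adj_idx <- function(ia, ib, Mb) {
  if (length(ia) == 0L || length(ib) == 0L)
    return(matrix(FALSE, length(ia), length(ib)))
  adj <- as.matrix(Mb[ia, ib, drop = FALSE]) > 0
  shared <- intersect(ia, ib)
  if (length(shared))
    adj[cbind(match(shared, ia), match(shared, ib))] <- FALSE
  adj
}

#' @export
print.sb_cooccur <- function(x, ...) {
  cat(sprintf("sb_cooccur ['%s']: %d pair(s), %d permutation trial(s), seed %d\n",
              x$sample_id, nrow(x$results), x$n_iter, x$seed))
  top <- x$results[order(x$results$p_est), , drop = FALSE]
  print(utils::head(top, 10), row.names = FALSE, digits = 3)
  if (nrow(top) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
summary.sb_cooccur <- function(object, alpha = 0.05, ...) {
  r <- object$results
  cat(sprintf("Co-occurrence permutation test, sample '%s' (%d trials)\n",
              object$sample_id, object$n_iter))
  cat(sprintf("  pairs evaluated: %d; significant at BH %.2g: %d; floored: %d\n",
              nrow(r), alpha, sum(r$p_adj <= alpha), sum(r$floored)))
  invisible(r)
}

#' Find recurrent co-occurring pairs across samples
#'
#' A pair is recurrent across samples when it shows at least one event in two
#' or more samples, and recurrent within a sample when it shows two or more
#' events in one.
#'
#' @param results A list of \code{"sb_cooccur"} objects (>= 1 sample).
#' @return data.frame (gene_a, gene_b, n_samples_with_event, max_k,
#'   recurrent_across, recurrent_within), pairs ordered canonically.
#' @export
find_recurrent_pairs <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "sb_cooccur")))
  rows <- do.call(rbind, lapply(results, function(r) {
    df <- r$results[, c("gene_a", "gene_b", "k")]
    df$sample <- r$sample_id
    df
  }))
  # canonical pair ordering so (A,B) and (B,A) collapse
  flip <- rows$gene_a > rows$gene_b
  tmp <- rows$gene_a[flip]
  rows$gene_a[flip] <- rows$gene_b[flip]
  rows$gene_b[flip] <- tmp
  key <- paste(rows$gene_a, rows$gene_b, sep = "\r")
  agg <- lapply(split(rows, key), function(d) {
    data.frame(gene_a = d$gene_a[1L], gene_b = d$gene_b[1L],
               n_samples_with_event = sum(d$k >= 1L),
               max_k = max(d$k),
               recurrent_across = sum(d$k >= 1L) >= 2L,
               recurrent_within = any(d$k >= 2L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}
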