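# Subclone reconstruction: adjacency matrix of insertion sites, hierarchical
# clustering of co-occurring sites, cell assignment, and driver annotation.

#' Build the insertion-site adjacency matrix of a sample
#'
#' Symmetric site-by-site matrix whose entry (i, j) counts the cells
#' harboring both sites; the diagonal counts the cells harboring each site.
#' Site ordering is deterministic (contig, position, orientation).
#'
#' @param sample An \code{"sb_sample"}.
#' @return A sparse symmetric integer \code{\link[Matrix]{Matrix}} with site
#'   keys as dimnames.
#' @export
build_adjacency <- function(sample) {
  stopifnot(inherits(sample, "sb_sample"))
  x <- site_incidence(sample)
  m <- Matrix::crossprod(x)          # sites x sites cell co-membership
  methods::as(m, "generalMatrix")
}

#' Fit subclones by hierarchical clustering of the adjacency matrix
#'
#' Co-occurrence distance between sites i and j is
#' \deqn{d(i,j) = 1 - M_{ij} / \min(M_{ii}, M_{jj}),}
#' i.e. 0 when the rarer site always co-occurs with the other and 1 when they
#' never share a cell. Pairs supported by fewer than \code{min_support} cells
#' are forced to distance 1 to suppress noise edges. Average-linkage
#' agglomerative clustering is cut at height \code{cut}; clusters with fewer
#' than \code{min_cluster_sites} sites are dissolved into the unclustered
#' singleton pool. Disjointness of the resulting site sets is guaranteed by
#' the tree cut.
#'
#' @param sample An \code{"sb_sample"}.
#' @param min_support Minimum shared-cell count for a pair to contribute
#'   co-occurrence signal (default 2).
#' @param linkage Linkage method for \code{\link[stats]{hclust}}
#'   (default \code{"average"}).
#' @param cut Tree cut height in distance units (default 0.5).
#' @param min_cluster_sites Minimum sites per reported subclone (default 2).
#' @return An object of class \code{"sb_subclones"}: list with
#'   \code{subclones} (list of site-key character vectors, named
#'   \code{c01, c02, ...} in decreasing size order), \code{site_cluster}
#'   (named vector mapping every site to its subclone id or \code{NA} for
#'   pooled sites), \code{adjacency}, \code{params}, \code{sample_id},
#'   \code{driver_genes} (filled by \code{\link{annotate_drivers}}).
#' @export
fit_subclones <- function(sample, min_support = 2L, linkage = "average",
                          cut = 0.5, min_cluster_sites = 2L) {
  stopifnot(inherits(sample, "sb_sample"))
  M <- build_adjacency(sample)
  n <- nrow(M)
  lab <- rep(NA_integer_, n)
  if (n == 1L) {
    cl <- 1L
    lab <- if (min_cluster_sites <= 1L) 1L else NA_integer_
    hc <- NULL
  } else {
    dM <- as.matrix(M)
    diagv <- diag(dM)
    dn <- 1 - dM / outer(diagv, diagv, pmin)
    dn[dM < min_support] <- 1
    diag(dn) <- 0
    hc <- stats::hclust(stats::as.dist(dn), method = linkage)
    cl <- stats::cutree(hc, h = cut)
    sizes <- table(cl)
    good <- as.integer(names(sizes)[sizes >= min_cluster_sites])
    lab[cl %in% good] <- cl[cl %in% good]
  }
  names(lab) <- rownames(M)
  # relabel in decreasing size order for stable, readable ids
  kept <- sort(table(lab[!is.na(lab)]), decreasing = TRUE)
  ids <- stats::setNames(sprintf("c%02d", seq_along(kept)), names(kept))
  site_cluster <- stats::setNames(rep(NA_character_, n), names(lab))
  has <- !is.na(lab)
  site_cluster[has] <- ids[as.character(lab[has])]
  subclones <- split(names(site_cluster)[has], site_cluster[has])
  structure(list(subclones = subclones, site_cluster = site_cluster,
                 adjacency = M, hclust = hc,
                 params = list(min_support = as.integer(min_support),
                               linkage = linkage, cut = cut,
                               min_cluster_sites = as.integer(min_cluster_sites)),
                 sample_id = sample$sample_id,
                 driver_genes = NULL),
            class = "sb_subclones")
}

#' @export
print.sb_subclones <- function(x, ...) {
  cat(sprintf("sb_subclones ['%s']: %d subclone(s) over %d site(s) (%d pooled)\n",
              x$sample_id, length(x$subclones), length(x$site_cluster),
              sum(is.na(x$site_cluster))))
  invisible(x)
}

#' @export
summary.sb_subclones <- function(object, ...) {
  df <- data.frame(subclone = names(object$subclones),
                   n_sites = lengths(object$subclones),
                   stringsAsFactors = FALSE)
  if (!is.null(object$assignment)) {
    tab <- table(object$assignment)
    df$n_cells <- as.integer(tab[df$subclone])
    df$n_cells[is.na(df$n_cells)] <- 0L
  }
  if (!is.null(object$driver_genes))
    df$driver_genes <- vapply(object$driver_genes[df$subclone],
                              paste, character(1), collapse = ",")
  rownames(df) <- NULL
  df
}

#' Heatmap of the clustered adjacency matrix
#'
#' Displays the site-by-site adjacency matrix with sites ordered by the
#' clustering dendrogram, the visual analogue of the per-tumor subclone
#' blocks.
#'
#' @param x An \code{"sb_subclones"}.
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @export
plot.sb_subclones <- function(x, ...) {
  M <- as.matrix(x$adjacency)
  ord <- if (!is.null(x$hclust)) x$hclust$order else seq_len(nrow(M))
  M <- M[ord, ord, drop = FALSE]
  graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), M,
                  xlab = "site (dendrogram order)",
                  ylab = "site (dendrogram order)",
                  main = sprintf("Insertion-site adjacency, sample %s",
                                 x$sample_id), ...)
  invisible(x)
}

#' Assign cells to subclones
#'
#' Each cell's qualifying sites are intersected with every subclone's site
#' set. A cell is assigned to the unique subclone with overlap at least
#' \code{min_overlap_sites}; cells overlapping two or more subclones are
#' labeled \code{MULTI} (doublet suspects); cells overlapping none are
#' \code{UNASSIGNED}.
#'
#' @param sample An \code{"sb_sample"}.
#' @param fit An \code{"sb_subclones"} from \code{\link{fit_subclones}}.
#' @param min_overlap_sites Minimum shared sites for membership (default 1).
#' @return A named character vector (barcode -> subclone id, \code{"MULTI"}
#'   or \code{"UNASSIGNED"}) covering every post-QC cell exactly once. Also
#'   stored on the returned fit when assigned via \code{\link{run_pipeline}}.
#' @export
assign_cells <- function(sample, fit, min_overlap_sites = 1L) {
  stopifnot(inherits(sample, "sb_sample"), inherits(fit, "sb_subclones"))
  x <- site_incidence(sample)                      # cells x sites
  sc <- fit$site_cluster[colnames(x)]
  ids <- names(fit$subclones)
  out <- rep("UNASSIGNED", nrow(x))
  names(out) <- rownames(x)
  if (length(ids)) {
    Z <- Matrix::sparseMatrix(
      i = which(!is.na(sc)),
      j = match(sc[!is.na(sc)], ids),
      x = 1, dims = c(ncol(x), length(ids)),
      dimnames = list(colnames(x), ids))
    ov <- as.matrix(x %*% Z)                       # cells x subclones overlap
    hit <- ov >= min_overlap_sites
    nhit <- rowSums(hit)
    one <- nhit == 1L
    out[one] <- ids[apply(hit[one, , drop = FALSE], 1L, which)]
    out[nhit >= 2L] <- "MULTI"
  }
  out
}

#' Annotate subclones with driver genes
#'
#' Marks each subclone with the driver genes (a bulk-derived list, FDR <= 0.05)
#' hit by at least one of its insertion sites under the gene-body-plus-
#' promoter-window annotation. Orientations collapse to one coordinate here:
#' a TA hit on either strand is one genomic event for annotation.
#'
#' @param fit An \code{"sb_subclones"}.
#' @param drivers Character vector of driver gene ids, or a data.frame/path
#'   to a TSV whose first column (or \code{gene_id} column) lists them.
#' @param annotation An \code{"sb_annotation"}.
#' @return The fit with \code{driver_genes} filled (named list: subclone id
#'   -> character vector of hit driver genes, possibly empty).
#' @export
annotate_drivers <- function(fit, drivers, annotation) {
  stopifnot(inherits(fit, "sb_subclones"), inherits(annotation, "sb_annotation"))
  if (is.character(drivers) && length(drivers) == 1L && file.exists(drivers))
    drivers <- read_tsv(drivers)
  if (is.data.frame(drivers))
    drivers <- as.character(
      if ("gene_id" %in% names(drivers)) drivers$gene_id else drivers[[1L]])
  drivers <- unique(drivers)
  if (length(drivers) == 0L)
    warnf("empty driver list: all subclones annotated driverless")
  fit$driver_genes <- lapply(fit$subclones, function(site_keys) {
    parts <- strsplit(site_keys, ":", fixed = TRUE)
    contig <- vapply(parts, `[`, character(1), 1L)
    pos <- as.integer(vapply(parts, `[`, character(1), 2L))
    # collapse the two orientations at one TA to a single coordinate
    u <- !duplicated(paste(contig, pos))
    genes <- unique(unlist(annotate_site(contig[u], pos[u], annotation)))
    sort(intersect(genes, drivers))
  })
  fit
}

#' Subclone summary table
#'
#' Per-subclone site and cell counts plus annotated driver genes — the shape
#' of the per-tumor subclone side tables.
#'
#' @param fit An \code{"sb_subclones"} (after \code{\link{annotate_drivers}}
#'   if driver columns are wanted).
#' @param assignment Optional cell assignment from \code{\link{assign_cells}}.
#' @return data.frame (subclone, n_sites, n_cells, driver_genes).
#' @export
subclone_table <- function(fit, assignment = NULL) {
  df <- data.frame(subclone = names(fit$subclones),
                   n_sites = lengths(fit$subclones),
                   stringsAsFactors = FALSE)
  if (!is.null(assignment)) {
    tab <- table(assignment)
    df$n_cells <- as.integer(tab[df$subclone])
    df$n_cells[is.na(df$n_cells)] <- 0L
  }
  if (!is.null(fit$driver_genes))
    df$driver_genes <- vapply(fit$driver_genes[df$subclone], paste,
                              character(1), collapse = ",")
  rownames(df) <- NULL
  df
}
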