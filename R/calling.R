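# Insertion calling: aggregate junction calls into per-cell insertion
# profiles, apply the quality filter (a site qualifies with >9 supporting
# reads; a cell is kept with >=2 qualifying sites), and build per-sample
# nonredundant site sets.

#' Aggregate junction calls into raw cell profiles
#'
#' One profile per distinct barcode; the read count per insertion site is the
#' number of junction records for that (barcode, site). Site identity is
#' (contig, position, orientation).
#'
#' @param junctions An \code{"sb_junctions"} object or its junction
#'   data.frame (columns barcode, contig, pos, orientation).
#' @return data.frame (barcode, contig, pos, orientation, reads), one row per
#'   (cell, site).
#' @export
aggregate_cells <- function(junctions) {
  if (inherits(junctions, "sb_junctions")) junctions <- junctions$junctions
  stopifnot(all(c("barcode", "contig", "pos", "orientation") %in%
                  names(junctions)))
  if (nrow(junctions) == 0L)
    return(data.frame(barcode = character(), contig = character(),
                      pos = integer(), orientation = character(),
                      reads = integer(), stringsAsFactors = FALSE))
  key <- paste(junctions$barcode, junctions$contig, junctions$pos,
               junctions$orientation, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(barcode = vapply(parts, `[`, character(1), 1L),
                    contig = vapply(parts, `[`, character(1), 2L),
                    pos = as.integer(vapply(parts, `[`, character(1), 3L)),
                    orientation = vapply(parts, `[`, character(1), 4L),
                    reads = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$barcode, out$contig, out$pos, out$orientation), ,
      drop = FALSE]
}

#' Quality-filter cell profiles
#'
#' A site qualifies when its supporting read count is at least
#' \code{min_reads_per_site} (default 10, i.e. strictly more than 9 reads); a
#' cell is kept when it has at least \code{min_sites} qualifying sites
#' (default 2). By default kept cells retain only their qualifying sites;
#' sub-threshold sites of kept cells are returned separately for auditing
#' (set \code{keep_subthreshold = TRUE} to retain them in the profiles).
#'
#' @param cells data.frame from \code{\link{aggregate_cells}}.
#' @param min_reads_per_site Minimum reads for a site to qualify (default 10).
#' @param min_sites Minimum qualifying sites for a cell to be kept (default 2).
#' @param keep_subthreshold Keep sub-threshold sites inside kept cells
#'   (default \code{FALSE}).
#' @return List of class \code{"sb_qc"}: \code{cells} (filtered profile
#'   data.frame), \code{subthreshold} (audit data.frame of low-count sites in
#'   kept cells), \code{n_cells_raw}, \code{n_cells_kept}, and the thresholds.
#' @export
qc_filter <- function(cells, min_reads_per_site = 10L, min_sites = 2L,
                      keep_subthreshold = FALSE) {
  stopifnot(is.data.frame(cells))
  qual <- cells$reads >= min_reads_per_site
  qual_sites_per_cell <- tapply(qual, cells$barcode, sum)
  kept_bc <- names(qual_sites_per_cell)[qual_sites_per_cell >= min_sites]
  in_kept <- cells$barcode %in% kept_bc
  sub <- cells[in_kept & !qual, , drop = FALSE]
  kept <- if (keep_subthreshold) cells[in_kept, , drop = FALSE]
          else cells[in_kept & qual, , drop = FALSE]
  rownames(kept) <- rownames(sub) <- NULL
  structure(list(cells = kept, subthreshold = sub,
                 n_cells_raw = length(unique(cells$barcode)),
                 n_cells_kept = length(kept_bc),
                 min_reads_per_site = as.integer(min_reads_per_site),
                 min_sites = as.integer(min_sites),
                 keep_subthreshold = keep_subthreshold),
            class = "sb_qc")
}

#' @export
print.sb_qc <- function(x, ...) {
  cat(sprintf("sb_qc: %d/%d cell(s) kept (site >= %d reads, >= %d such sites)\n",
              x$n_cells_kept, x$n_cells_raw, x$min_reads_per_site, x$min_sites))
  invisible(x)
}

#' Build a per-sample dataset with its nonredundant site set
#'
#' @param qc An \code{"sb_qc"} from \code{\link{qc_filter}} (or a plain
#'   profile data.frame, in which case no audit counts are available).
#' @param sample_id Sample identifier.
#' @return An \code{"sb_sample"}: list with \code{sample_id}, \code{cells}
#'   (per-cell site read counts), \code{sites} (nonredundant site table:
#'   site, contig, pos, orientation — ordered by contig, position,
#'   orientation), and \code{audit}.
#' @export
build_sample <- function(qc, sample_id) {
  if (inherits(qc, "sb_qc")) {
    cells <- qc$cells
    audit <- list(n_cells_raw = qc$n_cells_raw, n_cells_kept = qc$n_cells_kept,
                  min_reads_per_site = qc$min_reads_per_site,
                  min_sites = qc$min_sites)
  } else {
    cells <- qc
    audit <- list(n_cells_raw = length(unique(cells$barcode)),
                  n_cells_kept = length(unique(cells$barcode)))
  }
  if (nrow(cells) == 0L)
    stopf("sample '%s': no cells pass QC (raw cells: %d)", sample_id,
          audit$n_cells_raw)
  skey <- site_key(cells$contig, cells$pos, cells$orientation)
  u <- !duplicated(skey)
  sites <- data.frame(site = skey[u], contig = cells$contig[u],
                      pos = cells$pos[u], orientation = cells$orientation[u],
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$contig, sites$pos, sites$orientation), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  cells$site <- skey
  structure(list(sample_id = sample_id, cells = cells, sites = sites,
                 audit = audit),
            class = "sb_sample")
}

#' @export
print.sb_sample <- function(x, ...) {
  cat(sprintf("sb_sample '%s': %d cell(s), %d nonredundant site(s)\n",
              x$sample_id, length(unique(x$cells$barcode)), nrow(x$sites)))
  if (!is.null(x$audit$n_cells_raw))
    cat(sprintf("  QC: %d/%d cells kept\n", x$audit$n_cells_kept,
                x$audit$n_cells_raw))
  invisible(x)
}

# Sparse cell x site incidence matrix (logical), optionally collapsing the
# two orientations at one TA to a single coordinate (used for annotation and
# co-occurrence, where orientation is irrelevant to the TA-replacement null).
#' @keywords internal
site_incidence <- function(sample, collapse_orientation = FALSE) {
  cells <- sample$cells
  if (collapse_orientation) {
    skey <- site_key(cells$contig, cells$pos)
    usite <- sort(unique(skey))
  } else {
    skey <- cells$site
    usite <- sample$sites$site
  }
  ubc <- sort(unique(cells$barcode))
  m <- Matrix::sparseMatrix(
    i = match(cells$barcode, ubc),
    j = match(skey, usite),
    x = 1,
    dims = c(length(ubc), length(usite)),
    dimnames = list(ubc, usite))
  # collapsing orientations can produce duplicate (cell, coordinate) entries
  m@x[] <- 1
  m
}

# Nonredundant collapsed (orientation-free) site table of a sample.
#' @keywords internal
collapsed_sites <- function(sample) {
  skey <- site_key(sample$sites$contig, sample$sites$pos)
  u <- !duplicated(skey)
  df <- data.frame(site = skey[u], contig = sample$sites$contig[u],
                   pos = sample$sites$pos[u], stringsAsFactors = FALSE)
  df <- df[order(df$site), , drop = FALSE]  # match site_incidence column order
  rownames(df) <- NULL
  df
}

#' Write a sample's cell-by-site matrix and site set as TSV
#'
#' @param sample An \code{"sb_sample"}.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- write_tsv(sample$cells,
                  file.path(dir, paste0(sample$sample_id, "_cell_sites.tsv")))
  p2 <- write_tsv(sample$sites,
                  file.path(dir, paste0(sample$sample_id, "_sites.tsv")))
  jsonlite::write_json(sample$audit,
                       file.path(dir, paste0(sample$sample_id, "_qc.json")),
                       auto_unbox = TRUE)
  invisible(c(p1, p2))
}
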