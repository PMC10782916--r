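# Synthetic-data generator: seeded genomes, planted subclonal architectures,
# and barcoded paired reads with full ground truth. Defaults reproduce the
# structure observed in the real tumors: 6-16 disjoint subclones per sample,
# 2-84 insertion sites each, 19-1250 cells each, plus singleton cells carrying
# never-reused private sites and doublet barcodes spanning two subclones.

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Every stochastic step is
#' driven by \code{seed}; two runs with the same config are byte-identical.
#'
#' @param genome_length Total genome length in bases.
#' @param n_contigs Number of contigs (length split evenly).
#' @param ta_enrichment Target TA dinucleotide density (TA sites per base);
#'   must be in (0, 0.25].
#' @param n_subclones Number of planted subclones, or a length-2 range to
#'   sample from (default \code{c(6, 16)}).
#' @param sites_per_subclone Range of insertion sites per subclone
#'   (default \code{c(2, 84)}).
#' @param cells_per_subclone Range of cells per subclone
#'   (default \code{c(19, 1250)}).
#' @param singleton_cell_rate Fraction of cells (relative to clustered cells)
#'   that are singletons carrying unique private sites (default 0.05).
#' @param doublet_rate Fraction of barcodes that are doublets merging two
#'   subclones' site sets (default 0.01).
#' @param sites_per_singleton Sites carried by each singleton cell.
#' @param reads_per_site_mean,reads_per_site_dispersion Negative binomial
#'   mean and dispersion (\code{size}) for per-(cell, site) read counts; a
#'   zero draw means that site goes unobserved in that cell.
#' @param junk_read_rate Fraction of extra read pairs lacking the transposon
#'   tag (library noise; rejected by read processing).
#' @param barcode_length Cell barcode length (16, as in the assay).
#' @param transposon_tag DNA sequence marking a genuine transposon-genome
#'   junction at the start of read 2.
#' @param read_length Length of emitted reads.
#' @param seed Mandatory integer seed.
#' @return A validated list of class \code{"sb_sim_config"}.
#' @export
sim_config <- function(genome_length = 200000L,
                       n_contigs = 2L,
                       ta_enrichment = 0.05,
                       n_subclones = c(6L, 16L),
                       sites_per_subclone = c(2L, 84L),
                       cells_per_subclone = c(19L, 1250L),
                       singleton_cell_rate = 0.05,
                       doublet_rate = 0.01,
                       sites_per_singleton = 2L,
                       reads_per_site_mean = 20,
                       reads_per_site_dispersion = 10,
                       junk_read_rate = 0,
                       barcode_length = 16L,
                       transposon_tag = "TGTATGTAAACTTCCGACTT",
                       read_length = 50L,
                       seed) {
  if (missing(seed)) stopf("sim_config: seed is mandatory")
  cfg <- list(genome_length = as.integer(genome_length),
              n_contigs = as.integer(n_contigs),
              ta_enrichment = ta_enrichment,
              n_subclones = as.integer(n_subclones),
              sites_per_subclone = as.integer(sites_per_subclone),
              cells_per_subclone = as.integer(cells_per_subclone),
              singleton_cell_rate = singleton_cell_rate,
              doublet_rate = doublet_rate,
              sites_per_singleton = as.integer(sites_per_singleton),
              reads_per_site_mean = reads_per_site_mean,
              reads_per_site_dispersion = reads_per_site_dispersion,
              junk_read_rate = junk_read_rate,
              barcode_length = as.integer(barcode_length),
              transposon_tag = toupper(transposon_tag),
              read_length = as.integer(read_length),
              seed = as.integer(seed))
  for (r in c("singleton_cell_rate", "doublet_rate", "junk_read_rate"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stopf("%s must be in [0,1]", r)
  if (cfg$ta_enrichment <= 0 || cfg$ta_enrichment > 0.25)
    stopf("ta_enrichment must be in (0, 0.25]")
  for (r in c("n_subclones", "sites_per_subclone", "cells_per_subclone")) {
    v <- cfg[[r]]
    if (!length(v) %in% 1:2 || any(v < 1) || (length(v) == 2 && v[2] < v[1]))
      stopf("%s must be a positive value or nondecreasing range", r)
    if (length(v) == 1L) cfg[[r]] <- c(v, v)
  }
  if (grepl("[^ACGT]", cfg$transposon_tag))
    stopf("transposon_tag must be ACGT only")
  class(cfg) <- "sb_sim_config"
  cfg
}

# sample an integer uniformly from a closed range
#' @keywords internal
runif_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a random genome with a target TA density
#'
#' Bases are drawn i.i.d. with letter probabilities chosen so the expected TA
#' dinucleotide density equals \code{ta_enrichment}
#' (\eqn{P(T) = P(A) = \sqrt{d}}, remainder split between C and G), which for
#' desk-scale genomes lands the realized density within a few percent of the
#' target. Deterministic given \code{config$seed}.
#'
#' @param config An \code{"sb_sim_config"}.
#' @return An \code{"sb_genome"} with contigs \code{sim1..simK}.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sb_sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  d <- config$ta_enrichment
  pt <- sqrt(d)
  probs <- c(A = pt, C = (1 - 2 * pt) / 2, G = (1 - 2 * pt) / 2, T = pt)
  len <- rep(config$genome_length %/% config$n_contigs, config$n_contigs)
  len[1] <- len[1] + config$genome_length %% config$n_contigs
  if (any(len < 2L)) stopf("genome too short for %d contigs", config$n_contigs)
  seqs <- vapply(len, function(L) {
    paste(sample(names(probs), L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
  names(seqs) <- paste0("sim", seq_along(seqs))
  as_genome(seqs)
}

#' Plant a subclonal architecture onto a genome
#'
#' Samples disjoint TA-site sets for each subclone (uniformly over the
#' genome's TA index), assigns cells to subclones, adds singleton cells with
#' unique never-reused private sites, converts a fraction of barcodes into
#' doublets merging two subclones, and draws per-(cell, site) read counts
#' from a negative binomial. Orientation per site is a fair coin flip, fixed
#' per site (one integration event per subclone site).
#'
#' @param genome An \code{"sb_genome"}.
#' @param config An \code{"sb_sim_config"}.
#' @return An \code{"sb_truth"} object: list with \code{subclone_sites}
#'   (data.frame: subclone, site, contig, pos, orientation), \code{cells}
#'   (data.frame: barcode, label — subclone id, \code{SINGLETON} or
#'   \code{DOUBLET}), \code{counts} (data.frame: barcode, contig, pos,
#'   orientation, reads; only nonzero counts), and \code{config}.
#' @export
plant_subclones <- function(genome, config) {
  stopifnot(inherits(genome, "sb_genome"), inherits(config, "sb_sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  ta <- ta_index_table(build_ta_index(genome))
  if (nrow(ta) == 0L) stopf("genome has no TA sites")

  n_sub <- runif_range(1L, config$n_subclones)
  n_sites <- runif_range(n_sub, config$sites_per_subclone)
  n_cells <- runif_range(n_sub, config$cells_per_subclone)
  n_clustered <- sum(n_cells)
  n_single <- rbinom(1L, n_clustered, config$singleton_cell_rate)
  need <- sum(n_sites) + n_single * config$sites_per_singleton
  if (need > nrow(ta))
    stopf("genome hosts %d TA sites but %d are required", nrow(ta), need)

  picked <- ta[sample.int(nrow(ta), need), , drop = FALSE]
  picked$orientation <- sample(c("+", "-"), need, replace = TRUE)
  sub_ids <- sprintf("s%02d", seq_len(n_sub))
  owner <- c(rep(sub_ids, n_sites),
             rep(sprintf("singleton%04d", seq_len(n_single)),
                 each = config$sites_per_singleton)[seq_len(n_single * config$sites_per_singleton)])
  sites <- data.frame(subclone = owner,
                      contig = picked$contig, pos = picked$pos,
                      orientation = picked$orientation,
                      stringsAsFactors = FALSE)

  # barcodes: clustered cells, then singleton cells; some become doublets
  n_bc <- n_clustered + n_single
  barcodes <- random_barcodes(n_bc, config$barcode_length)
  label <- c(rep(sub_ids, n_cells),
             rep("SINGLETON", n_single))
  member_of <- c(rep(sub_ids, n_cells),
                 sprintf("singleton%04d", seq_len(n_single)))
  second <- rep(NA_character_, n_bc)
  if (n_sub >= 2L && config$doublet_rate > 0) {
    clustered_idx <- seq_len(n_clustered)
    is_dbl <- clustered_idx[stats::runif(n_clustered) < config$doublet_rate]
    for (i in is_dbl) {
      other <- sample(setdiff(sub_ids, member_of[i]), 1L)
      second[i] <- other
      label[i] <- "DOUBLET"
    }
  }
  cells <- data.frame(barcode = barcodes, label = label,
                      member_of = member_of, second = second,
                      stringsAsFactors = FALSE)

  counts <- draw_counts(cells, sites, config)
  structure(list(subclone_sites = sites[grepl("^s\\d", sites$subclone), ,
                                        drop = FALSE],
                 all_sites = sites, cells = cells, counts = counts,
                 config = config),
            class = "sb_truth")
}

#' @keywords internal
random_barcodes <- function(n, len) {
  repeat {
    bc <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(bc)) return(bc)
  }
}

# per-(cell, site) read counts; zero draws drop the record
#' @keywords internal
draw_counts <- function(cells, sites, config) {
  groups <- split(seq_len(nrow(sites)), sites$subclone)
  own_list <- lapply(seq_len(nrow(cells)), function(i) {
    own <- groups[[cells$member_of[i]]]
    if (!is.na(cells$second[i])) own <- c(own, groups[[cells$second[i]]])
    own
  })
  site_idx <- unlist(own_list, use.names = FALSE)
  bc <- rep(cells$barcode, lengths(own_list))
  k <- stats::rnbinom(length(site_idx), mu = config$reads_per_site_mean,
                      size = config$reads_per_site_dispersion)
  keep <- k > 0L
  data.frame(barcode = bc[keep],
             contig = sites$contig[site_idx[keep]],
             pos = sites$pos[site_idx[keep]],
             orientation = sites$orientation[site_idx[keep]],
             reads = k[keep],
             stringsAsFactors = FALSE)
}

#' @export
print.sb_truth <- function(x, ...) {
  n_sub <- length(unique(x$subclone_sites$subclone))
  cat("sb_truth:", n_sub, "subclone(s),", nrow(x$cells), "cell(s),",
      nrow(x$all_sites), "planted site(s)\n")
  tab <- table(x$cells$label)
  cat("  cell labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Emit paired FASTQ reads for a planted truth
#'
#' Read 1 carries the 16-base cell barcode followed by random filler; read 2
#' carries the transposon tag followed by genomic flank starting at the
#' junction TA on the recorded orientation (\code{+}: flank reads into
#' increasing coordinates from the TA; \code{-}: reverse complement, reading
#' into decreasing coordinates — either way the emitted flank begins with
#' "TA"). Per-(cell, site) pair counts are the counts drawn at planting.
#' A fraction \code{junk_read_rate} of additional pairs lack the tag.
#'
#' @param truth An \code{"sb_truth"} from \code{\link{plant_subclones}}.
#' @param genome The same \code{"sb_genome"}.
#' @param config The same \code{"sb_sim_config"}.
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisibly, a list with the two paths and the emitted pair count.
#' @export
emit_reads <- function(truth, genome, config,
                       r1_path = tempfile(fileext = "_R1.fastq"),
                       r2_path = tempfile(fileext = "_R2.fastq")) {
  stopifnot(inherits(truth, "sb_truth"), inherits(genome, "sb_genome"))
  set.seed(derive_seed(config$seed, 3L))
  cn <- truth$counts
  n_pairs <- sum(cn$reads)
  idx <- rep(seq_len(nrow(cn)), cn$reads)
  flank_len <- config$read_length - nchar(config$transposon_tag)
  if (flank_len < 20L)
    stopf("read_length leaves %d flank bases after the tag; need >= 20", flank_len)

  r2_genomic <- junction_flank(genome, cn$contig[idx], cn$pos[idx],
                               cn$orientation[idx], flank_len)
  r2 <- paste0(config$transposon_tag, r2_genomic)
  filler_len <- config$read_length - config$barcode_length
  filler <- vapply(seq_len(n_pairs), function(i)
    paste(sample(c("A", "C", "G", "T"), filler_len, TRUE), collapse = ""),
    character(1))
  r1 <- paste0(cn$barcode[idx], filler)
  ids <- sprintf("sim_pair_%06d", seq_len(n_pairs))

  n_junk <- rbinom(1L, n_pairs, config$junk_read_rate)
  if (n_junk > 0L) {
    junk_seq <- function(L) vapply(seq_len(n_junk), function(i)
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), character(1))
    jr1 <- paste0(sample(truth$cells$barcode, n_junk, TRUE),
                  junk_seq(filler_len))
    jr2 <- junk_seq(config$read_length)
    r1 <- c(r1, jr1)
    r2 <- c(r2, jr2)
    ids <- c(ids, sprintf("junk_pair_%06d", seq_len(n_junk)))
  }

  write_fastq(ids, r1, r1_path)
  write_fastq(ids, r2, r2_path)
  invisible(list(r1 = r1_path, r2 = r2_path, n_pairs = length(ids),
                 n_junk = n_junk))
}

# genomic flank downstream of the junction TA on the given orientation;
# truncated at contig ends (never shorter than 2: the TA itself).
#' @keywords internal
junction_flank <- function(genome, contig, pos, orientation, flank_len) {
  seqs <- unclass(genome)
  L <- nchar(seqs)[contig]
  out <- character(length(pos))
  plus <- orientation == "+"
  # +: [pos, pos+flank_len) ; -: revcomp of [pos+2-flank_len, pos+2)
  if (any(plus)) {
    out[plus] <- substr(seqs[contig[plus]], pos[plus] + 1L,
                        pmin(L[plus], pos[plus] + flank_len))
  }
  if (any(!plus)) {
    from <- pmax(1L, pos[!plus] + 3L - flank_len)
    raw <- substr(seqs[contig[!plus]], from, pos[!plus] + 2L)
    out[!plus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(raw)))
  }
  out
}

#' @keywords internal
write_fastq <- function(ids, seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read paired FASTQ files
#'
#' @param r1_path,r2_path FASTQ paths (mates in the same order).
#' @return List with character vectors \code{id}, \code{r1}, \code{r2}.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  s1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(s1) != length(s2))
    stopf("mate files differ in read count (%d vs %d)", length(s1), length(s2))
  id1 <- sub("\\s.*$", "", names(s1))
  id2 <- sub("\\s.*$", "", names(s2))
  if (!identical(id1, id2)) stopf("mate ids are not paired in order")
  list(id = id1, r1 = as.character(s1), r2 = as.character(s2))
}

#' Ground-truth cell profiles from a planted architecture
#'
#' Returns the per-cell site read counts exactly as the read-processing and
#' aggregation stages would recover them at zero noise — the bridge used to
#' exercise clustering and co-occurrence at scale without emitting FASTQ.
#'
#' @param truth An \code{"sb_truth"}.
#' @return A data.frame (barcode, contig, pos, orientation, reads).
#' @export
truth_cells <- function(truth) {
  stopifnot(inherits(truth, "sb_truth"))
  truth$counts
}

#' Write truth tables as TSV
#'
#' @param truth An \code{"sb_truth"}.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- write_tsv(truth$all_sites, file.path(dir, "truth_sites.tsv"))
  p2 <- write_tsv(truth$cells, file.path(dir, "truth_cells.tsv"))
  p3 <- write_tsv(truth$counts, file.path(dir, "truth_counts.tsv"))
  invisible(c(p1, p2, p3))
}
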