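#' Read a reference genome from FASTA
#'
#' Loads a (possibly multi-contig) genome, uppercases the sequence, and
#' validates the alphabet. \code{N} bases are retained; any character outside
#' \code{A,C,G,T,N} is an error. Sleeping Beauty insertion-site analysis only
#' needs the TA landscape of the reference, so any FASTA (a real assembly or a
#' simulated genome from \code{\link{simulate_genome}}) can be used.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase contig sequences, class
#'   \code{"sb_genome"}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "TATAGGCC"), fa)
#' g <- read_genome(fa)
#' nchar(g[["c1"]])
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("genome FASTA not found: %s", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stopf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  if (length(set) == 0L) stopf("malformed FASTA '%s': no records", path)
  seqs <- toupper(as.character(set))
  # readDNAStringSet keeps full header lines; contig name = first token
  names(seqs) <- sub("\\s.*$", "", names(set))
  as_genome(seqs)
}

#' Construct a genome object from named sequences
#'
#' @param seqs Named character vector of DNA sequences.
#' @return An \code{"sb_genome"} object (named uppercase character vector).
#' @export
as_genome <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stopf("all contigs must be named")
  if (anyDuplicated(names(seqs)))
    stopf("duplicate contig name: %s",
          paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    bad <- names(seqs)[!nzchar(seqs)]
    stopf("empty sequence for contig: %s", paste(bad, collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stopf("non-ACGTN characters in contig: %s",
          paste(names(seqs)[bad], collapse = ", "))
  structure(seqs, class = "sb_genome")
}

#' @export
print.sb_genome <- function(x, ...) {
  cat("sb_genome:", length(x), "contig(s),", sum(nchar(x)), "bp total\n")
  for (nm in utils::head(names(x), 10))
    cat(sprintf("  %s  %d bp\n", nm, nchar(x[[nm]])))
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome An \code{"sb_genome"} object.
#' @param path Output path.
#' @param width Line wrap width.
#' @return \code{path}, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Index all TA dinucleotide positions of a genome
#'
#' Sleeping Beauty integrates exclusively into TA dinucleotides; the
#' permutation null draws replacement sites uniformly from this index.
#' Positions are 0-based coordinates of the T. "TA" cannot overlap itself, so
#' the occurrence list is overlap-free by construction. Dinucleotides
#' containing \code{N} are never indexed.
#'
#' @param genome An \code{"sb_genome"} object.
#' @return An object of class \code{"sb_ta_index"}: list with
#'   \code{positions} (named list of strictly increasing integer vectors,
#'   0-based) and \code{total} (total TA count).
#' @examples
#' g <- as_genome(c(c1 = "TATA"))
#' build_ta_index(g)$positions$c1  # 0 2
#' @export
build_ta_index <- function(genome) {
  stopifnot(inherits(genome, "sb_genome"))
  pos <- lapply(unclass(genome), function(s) {
    m <- gregexpr("TA", s, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  })
  structure(list(positions = pos, total = sum(lengths(pos))),
            class = "sb_ta_index")
}

#' @export
print.sb_ta_index <- function(x, ...) {
  cat("sb_ta_index:", x$total, "TA sites across", length(x$positions),
      "contig(s)\n")
  invisible(x)
}

#' Export a TA index as TSV
#'
#' @param index An \code{"sb_ta_index"}.
#' @param path Output TSV path (columns: contig, position; 0-based).
#' @return \code{path}, invisibly.
#' @export
write_ta_index <- function(index, path) {
  df <- data.frame(
    contig = rep(names(index$positions), lengths(index$positions)),
    position = unlist(index$positions, use.names = FALSE))
  write_tsv(df, path)
}

# Flatten a TA index to a two-column data.frame for uniform global sampling.
#' @keywords internal
ta_index_table <- function(index) {
  data.frame(
    contig = rep(names(index$positions), lengths(index$positions)),
    pos = unlist(index$positions, use.names = FALSE),
    stringsAsFactors = FALSE)
}

#' Read gene models from BED6 or GFF3
#'
#' BED input is taken as 0-based half-open (used directly); GFF3 is 1-based
#' closed and converted. The format is chosen from the file extension
#' (\code{.bed} vs \code{.gff}/\code{.gff3}) unless given explicitly. One
#' interval per gene; for GFF3 only records of type \code{gene} are used and
#' the gene identifier is taken from \code{ID=} (or \code{gene_id=}/
#' \code{Name=}) in the attributes.
#'
#' @param path Path to a BED6 or GFF3 file.
#' @param format \code{"auto"}, \code{"bed"} or \code{"gff3"}.
#' @return A data.frame with columns \code{gene_id}, \code{contig},
#'   \code{strand} (\code{+}/\code{-}), \code{start}, \code{end}
#'   (0-based half-open), class \code{c("sb_genes","data.frame")}.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("gene file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6L) stopf("BED input must have >= 6 columns (BED6)")
    genes <- data.frame(gene_id = as.character(df[[4L]]),
                        contig = as.character(df[[1L]]),
                        strand = as.character(df[[6L]]),
                        start = as.integer(df[[2L]]),
                        end = as.integer(df[[3L]]),
                        stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(f) < 9L
    if (any(bad)) stopf("GFF3 line with < 9 fields: %s", lines[which(bad)[1L]])
    f <- f[vapply(f, function(x) x[3L] == "gene", logical(1))]
    if (!length(f)) stopf("no 'gene' records in GFF3 file %s", path)
    attr_id <- function(a) {
      for (key in c("ID=", "gene_id=", "Name=")) {
        m <- regmatches(a, regexpr(paste0(key, "[^;]+"), a))
        if (length(m)) return(sub(key, "", m, fixed = TRUE))
      }
      NA_character_
    }
    genes <- data.frame(
      gene_id = vapply(f, function(x) attr_id(x[9L]), character(1)),
      contig = vapply(f, `[`, character(1), 1L),
      strand = vapply(f, `[`, character(1), 7L),
      # 1-based closed -> 0-based half-open
      start = as.integer(vapply(f, `[`, character(1), 4L)) - 1L,
      end = as.integer(vapply(f, `[`, character(1), 5L)),
      stringsAsFactors = FALSE)
    if (anyNA(genes$gene_id)) stopf("GFF3 gene record without ID attribute")
  }
  validate_genes(genes)
}

#' Construct a gene-model table from a data.frame
#'
#' Validates strands and intervals and applies the \code{"sb_genes"} class.
#' Coordinates must already be 0-based half-open.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{contig},
#'   \code{strand}, \code{start}, \code{end}.
#' @return The validated \code{"sb_genes"} data.frame.
#' @export
as_genes <- function(genes) validate_genes(genes)

#' @keywords internal
validate_genes <- function(genes) {
  if (any(!genes$strand %in% c("+", "-")))
    stopf("unknown strand symbol: %s",
          paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "))
  bad <- genes$end <= genes$start
  if (any(bad))
    stopf("gene with end <= start: %s", paste(genes$gene_id[bad], collapse = ", "))
  class(genes) <- c("sb_genes", "data.frame")
  genes
}

#' Build a gene annotation index with a promoter window
#'
#' A genomic site annotates to a gene if it lies in the gene body
#' \code{[start, end)} or within \code{promoter_window} bases upstream of the
#' transcription start (strand-aware by default: upstream of \code{start} for
#' \code{+} genes, downstream of \code{end} for \code{-} genes). The window
#' defaults to 40 kb, the span used to capture promoter-proximal activating
#' insertions. \code{promoter_mode = "symmetric"} extends the window on both
#' sides instead.
#'
#' @param genes An \code{"sb_genes"} data.frame from \code{\link{read_genes}}.
#' @param promoter_window Window length in bases (default 40000).
#' @param promoter_mode \code{"upstream"} (strand-aware, default) or
#'   \code{"symmetric"}.
#' @return An \code{"sb_annotation"} object.
#' @export
build_annotation <- function(genes, promoter_window = 40000L,
                             promoter_mode = c("upstream", "symmetric")) {
  promoter_mode <- match.arg(promoter_mode)
  stopifnot(inherits(genes, "sb_genes") || is.data.frame(genes))
  genes <- validate_genes(as.data.frame(genes))
  promoter_window <- as.integer(promoter_window)
  if (promoter_window < 0L) stopf("promoter_window must be >= 0")
  ws <- genes$start
  we <- genes$end
  if (promoter_mode == "upstream") {
    plus <- genes$strand == "+"
    ws[plus] <- pmax(0L, ws[plus] - promoter_window)
    we[!plus] <- we[!plus] + promoter_window
  } else {
    ws <- pmax(0L, ws - promoter_window)
    we <- we + promoter_window
  }
  win <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    # IRanges is 1-based closed: [ws, we) -> [ws+1, we]
    ranges = IRanges::IRanges(start = ws + 1L, end = we),
    gene_id = genes$gene_id)
  structure(list(genes = genes, windows = win,
                 promoter_window = promoter_window,
                 promoter_mode = promoter_mode),
            class = "sb_annotation")
}

#' @export
print.sb_annotation <- function(x, ...) {
  cat("sb_annotation:", nrow(x$genes), "gene(s), promoter window",
      x$promoter_window, "bp (", x$promoter_mode, ")\n")
  invisible(x)
}

#' Annotate genomic sites to genes
#'
#' Vectorized lookup of which genes (body + promoter window) contain each
#' site. Sites on unknown contigs annotate to no gene (with one warning).
#'
#' @param contig Character vector of contig names.
#' @param pos Integer vector of 0-based positions (same length).
#' @param annotation An \code{"sb_annotation"} from
#'   \code{\link{build_annotation}}.
#' @return A list (one element per site) of character vectors of gene ids;
#'   empty vector for intergenic sites.
#' @examples
#' genes <- as_genes(data.frame(gene_id = "g", contig = "c1",
#'   strand = "+", start = 100000L, end = 150000L))
#' ann <- build_annotation(genes)
#' annotate_site("c1", 99000L, ann)  # within the 40 kb promoter window
#' @export
annotate_site <- function(contig, pos, annotation) {
  stopifnot(inherits(annotation, "sb_annotation"))
  n <- length(pos)
  stopifnot(length(contig) == n)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- character(0)
  known <- GenomeInfoDb::seqlevels(annotation$windows)
  unknown <- !(contig %in% known)
  if (any(unknown))
    warnf("%d site(s) on contig(s) absent from annotation: %s",
          sum(unknown), paste(unique(contig[unknown]), collapse = ", "))
  keep <- which(!unknown)
  if (!length(keep)) return(out)
  q <- GenomicRanges::GRanges(contig[keep],
                              IRanges::IRanges(start = pos[keep] + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, annotation$windows)
  gid <- annotation$windows$gene_id[S4Vectors::subjectHits(hits)]
  qh <- S4Vectors::queryHits(hits)
  if (length(qh)) {
    sp <- split(gid, qh)
    for (j in names(sp)) out[[keep[as.integer(j)]]] <- unique(sp[[j]])
  }
  out
}

# Fast internal variant: returns a two-column (site_idx, gene_idx) matrix for
# many sites at once against the annotation windows; no warnings, used in the
# permutation hot loop. gene_idx indexes annotation$genes rows.
#' @keywords internal
annotate_hits <- function(contig, pos, annotation) {
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start = pos + 1L, width = 1L))
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(q, annotation$windows))
  cbind(site = S4Vectors::queryHits(hits), gene = S4Vectors::subjectHits(hits))
}
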