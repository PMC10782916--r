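# Read processing: turn raw paired reads into barcoded, genome-mapped
# transposon junction calls. Read 1 carries the cell barcode; read 2 carries
# the transposon tag followed by genomic flank. Mapping is exact k-mer
# seeding with full-length verification and a unique-placement contract
# (an adapter seam for an external aligner exists via map_fun in
# process_reads); the junction coordinate is snapped to the nearest TA.

#' Extract the cell barcode from read 1
#'
#' The barcode is the first \code{barcode_length} bases of read 1. With a
#' whitelist, barcodes within one mismatch of a unique whitelist entry are
#' corrected to it; barcodes matching no entry (or several) are rejected.
#'
#' @param r1 Character vector of read 1 sequences.
#' @param barcode_length Barcode length (default 16).
#' @param whitelist Optional character vector of valid barcodes; default
#'   \code{NULL} keeps the raw 16-mer (no correction, as in the assay).
#' @param max_mismatch Maximum mismatches for whitelist correction (default 1).
#' @return Character vector of barcodes, \code{NA} where rejected.
#' @export
extract_barcode <- function(r1, barcode_length = 16L, whitelist = NULL,
                            max_mismatch = 1L) {
  bc <- ifelse(nchar(r1) >= barcode_length,
               substr(r1, 1L, barcode_length), NA_character_)
  if (!is.null(whitelist)) {
    ok <- !is.na(bc)
    hit <- match(bc, whitelist)
    fix <- ok & is.na(hit)
    if (any(fix) && max_mismatch > 0L) {
      for (i in which(fix)) {
        d <- hamming_to_all(bc[i], whitelist)
        cand <- which(d <= max_mismatch)
        bc[i] <- if (length(cand) == 1L) whitelist[cand] else NA_character_
      }
    } else if (any(fix)) {
      bc[fix] <- NA_character_
    }
  }
  bc
}

# Hamming distance of one string against many equal-length strings.
#' @keywords internal
hamming_to_all <- function(x, pool) {
  xs <- strsplit(x, "")[[1L]]
  vapply(strsplit(pool, ""), function(p) {
    if (length(p) != length(xs)) return(Inf)
    sum(p != xs)
  }, numeric(1))
}

#' Isolate the transposon tag and trim read 2
#'
#' Keeps reads where the tag occurs within the first \code{search_window}
#' start offsets of read 2 with at most \code{max_mismatch} substitutions,
#' and returns the genomic sequence downstream of the tag. The first
#' (leftmost) hit wins when several offsets match.
#'
#' @param r2 Character vector of read 2 sequences.
#' @param tag Transposon tag sequence.
#' @param max_mismatch Maximum substitutions inside the tag (default 1).
#' @param search_window Number of start offsets (0-based offsets
#'   \code{0..search_window-1}) at which the tag may begin (default 5).
#' @return Character vector of trimmed genomic sequences, \code{NA} where the
#'   tag was not found.
#' @export
isolate_and_trim <- function(r2, tag, max_mismatch = 1L, search_window = 5L) {
  tl <- nchar(tag)
  tagv <- strsplit(tag, "")[[1L]]
  vapply(r2, function(s) {
    n <- nchar(s)
    for (off in 0:(search_window - 1L)) {
      if (off + tl > n) break
      win <- strsplit(substr(s, off + 1L, off + tl), "")[[1L]]
      if (sum(win != tagv) <= max_mismatch)
        return(substr(s, off + tl + 1L, n))
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Build an exact k-mer seed index over both strands of the genome. Seeds are
# the k-prefixes of fragments; matches are verified full-length.
#' @keywords internal
genome_kmer_env <- function(genome, k) {
  seqs <- unclass(genome)
  env <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(kmer, val) {
    cur <- env[[kmer]]
    env[[kmer]] <- if (is.null(cur)) list(val) else c(cur, list(val))
  }
  for (cname in names(seqs)) {
    s <- seqs[[cname]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    for (i in which(ok)) add(kmers[i], c(cname, starts[i] - 1L, "+"))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    kmers <- substring(rc, starts, starts + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    for (i in which(ok)) add(kmers[i], c(cname, starts[i] - 1L, "-"))
  }
  env
}

#' Map genomic fragments by exact seed-and-verify
#'
#' Seeds on the first \code{k} bases of each fragment against both strands,
#' verifies the full fragment as an exact match, and requires a unique
#' placement. Multi-mapping fragments and fragments with no placement are
#' reported as unmapped with a reason; fragments shorter than \code{min_len}
#' are \code{"too_short"}.
#'
#' Coordinates: a \code{+} placement at 0-based position \code{p} means the
#' fragment reads into increasing coordinates starting at \code{p} (junction
#' at \code{p}); a \code{-} placement means the fragment is the reverse
#' complement of the reference and reads into decreasing coordinates, with
#' the junction at the fragment's 5' end (reported position).
#'
#' @param frags Character vector of genomic fragments (\code{NA} allowed,
#'   reported as \code{"no_seq"}).
#' @param genome An \code{"sb_genome"}.
#' @param k Seed length (default 20).
#' @param min_len Minimum mappable fragment length (default 20).
#' @return data.frame with columns \code{contig}, \code{pos} (0-based
#'   junction coordinate), \code{strand}, \code{status}
#'   (\code{mapped}/\code{none}/\code{multi}/\code{too_short}/\code{no_seq}).
#' @export
map_fragments <- function(frags, genome, k = 20L, min_len = 20L) {
  stopifnot(inherits(genome, "sb_genome"))
  env <- genome_kmer_env(genome, k)
  seqs <- unclass(genome)
  n <- length(frags)
  contig <- rep(NA_character_, n); pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n); status <- rep("none", n)
  for (i in seq_len(n)) {
    f <- frags[i]
    if (is.na(f)) { status[i] <- "no_seq"; next }
    fl <- nchar(f)
    if (fl < min_len || fl < k) { status[i] <- "too_short"; next }
    hits <- env[[substr(f, 1L, k)]]
    if (is.null(hits)) next
    placements <- list()
    for (h in hits) {
      cname <- h[1L]; p0 <- as.integer(h[2L]); st <- h[3L]
      L <- nchar(seqs[[cname]])
      if (st == "+") {
        if (p0 + fl > L) next
        if (substr(seqs[[cname]], p0 + 1L, p0 + fl) == f)
          placements[[length(placements) + 1L]] <- list(cname, p0, "+")
      } else {
        # seed hit at p0 on the reverse-complemented contig; fragment occupies
        # rc positions [p0, p0+fl) i.e. forward [L-p0-fl, L-p0); junction
        # (fragment 5' end) at forward coordinate L-p0-2 for the TA
        if (p0 + fl > L) next
        fwd <- substr(seqs[[cname]], L - p0 - fl + 1L, L - p0)
        rcf <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
        if (rcf == f)
          placements[[length(placements) + 1L]] <- list(cname, L - p0 - 2L, "-")
      }
    }
    if (length(placements) == 0L) next
    if (length(placements) > 1L) { status[i] <- "multi"; next }
    contig[i] <- placements[[1L]][[1L]]
    pos[i] <- placements[[1L]][[2L]]
    strand[i] <- placements[[1L]][[3L]]
    status[i] <- "mapped"
  }
  data.frame(contig = contig, pos = pos, strand = strand, status = status,
             stringsAsFactors = FALSE)
}

#' Snap mapped junctions to the nearest TA dinucleotide
#'
#' The biological junction must sit on a TA. If the mapped coordinate does
#' not dereference to "TA", the nearest TA within \code{tolerance} bases
#' (smaller absolute offset wins; ties go to the left) is used; otherwise the
#' mapping is rejected with reason \code{"no_TA"}.
#'
#' @param mapped data.frame from \code{\link{map_fragments}} (only
#'   \code{status == "mapped"} rows are considered).
#' @param genome An \code{"sb_genome"}.
#' @param tolerance Maximum snap distance in bases (default 2).
#' @return The input data.frame with \code{pos} snapped and \code{status}
#'   updated to \code{"no_TA"} where no TA lies within tolerance.
#' @export
snap_to_ta <- function(mapped, genome, tolerance = 2L) {
  seqs <- unclass(genome)
  is_ta <- function(cname, p) {
    L <- nchar(seqs[[cname]])
    !is.na(p) && p >= 0L && p + 2L <= L &&
      substr(seqs[[cname]], p + 1L, p + 2L) == "TA"
  }
  for (i in which(mapped$status == "mapped")) {
    cname <- mapped$contig[i]; p <- mapped$pos[i]
    if (is_ta(cname, p)) next
    snapped <- NA_integer_
    for (d in seq_len(tolerance)) {
      for (cand in c(p - d, p + d)) {
        if (is_ta(cname, cand)) { snapped <- cand; break }
      }
      if (!is.na(snapped)) break
    }
    if (is.na(snapped)) {
      mapped$status[i] <- "no_TA"
      mapped$pos[i] <- NA_integer_
    } else {
      mapped$pos[i] <- snapped
    }
  }
  mapped
}

#' Process paired reads into mapped junction calls
#'
#' Runs barcode extraction, tag isolation/trimming, mapping, and TA snapping,
#' and returns the junction table plus a rejection audit whose category
#' counts sum to the input read-pair count.
#'
#' @param r1_path,r2_path Paired FASTQ paths.
#' @param genome An \code{"sb_genome"}.
#' @param tag Transposon tag sequence expected at the start of read 2.
#' @param barcode_length,whitelist,max_bc_mismatch Passed to
#'   \code{\link{extract_barcode}}.
#' @param tag_max_mismatch,tag_search_window Passed to
#'   \code{\link{isolate_and_trim}}.
#' @param k,min_len Passed to \code{\link{map_fragments}}.
#' @param snap_tolerance Passed to \code{\link{snap_to_ta}}.
#' @param map_fun Mapping function with the signature of
#'   \code{\link{map_fragments}} — the seam for plugging an external aligner.
#' @return List of class \code{"sb_junctions"}: \code{junctions} (data.frame
#'   barcode, contig, pos, orientation, mate_id) and \code{audit} (named
#'   counts: kept plus each rejection reason).
#' @export
process_reads <- function(r1_path, r2_path, genome, tag,
                          barcode_length = 16L, whitelist = NULL,
                          max_bc_mismatch = 1L,
                          tag_max_mismatch = 1L, tag_search_window = 5L,
                          k = 20L, min_len = 20L, snap_tolerance = 2L,
                          map_fun = map_fragments) {
  pairs <- read_fastq_pairs(r1_path, r2_path)
  n <- length(pairs$id)
  bc <- extract_barcode(pairs$r1, barcode_length, whitelist, max_bc_mismatch)
  frag <- isolate_and_trim(pairs$r2, tag, tag_max_mismatch, tag_search_window)

  reason <- rep(NA_character_, n)
  reason[is.na(bc)] <- "bad_barcode"
  reason[is.na(reason) & is.na(frag)] <- "no_tag"
  todo <- which(is.na(reason))

  mp <- map_fun(frag[todo], genome, k = k, min_len = min_len)
  mp <- snap_to_ta(mp, genome, tolerance = snap_tolerance)
  ok <- mp$status == "mapped"
  reason[todo[!ok]] <- paste0("unmapped_", mp$status[!ok])
  reason[todo[ok]] <- "kept"

  junctions <- data.frame(barcode = bc[todo[ok]],
                          contig = mp$contig[ok],
                          pos = mp$pos[ok],
                          orientation = mp$strand[ok],
                          mate_id = pairs$id[todo[ok]],
                          stringsAsFactors = FALSE)
  audit <- table(factor(reason))
  structure(list(junctions = junctions,
                 audit = stats::setNames(as.integer(audit), names(audit)),
                 n_pairs = n),
            class = "sb_junctions")
}

#' @export
print.sb_junctions <- function(x, ...) {
  cat("sb_junctions:", nrow(x$junctions), "junction call(s) from", x$n_pairs,
      "read pair(s)\n")
  cat("  audit:", paste(names(x$audit), x$audit, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a junction table and its audit
#'
#' @param jx An \code{"sb_junctions"}.
#' @param path Output TSV path; audit is written alongside as
#'   \code{<path>.audit.json}.
#' @return Invisibly, \code{path}.
#' @export
write_junctions <- function(jx, path) {
  write_tsv(jx$junctions, path)
  jsonlite::write_json(as.list(jx$audit), paste0(path, ".audit.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
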