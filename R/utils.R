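# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open; 1-based coordinates appear only at GFF3 I/O
# and when talking to IRanges (converted at the call site).

#' @keywords internal
site_key <- function(contig, pos, orientation = NULL) {
  if (is.null(orientation)) paste(contig, pos, sep = ":")
  else paste(contig, pos, orientation, sep = ":")
}

# Derive a child RNG seed from a master seed and a stream index.
# Keeps results reproducible per stage/trial while staying < 2^31.
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used to stamp output files with a config fingerprint.
#' @keywords internal
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; arithmetic stays in double (exact < 2^53)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Write a data.frame as TSV with an optional "# key: value" comment header.
#' @keywords internal
write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
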