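# Small in-code fixtures shared across test files.

write_fasta_fixture <- function(lines) {
  fa <- tempfile(fileext = ".fa")
  writeLines(lines, fa)
  fa
}

# cell profile rows: one barcode carrying the given (pos, reads) sites
profile_rows <- function(barcode, pos, reads, contig = "c1",
                         orientation = "+") {
  data.frame(barcode = barcode, contig = contig, pos = as.integer(pos),
             orientation = orientation, reads = as.integer(reads),
             stringsAsFactors = FALSE)
}

# a sample where named groups of cells share site sets:
# groups = list(list(n = <cells>, pos = <site positions>), ...)
group_sample <- function(groups, sample_id = "s", contig = "c1", reads = 15L) {
  rows <- list()
  bc <- 0L
  for (g in groups) {
    for (i in seq_len(g$n)) {
      bc <- bc + 1L
      rows[[length(rows) + 1L]] <-
        profile_rows(sprintf("BC%04d", bc), g$pos, reads, contig)
    }
  }
  build_sample(do.call(rbind, rows), sample_id)
}

# random sample with cluster structure for property tests:
# n_groups groups of group_cells cells sharing sites_per_group sites drawn
# from n_positions distinct positions
random_group_sample <- function(seed, n_groups = 5L, group_cells = 4L,
                                sites_per_group = 3L, n_positions = 200L) {
  set.seed(seed)
  pool <- sample.int(n_positions, n_groups * sites_per_group) * 10L
  groups <- lapply(seq_len(n_groups), function(i) {
    list(n = group_cells,
         pos = pool[((i - 1L) * sites_per_group + 1L):(i * sites_per_group)])
  })
  group_sample(groups, sample_id = sprintf("rnd%d", seed))
}

# genome with a known TA landscape, built from an explicit sequence
toy_genome <- function(seqs) as_genome(seqs)

# a TA-index over arbitrary planted positions (synthetic; positions must be
# TA in no real sequence -- used only where the index is consumed as a site
# universe, e.g. permute_sample)
synthetic_ta_index <- function(positions, contig = "c1") {
  structure(list(positions = setNames(list(sort(as.integer(positions))),
                                      contig),
                 total = length(positions)),
            class = "sb_ta_index")
}
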