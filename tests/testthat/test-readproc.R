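test_that("barcode extraction takes the first 16 bases and rejects short reads", {
  r1 <- c("ACGTACGTACGTACGTTTTT", "ACGTACGTAC")
  bc <- extract_barcode(r1)
  expect_equal(bc[1L], "ACGTACGTACGTACGT")
  expect_true(is.na(bc[2L]))
})

test_that("whitelist correction fixes unique 1-mismatch barcodes", {
  wl <- c("AAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCC", "GGGGGGGGGGGGGGGG")
  # one mismatch from the first entry
  q <- "AAAAAAAATAAAAAAA"
  expect_equal(hamming(q, wl[1L]), 1)
  expect_equal(extract_barcode(paste0(q, "TT"), whitelist = wl), wl[1L])
  # exact hit passes through
  expect_equal(extract_barcode(paste0(wl[2L], "TT"), whitelist = wl), wl[2L])
  # two mismatches from everything -> rejected
  q2 <- "AAAAAAAATTAAAAAA"
  expect_true(min(sapply(wl, hamming, a = q2)) > 1)
  expect_true(is.na(extract_barcode(paste0(q2, "TT"), whitelist = wl)))
})

test_that("tag isolation trims at the tag and tolerates one substitution", {
  tag <- "TGTATGTAAACTTCCGACTT"
  expect_equal(isolate_and_trim(paste0(tag, "TACCGGTT"), tag), "TACCGGTT")
  expect_true(is.na(isolate_and_trim("ACGTACGTACGTACGTACGTACGTACGT", tag)))
  # one substitution inside the tag
  mut <- tag
  substr(mut, 5, 5) <- ifelse(substr(tag, 5, 5) == "A", "C", "A")
  expect_equal(isolate_and_trim(paste0(mut, "GATTACA"), tag), "GATTACA")
  expect_true(is.na(isolate_and_trim(paste0(mut, "GATTACA"), tag,
                                     max_mismatch = 0L)))
  # tag two bases into the read, inside the search window
  expect_equal(isolate_and_trim(paste0("GG", tag, "CCAA"), tag), "CCAA")
  # sliding-window mismatch-count oracle over random reads
  set.seed(13)
  for (i in 1:20) {
    r2 <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    got <- isolate_and_trim(r2, tag)
    oracle <- NA_character_
    for (off in 0:4) {
      win <- substr(r2, off + 1L, off + nchar(tag))
      if (nchar(win) == nchar(tag) && hamming(win, tag) <= 1) {
        oracle <- substr(r2, off + nchar(tag) + 1L, nchar(r2)); break
      }
    }
    expect_identical(got, oracle)
  }
})

test_that("mapping requires a unique exact placement", {
  set.seed(19)
  body <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  g <- as_genome(c(c1 = body))
  frag <- substr(body, 101, 130)        # unique 30-mer at 0-based 100
  mp <- map_fragments(frag, g)
  expect_equal(mp$status, "mapped")
  expect_equal(mp$pos, 100L)
  expect_equal(mp$strand, "+")

  absent <- strrep("ACGT", 8)
  expect_equal(map_fragments(absent, g)$status,
               if (grepl(absent, body, fixed = TRUE)) "mapped" else "none")

  dupg <- as_genome(c(c1 = paste0(body, body)))  # every fragment twice
  expect_equal(map_fragments(frag, dupg)$status, "multi")

  expect_equal(map_fragments("ACGTACGT", g)$status, "too_short")
  # exhaustive substring-search oracle on a batch of random fragments
  for (i in 1:10) {
    f <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    n_fwd <- length(gregexpr(f, body, fixed = TRUE)[[1L]][
      gregexpr(f, body, fixed = TRUE)[[1L]] > 0])
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(f)))
    n_rev <- length(gregexpr(rc, body, fixed = TRUE)[[1L]][
      gregexpr(rc, body, fixed = TRUE)[[1L]] > 0])
    st <- map_fragments(f, g)$status
    expect_equal(st, if (n_fwd + n_rev == 1L) "mapped"
                 else if (n_fwd + n_rev == 0L) "none" else "multi")
  }
})

test_that("minus-strand mapping reports the junction TA coordinate", {
  set.seed(23)
  body <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  # plant a TA at 0-based 200 and read off the minus-orientation flank
  substr(body, 201, 202) <- "TA"
  g <- as_genome(c(c1 = body))
  flank <- sbclone:::junction_flank(g, "c1", 200L, "-", 30L)
  expect_equal(substr(flank, 1, 2), "TA")
  mp <- map_fragments(flank, g)
  if (mp$status == "mapped") {       # unique placement expected in random seq
    expect_equal(mp$strand, "-")
    expect_equal(mp$pos, 200L)
  }
})

test_that("junctions snap to the nearest TA within tolerance", {
  g <- as_genome(c(c1 = "GGGGTAGGGGGGGGGG"))
  mk <- function(p) data.frame(contig = "c1", pos = p, strand = "+",
                               status = "mapped", stringsAsFactors = FALSE)
  expect_equal(snap_to_ta(mk(4L), g)$pos, 4L)       # already on TA
  s <- snap_to_ta(mk(5L), g)
  expect_equal(s$pos, 4L)                           # snapped 1 base left
  expect_equal(s$status, "mapped")
  far <- snap_to_ta(mk(10L), g)
  expect_equal(far$status, "no_TA")
  expect_true(is.na(far$pos))
})

test_that("process_reads audit categories sum to the input pair count", {
  cfg <- sim_config(genome_length = 20000L, n_contigs = 1L,
                    ta_enrichment = 0.05, n_subclones = 2L,
                    sites_per_subclone = 3L, cells_per_subclone = 4L,
                    junk_read_rate = 0.2, seed = 31)
  g <- simulate_genome(cfg)
  tr <- plant_subclones(g, cfg)
  out <- emit_reads(tr, g, cfg)
  jx <- process_reads(out$r1, out$r2, g, cfg$transposon_tag)
  expect_equal(sum(jx$audit), out$n_pairs)
  expect_equal(unname(jx$audit["no_tag"]), out$n_junk)
  # every junction call sits on a reference TA
  seqs <- unclass(g)
  di <- substr(seqs[jx$junctions$contig], jx$junctions$pos + 1L,
               jx$junctions$pos + 2L)
  expect_true(all(di == "TA"))
})
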