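test_that("sim_config validates rates, ranges and the mandatory seed", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(singleton_cell_rate = 1.5, seed = 1), "\\[0,1\\]")
  expect_error(sim_config(ta_enrichment = 0.4, seed = 1), "ta_enrichment")
  expect_error(sim_config(n_subclones = c(5, 2), seed = 1), "range")
  cfg <- sim_config(n_subclones = 3, seed = 1)
  expect_equal(cfg$n_subclones, c(3L, 3L))
})

test_that("simulated genome hits the target TA density and is deterministic", {
  cfg <- sim_config(genome_length = 100000L, n_contigs = 1L,
                    ta_enrichment = 0.05, seed = 1)
  g <- simulate_genome(cfg)
  n_ta <- build_ta_index(g)$total
  expect_gte(n_ta, 4500L)
  expect_lte(n_ta, 5500L)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  sbclone:::write_genome(simulate_genome(cfg), f1)
  sbclone:::write_genome(simulate_genome(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planting yields disjoint subclone site sets within range", {
  cfg <- sim_config(genome_length = 30000L, n_contigs = 1L,
                    ta_enrichment = 0.05, n_subclones = 3L,
                    sites_per_subclone = 5L, cells_per_subclone = c(5L, 10L),
                    singleton_cell_rate = 0, doublet_rate = 0, seed = 4)
  g <- simulate_genome(cfg)
  tr <- plant_subclones(g, cfg)
  s <- tr$subclone_sites
  expect_equal(length(unique(s$subclone)), 3L)
  expect_equal(nrow(s), 15L)
  expect_equal(anyDuplicated(paste(s$contig, s$pos)), 0L)
  per <- table(s$subclone)
  expect_true(all(per == 5L))
})

test_that("planting fails when the genome cannot host the requested sites", {
  cfg <- sim_config(genome_length = 200L, n_contigs = 1L,
                    ta_enrichment = 0.02, n_subclones = 4L,
                    sites_per_subclone = c(50L, 50L),
                    cells_per_subclone = 5L, seed = 2)
  g <- simulate_genome(cfg)
  expect_error(plant_subclones(g, cfg), "TA sites")
})

test_that("emit_reads writes exactly the drawn pair counts with barcode and tag", {
  cfg <- sim_config(genome_length = 5000L, n_contigs = 1L,
                    ta_enrichment = 0.05, seed = 3)
  g <- simulate_genome(cfg)
  ta <- build_ta_index(g)$positions$sim1
  truth <- structure(list(
    counts = data.frame(barcode = strrep("A", 16), contig = "sim1",
                        pos = ta[5L], orientation = "+", reads = 12L,
                        stringsAsFactors = FALSE),
    cells = data.frame(barcode = strrep("A", 16), label = "s01",
                       stringsAsFactors = FALSE)),
    class = "sb_truth")
  out <- emit_reads(truth, g, cfg)
  pairs <- read_fastq_pairs(out$r1, out$r2)
  expect_length(pairs$id, 12L)
  expect_true(all(substr(pairs$r1, 1, 16) == strrep("A", 16)))
  expect_true(all(startsWith(pairs$r2, cfg$transposon_tag)))
  # the genomic flank always begins with the junction TA
  flank <- substr(pairs$r2, nchar(cfg$transposon_tag) + 1L,
                  nchar(cfg$transposon_tag) + 2L)
  expect_true(all(flank == "TA"))
})

test_that("emitted minus-orientation flanks also begin with TA", {
  cfg <- sim_config(genome_length = 20000L, n_contigs = 1L,
                    ta_enrichment = 0.06, n_subclones = 2L,
                    sites_per_subclone = 4L, cells_per_subclone = 3L,
                    singleton_cell_rate = 0, doublet_rate = 0, seed = 8)
  g <- simulate_genome(cfg)
  tr <- plant_subclones(g, cfg)
  expect_true(any(tr$counts$orientation == "-"))
  out <- emit_reads(tr, g, cfg)
  pairs <- read_fastq_pairs(out$r1, out$r2)
  flank <- substr(pairs$r2, nchar(cfg$transposon_tag) + 1L,
                  nchar(cfg$transposon_tag) + 2L)
  expect_true(all(flank == "TA"))
})

test_that("with doublet_rate 0 no barcode spans two subclones", {
  cfg <- sim_config(genome_length = 30000L, n_contigs = 1L,
                    ta_enrichment = 0.05, n_subclones = 4L,
                    sites_per_subclone = 5L, cells_per_subclone = 8L,
                    singleton_cell_rate = 0, doublet_rate = 0, seed = 5)
  g <- simulate_genome(cfg)
  tr <- plant_subclones(g, cfg)
  site_owner <- setNames(tr$subclone_sites$subclone,
                         paste(tr$subclone_sites$contig, tr$subclone_sites$pos))
  owners_per_cell <- tapply(
    site_owner[paste(tr$counts$contig, tr$counts$pos)],
    tr$counts$barcode, function(x) length(unique(x)))
  expect_true(all(owners_per_cell == 1L))
})

test_that("full determinism of planting and emission under a fixed seed", {
  cfg <- sim_config(genome_length = 20000L, n_contigs = 2L,
                    ta_enrichment = 0.05, n_subclones = 2L,
                    sites_per_subclone = 3L, cells_per_subclone = 4L,
                    junk_read_rate = 0.1, seed = 12)
  g <- simulate_genome(cfg)
  t1 <- plant_subclones(g, cfg); t2 <- plant_subclones(g, cfg)
  expect_identical(t1$counts, t2$counts)
  o1 <- emit_reads(t1, g, cfg); o2 <- emit_reads(t2, g, cfg)
  expect_identical(readLines(o1$r1), readLines(o2$r1))
  expect_identical(readLines(o1$r2), readLines(o2$r2))
})

test_that("zero-noise round trip recovers every planted site with >=10 reads", {
  cfg <- sim_config(genome_length = 40000L, n_contigs = 1L,
                    ta_enrichment = 0.05, n_subclones = 3L,
                    sites_per_subclone = 4L, cells_per_subclone = c(6L, 8L),
                    singleton_cell_rate = 0, doublet_rate = 0,
                    junk_read_rate = 0, reads_per_site_mean = 25,
                    seed = 21)
  g <- simulate_genome(cfg)
  tr <- plant_subclones(g, cfg)
  out <- emit_reads(tr, g, cfg)
  jx <- process_reads(out$r1, out$r2, g, cfg$transposon_tag)
  cells <- aggregate_cells(jx)

  # per-(cell, site) counts equal the emitted truth for uniquely mapped sites
  truth_key <- paste(tr$counts$barcode, tr$counts$contig, tr$counts$pos,
                     tr$counts$orientation)
  got_key <- paste(cells$barcode, cells$contig, cells$pos, cells$orientation)
  got <- setNames(cells$reads, got_key)
  deep <- tr$counts$reads >= 10L
  expect_true(all(truth_key[deep] %in% got_key))
  expect_equal(unname(got[truth_key[deep]]), tr$counts$reads[deep])

  smp <- build_sample(qc_filter(cells), "rt")
  planted <- unique(paste(tr$counts$contig[deep], tr$counts$pos[deep],
                          tr$counts$orientation[deep], sep = ":"))
  expect_true(all(planted %in% smp$sites$site))
})
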