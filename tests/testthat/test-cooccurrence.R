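toy_annotation <- function() {
  build_annotation(as_genes(data.frame(
    gene_id = c("gA", "gB", "gC"), contig = "c1", strand = "+",
    start = c(0L, 10000L, 20000L), end = c(1000L, 11000L, 21000L))),
    promoter_window = 0L)
}

test_that("gene_site_map collects the distinct sites of each gene", {
  ann <- toy_annotation()
  smp <- group_sample(list(list(n = 3, pos = c(100, 200, 300)),
                           list(n = 2, pos = c(10100, 50000))))
  gm <- gene_site_map(smp, ann)
  expect_length(gm$gA, 3L)
  expect_length(gm$gB, 1L)
  expect_false("gC" %in% names(gm))

  # intergenic-only sample gives an empty map
  smp2 <- group_sample(list(list(n = 2, pos = c(50000, 60000))))
  expect_length(gene_site_map(smp2, ann), 0L)

  # inversion oracle: site-wise annotate_site aggregation
  cs <- sbclone:::collapsed_sites(smp)
  per_site <- annotate_site(cs$contig, cs$pos, ann)
  for (g in names(gm))
    expect_setequal(gm[[g]],
                    cs$site[vapply(per_site, function(h) g %in% h, logical(1))])
})

test_that("one co-occurrence event per unique site (maximum matching)", {
  ann <- toy_annotation()
  # 50 cells of one subclone sharing a1 and b1: one event, not fifty
  smp <- group_sample(list(list(n = 50, pos = c(100, 10100))))
  expect_equal(count_pair_events(smp, "gA", "gB", ann), 1L)

  # three independent subclones each with a private (a_i, b_i) pair
  smp3 <- group_sample(list(list(n = 10, pos = c(100, 10100)),
                            list(n = 10, pos = c(200, 10200)),
                            list(n = 10, pos = c(300, 10300))))
  expect_equal(count_pair_events(smp3, "gA", "gB", ann), 3L)

  # edges {a1-b1, a1-b2} only: a1 can contribute once
  smpx <- group_sample(list(list(n = 5, pos = c(100, 10100)),
                            list(n = 5, pos = c(100, 10200))))
  expect_equal(count_pair_events(smpx, "gA", "gB", ann), 1L)

  expect_error(count_pair_events(smp, "gA", "gA", ann), "differ")
})

test_that("a site annotated to both genes never pairs with itself", {
  # overlapping genes sharing one site
  ann <- build_annotation(as_genes(data.frame(
    gene_id = c("g1", "g2"), contig = "c1", strand = "+",
    start = c(0L, 500L), end = c(1000L, 1500L))), promoter_window = 0L)
  smp <- group_sample(list(list(n = 5, pos = 700)))   # one shared site only
  expect_equal(count_pair_events(smp, "g1", "g2", ann), 0L)
  # but a second site in the overlap does give one event
  smp2 <- group_sample(list(list(n = 5, pos = c(700, 800))))
  expect_equal(count_pair_events(smp2, "g1", "g2", ann), 1L)
})

test_that("maximum matching equals exhaustive enumeration on random instances", {
  set.seed(61)
  for (i in 1:60) {
    nl <- sample(1:6, 1); nr <- sample(1:6, 1)
    adj <- matrix(runif(nl * nr) < 0.4, nl, nr)
    expect_equal(sbclone:::max_matching_size(adj), enum_matching_size(adj))
  }
})

test_that("maximum matching agrees with igraph on larger random instances", {
  skip_if_not_installed("igraph")
  set.seed(67)
  for (i in 1:20) {
    nl <- sample(2:12, 1); nr <- sample(2:12, 1)
    adj <- matrix(runif(nl * nr) < 0.3, nl, nr)
    g <- igraph::graph_from_biadjacency_matrix(adj)
    ref <- igraph::max_bipartite_match(g)$matching_size
    expect_equal(sbclone:::max_matching_size(adj), ref)
  }
})

test_that("permutation preserves the cell-site incidence structure", {
  smp <- random_group_sample(71, n_groups = 6, group_cells = 3,
                             sites_per_group = 4)
  ta <- synthetic_ta_index(seq(0, 99990, by = 10))
  ps <- permute_sample(smp, ta, seed = 5)
  # per-cell site multiplicities identical
  expect_equal(table(ps$cells$barcode), table(smp$cells$barcode))
  # site degree multiset (cells per site) identical
  deg <- function(s) sort(as.integer(table(s$cells$site)))
  expect_equal(deg(ps), deg(smp))
  # read counts ride along unchanged
  expect_equal(sort(ps$cells$reads), sort(smp$cells$reads))
  # same seed, same draw; bijection onto distinct TA positions
  ps2 <- permute_sample(smp, ta, seed = 5)
  expect_identical(ps$cells, ps2$cells)
  expect_equal(nrow(ps$sites), nrow(smp$sites))
  expect_error(permute_sample(smp, synthetic_ta_index(c(0, 10)), 1),
               "TA index")
})

test_that("exactly-exhausted TA index forces a bijection onto all sites", {
  smp <- group_sample(list(list(n = 2, pos = c(100, 200)),
                           list(n = 2, pos = c(300, 400, 500))))
  ta <- synthetic_ta_index(c(10, 20, 30, 40, 50))
  ps <- permute_sample(smp, ta, seed = 9)
  expect_setequal(ps$sites$pos, c(10L, 20L, 30L, 40L, 50L))
})

test_that("raw p-value is the single co-occurrence rate with a floor at 1/N", {
  # the rate is c/N: 3 event-positive trials of 10 000 give 3e-4
  expect_equal(single_cooccurrence_p(3, 10000)$p, 3e-4)
  expect_equal(single_cooccurrence_p(30, 10000)$p, 0.003)
  expect_equal(single_cooccurrence_p(10000, 10000)$p, 1)
  z <- single_cooccurrence_p(0, 10000)
  expect_equal(z$p, 1e-4)
  expect_true(z$floored)
  expect_error(single_cooccurrence_p(3, 0), "n_iter")
  expect_error(single_cooccurrence_p(-1, 10), "c must")
})

test_that("BH adjustment matches the hand-written step-up on random vectors", {
  expect_equal(bh_adjust(0.003), 0.003)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_length(bh_adjust(numeric(0)), 0L)
  set.seed(73)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_stepup(p))
    expect_true(all(adj >= p & adj <= 1))
  }
})

test_that("estimated p-value is the adjusted p raised to the event count", {
  expect_equal(estimated_p(2.29e-3, 1), 2.29e-3)       # k = 1 identity
  expect_equal(signif(estimated_p(1.26e-3, 3), 3), 2.00e-9)
  expect_equal(signif(estimated_p(6.59e-4, 2), 3), 4.34e-7)
  expect_error(estimated_p(0.01, 0), "k must")
  expect_error(estimated_p(1.2, 1), "p_adj")
})

test_that("cooccurrence_test is deterministic and self-consistent", {
  ann <- toy_annotation()
  smp <- group_sample(list(list(n = 10, pos = c(100, 10100)),
                           list(n = 10, pos = c(200, 20100))))
  ta <- synthetic_ta_index(seq(0, 80000, by = 40))
  cx1 <- cooccurrence_test(smp, ann, ta, n_iter = 300, seed = 11)
  cx2 <- cooccurrence_test(smp, ann, ta, n_iter = 300, seed = 11)
  expect_identical(cx1$results, cx2$results)
  r <- cx1$results
  expect_setequal(paste(r$gene_a, r$gene_b),
                  c("gA gB", "gA gC"))
  expect_true(all(r$k == 1L))
  expect_equal(r$p_raw, ifelse(r$floored, 1 / 300, r$c / 300))
  expect_equal(r$p_adj, bh_stepup(r$p_raw))
  expect_equal(r$p_est, r$p_adj ^ r$k)
  expect_equal(r$p_obs, r$c / 300)            # k = 1: exceedance = event rate
  expect_true(all(r$p_raw >= 0 & r$p_raw <= 1))
})

test_that("explicit pair lists are honored and validated", {
  ann <- toy_annotation()
  smp <- group_sample(list(list(n = 5, pos = c(100, 10100))))
  ta <- synthetic_ta_index(seq(0, 50000, by = 50))
  cx <- cooccurrence_test(smp, ann, ta,
                          pairs = data.frame(gene_a = "gA", gene_b = "gC"),
                          n_iter = 50, seed = 2)
  expect_equal(cx$results$k, 0L)
  expect_true(is.na(cx$results$p_est))
  expect_equal(cx$results$p_obs, 1)
  expect_error(cooccurrence_test(smp, ann, ta,
                                 pairs = data.frame(gene_a = "gA",
                                                    gene_b = "gZ"),
                                 n_iter = 10, seed = 1), "absent")
})

test_that("recurrent pairs are flagged across and within samples", {
  mk <- function(id, gene_a, gene_b, k) {
    structure(list(results = data.frame(
      gene_a = gene_a, gene_b = gene_b, k = k, c = 1L, p_raw = 0.001,
      floored = FALSE, p_adj = 0.001, p_est = 0.001 ^ k, p_obs = 0.001,
      stringsAsFactors = FALSE), n_iter = 1000L, seed = 1L, sample_id = id),
      class = "sb_cooccur")
  }
  res <- list(mk("a", "NEDD4L", "BRAF", 1L),
              mk("b", c("BRAF", "MITF"), c("NEDD4L", "LPAR1"), c(3L, 1L)))
  rec <- find_recurrent_pairs(res)
  row_nb <- rec[rec$gene_a == "BRAF" & rec$gene_b == "NEDD4L", ]
  expect_true(row_nb$recurrent_across)        # k>=1 in two samples
  expect_true(row_nb$recurrent_within)        # k=3 in one sample
  row_ml <- rec[rec$gene_a == "LPAR1" & rec$gene_b == "MITF", ]
  expect_false(row_ml$recurrent_across)       # single sample, k = 1
  expect_false(row_ml$recurrent_within)
})
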