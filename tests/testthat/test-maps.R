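test_that("FPKM follows its definition and scale invariances", {
  expect_equal(compute_fpkm(10, 1000, 1e6), 10)
  expect_equal(compute_fpkm(0, 1000, 1e6), 0)
  expect_equal(compute_fpkm(2 * 7, 350, 2 * 3e6),
               compute_fpkm(7, 350, 3e6))
  expect_error(compute_fpkm(1, 0, 1e6), class = "smcoloc_param_error")
  expect_error(compute_fpkm(1, 100, 0), class = "smcoloc_param_error")
})

test_that("the zero-dispersion exact test reproduces hand-computed anchors", {
  expect_equal(exact_test_nodisp(0, 0), 1)
  expect_equal(exact_test_nodisp(0, 10), 2 * 0.5^10)
  expect_equal(exact_test_nodisp(0, 10), 0.001953125)
  # symmetry under group swap
  set.seed(701)
  for (i in 1:20) {
    a <- rpois(2, 80); b <- rpois(2, 120)
    la <- runif(2, 0.5e6, 2e6); lb <- runif(2, 0.5e6, 2e6)
    expect_equal(exact_test_nodisp(a, b, la, lb),
                 exact_test_nodisp(b, a, lb, la))
  }
})

test_that("the exact test agrees with edgeR's dispersion-free exactTest", {
  # equal library sizes, one replicate per group: the double-tail and
  # minimum-likelihood two-sided conventions coincide (symmetric binomial)
  set.seed(702)
  cases <- cbind(a = rpois(25, 60), b = rpois(25, 140))
  mine <- apply(cases, 1, function(r) exact_test_nodisp(r[1], r[2]))
  d <- edgeR::DGEList(counts = cases,
                      group = c("A", "B"),
                      lib.size = rep(1e6, 2))
  er <- edgeR::exactTest(d, pair = c("B", "A"), dispersion = 0)$table$PValue
  expect_equal(unname(mine), er, tolerance = 1e-8)
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(703)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_equal(q, stats::p.adjust(p, method = "BH"))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("enrichment records carry ratios, tests and flags", {
  counts <- tibble::tibble(
    gene = c("up4x", "flat"), length_bp = c(1000, 1000),
    t1 = c(400, 100), t2 = c(420, 105),
    c1 = c(100, 100), c2 = c(110, 102))
  samples <- tibble::tibble(
    sample = c("t1", "t2", "c1", "c2"),
    group = c("tagged", "tagged", "control", "control"),
    library_size = rep(1e6, 4))
  tbl <- enrichment_table(counts, samples)
  expect_equal(tbl$log2_enrichment[1],
               log2(mean(c(400.5, 420.5)) / mean(c(100.5, 110.5))))
  expect_true(tbl$flag_2x[1])
  expect_false(tbl$flag_2x[2])
  expect_false(tbl$flag_recovered_4x[2])
  expect_true(all(tbl$q_value >= tbl$p_value))
})

test_that("identical groups give zero enrichment and no flags", {
  counts <- tibble::tibble(gene = letters[1:3], length_bp = 500,
                           t1 = c(10, 20, 30), c1 = c(10, 20, 30))
  samples <- tibble::tibble(sample = c("t1", "c1"),
                            group = c("tagged", "control"),
                            library_size = c(1e6, 1e6))
  tbl <- enrichment_table(counts, samples)
  expect_equal(tbl$log2_enrichment, rep(0, 3))
  expect_equal(tbl$p_value, rep(1, 3))
  expect_false(any(tbl$flag_2x))
})

test_that("genes without a valid length are skipped with a warning", {
  counts <- tibble::tibble(gene = c("ok", "bad"), length_bp = c(100, 0),
                           t1 = c(5, 5), c1 = c(5, 5))
  samples <- tibble::tibble(sample = c("t1", "c1"),
                            group = c("tagged", "control"),
                            library_size = c(1e6, 1e6))
  expect_warning(tbl <- enrichment_table(counts, samples), "length")
  expect_equal(tbl$gene, "ok")
})

test_that("spiked genes are recovered from a small simulated pull-down", {
  sim <- simulate_maps_counts(n_genes = 300, n_reps_per_group = 2,
                              baseline_mean = 100, dispersion = 0.05,
                              spike_gene_count = 3, spike_fold = 8,
                              seed = 704)
  tbl <- enrichment_table(sim$counts, sim$samples)
  spiked <- tbl$gene %in% sim$truth$gene[sim$truth$spiked]
  expect_true(all(tbl$flag_recovered_4x[spiked]))
  expect_gte(mean(!tbl$flag_2x[!spiked]), 0.99)
})

test_that("count matrices round-trip through TSV", {
  counts <- tibble::tibble(gene = c("g1", "g2"), length_bp = c(100, 200),
                           s1 = c(1L, 2L), s2 = c(3L, 4L))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(counts, path)
  back <- read_count_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(counts))
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(counts[, -2], bad)
  expect_error(read_count_matrix(bad), class = "smcoloc_format_error")
})
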