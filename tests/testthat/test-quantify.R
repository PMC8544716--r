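test_that("moment initialization matches the closed formulas", {
  init <- nb_moment_init(c(1, 5, 3, 7, 4))   # mean 4, variance 5
  expect_equal(init$p0, 0.8)
  expect_equal(init$r0, 16)
})

test_that("the MLE recovers NB parameters and agrees with a grid search", {
  set.seed(401)
  counts <- rnbinom(10000, size = 3, prob = 0.4)
  fit <- fit_single_molecule_model(counts)
  expect_true(abs(fit$r - 3) / 3 <= 0.10)
  expect_true(abs(fit$p - 0.4) <= 0.05)
  # independent oracle: profile the likelihood on a grid around the truth
  tab <- table(counts)
  vals <- as.numeric(names(tab))
  freq <- as.numeric(tab)
  grid <- expand.grid(r = seq(2.5, 3.5, by = 0.02),
                      p = seq(0.33, 0.47, by = 0.002))
  ll <- mapply(function(r, p) {
    sum(freq * dnbinom(vals, size = r, prob = p, log = TRUE))
  }, grid$r, grid$p)
  best <- grid[which.max(ll), ]
  expect_true(abs(fit$r - best$r) <= 0.05)
  expect_true(abs(fit$p - best$p) <= 0.005)
  expect_gte(fit$loglik, max(ll) - 1e-3)
})

test_that("under-dispersed or scarce calibration data is refused", {
  expect_error(fit_single_molecule_model(rep(5, 100)),
               class = "smcoloc_underdispersion_error")
  expect_error(fit_single_molecule_model(c(1, 2, 3)),
               class = "smcoloc_sample_size_error")
  fit <- fit_single_molecule_model(rep(5, 100), poisson_fallback = TRUE)
  expect_equal(fit$family, "poisson")
  expect_equal(fit$lambda, 5)
})

test_that("reference-matrix entries hit the closed-form anchors", {
  ref <- build_reference_matrix(single_molecule_model(1, 0.5), k_max = 3)
  expect_equal(ref$entries[1, 1], 0.5)     # P(n=0 | k=1) = p^r
  expect_equal(ref$entries[1, 2], 0.25)    # P(n=0 | k=2) = p^(kr)
})

test_that("convolution equals the closed form NB(k r, p)", {
  ref <- build_reference_matrix(single_molecule_model(2.5, 0.3),
                                k_max = 5, n_max = 400)
  for (k in 1:5) {
    expect_lt(max(abs(ref$entries[, k] -
                        dnbinom(0:400, size = k * 2.5, prob = 0.3))),
              1e-10)
  }
})

test_that("an inadequate n_max raises a truncation error naming the mass", {
  expect_error(
    build_reference_matrix(single_molecule_model(10, 0.5), k_max = 5,
                           n_max = 30),
    "mass", class = "smcoloc_truncation_error")
})

test_that("copy-number inversion takes the likelihood argmax over k", {
  ref <- build_reference_matrix(single_molecule_model(10, 0.5), k_max = 20)
  # direct argmax over the enumerated pmfs, independent of the matrix
  oracle <- function(n) {
    which.max(vapply(1:20, function(k) dnbinom(n, 10 * k, 0.5),
                     numeric(1)))
  }
  expect_equal(estimate_copy_number(30, ref)$k_hat, 3)
  expect_equal(estimate_copy_number(30, ref)$k_hat, oracle(30))
  expect_equal(estimate_copy_number(1, ref)$k_hat, 1)
  ks <- suppressWarnings(estimate_copy_number(1:500, ref)$k_hat)
  expect_equal(ks, vapply(1:500, oracle, integer(1)))
  expect_true(all(diff(ks) >= 0))   # non-decreasing in n
})

test_that("saturated clusters are flagged", {
  ref <- build_reference_matrix(single_molecule_model(10, 0.5), k_max = 2,
                                n_max = 400)
  expect_warning(out <- estimate_copy_number(100, ref), "k_max")
  expect_true(out$saturated)
})

test_that("per-cluster accuracy is high in the singleton-dominated regime", {
  set.seed(402)
  # detected-cluster composition at in-vivo molecule densities: almost all
  # clusters hold a single RNA, occasional overlaps give k = 2 or 3
  k_true <- sample(1:3, 4000, replace = TRUE, prob = c(0.95, 0.04, 0.01))
  n <- rnbinom(4000, size = 10 * k_true, prob = 0.5)
  keep <- n >= 2
  ref <- build_reference_matrix(single_molecule_model(10, 0.5), k_max = 20)
  est <- estimate_copy_number(n[keep], ref)
  expect_gte(mean(est$k_hat == k_true[keep]), 0.8)
})

test_that("background correction is a clamped mean subtraction", {
  bg <- fit_background_model(c(0, 1, 2, 1))
  expect_equal(bg$mean_background_copies_per_cell, 1)
  expect_equal(correct_background(10, fit_background_model(rep(2, 5))), 8)
  expect_equal(correct_background(1, fit_background_model(rep(2, 5))), 0)
  expect_equal(correct_background(c(5, 0.5), 2), c(3, 0))
})

test_that("copy_number_table sums per-cluster estimates per cell", {
  ref <- build_reference_matrix(single_molecule_model(10, 0.5), k_max = 20)
  clusters <- tibble::tibble(
    cell_id = c(1L, 1L, 2L), channel = "sRNA",
    cluster_id = 1:3, n_spots = c(10L, 30L, 9L))
  out <- copy_number_table(clusters, ref)
  expect_equal(out$raw_copies[out$cell_id == 1], 1 + 3)
  expect_equal(out$raw_copies[out$cell_id == 2], 1)
})
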