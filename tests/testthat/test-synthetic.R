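test_that("an empty scene yields an empty localization table", {
  cfg <- scene_config(n_cells = 3, mean_srna = 0, mean_mrna = 0, kd_v = 1,
                      background_rate = 0, n_marker_cells = 0, seed = 1)
  sc <- simulate_scene(cfg)
  expect_equal(nrow(sc$fov$localizations), 0)
  expect_equal(nrow(sc$truth$molecules), 0)
})

test_that("non-physical configurations are rejected", {
  expect_error(scene_config(sigma_z = 5, sigma_xy = 10),
               class = "smcoloc_config_error")
  expect_error(scene_config(background_rate = -1),
               class = "smcoloc_config_error")
})

test_that("a noise-free degenerate scene clusters one molecule per cluster", {
  cfg <- scene_config(n_cells = 10, mean_srna = 3, mean_mrna = 2,
                      kd_v = 1e9, sigma_pair = 0, fixed_spots = 3,
                      sigma_xy = 0, sigma_z = 0, background_rate = 0,
                      shift = c(0, 0, 0), n_marker_cells = 0, seed = 5)
  sc <- simulate_scene(cfg)
  cl <- cluster_localizations(sc$fov$localizations, cluster_params())
  expect_equal(nrow(cl), nrow(sc$truth$molecules))
  expect_true(all(cl$n_spots == 3))
  # each cluster's members map to exactly one truth molecule
  mol_of <- sc$truth$loc_molecule
  per_cluster <- vapply(cl$members,
                        function(m) length(unique(mol_of[m])), integer(1))
  expect_true(all(per_cluster == 1))
})

test_that("localization bookkeeping conserves counts and partitions", {
  cfg <- scene_config(n_cells = 15, seed = 6)
  sc <- simulate_scene(cfg)
  n_bg <- sum(is.na(sc$truth$loc_molecule))
  expect_equal(nrow(sc$fov$localizations),
               sum(sc$truth$molecules$n_locs) + n_bg)
  counted <- table(sc$truth$loc_molecule)
  expect_equal(unname(counted[as.character(sc$truth$molecules$molecule_id[
    sc$truth$molecules$n_locs > 0])]),
    table(factor(sc$truth$loc_molecule,
                 levels = sc$truth$molecules$molecule_id[
                   sc$truth$molecules$n_locs > 0])) |> unname())
  expect_true(all(sc$truth$cells$C <= pmin(sc$truth$cells$S,
                                           sc$truth$cells$M)))
})

test_that("raising kd_v lowers the realized bound fraction", {
  f_at <- function(kd) {
    sc <- simulate_scene(scene_config(n_cells = 60, kd_v = kd,
                                      background_rate = 0,
                                      n_marker_cells = 0, seed = 7))
    sc$truth$true_bound_fraction
  }
  fs <- c(f_at(0), f_at(30), f_at(300), f_at(3000))
  expect_true(all(diff(fs) < 0))
  # kd_v = 0: every feasible pair is bound, f = E min(S,M)/M realized
  sc0 <- simulate_scene(scene_config(n_cells = 40, kd_v = 0,
                                     background_rate = 0,
                                     n_marker_cells = 0, seed = 8))
  expect_equal(sum(sc0$truth$cells$C),
               sum(pmin(sc0$truth$cells$S, sc0$truth$cells$M)))
})

test_that("scenes are reproducible from config plus seed", {
  cfg <- scene_config(n_cells = 8, seed = 9)
  a <- simulate_scene(cfg)
  b <- simulate_scene(cfg)
  expect_identical(a$fov$localizations, b$fov$localizations)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("marker cells carry matched dual-channel structure", {
  cfg <- scene_config(n_cells = 4, mean_srna = 0, mean_mrna = 0, kd_v = 1,
                      background_rate = 0, n_marker_cells = 5,
                      marker_molecules = 15, seed = 10)
  sc <- simulate_scene(cfg)
  mk <- sc$truth$molecules
  expect_equal(nrow(mk), 5 * 15 * 2)
  # same molecule positions in both channels
  s <- mk[mk$channel == "sRNA", c("x", "y", "z")]
  m <- mk[mk$channel == "mRNA", c("x", "y", "z")]
  expect_equal(s, m)
  expect_equal(sum(sc$fov$rois$strain_label == "marker"), 5)
})

test_that("MAPS count simulation honours null, spikes and determinism", {
  null_sim <- simulate_maps_counts(n_genes = 50, spike_gene_count = 0,
                                   seed = 11)
  expect_false(any(null_sim$truth$spiked))
  sim1 <- simulate_maps_counts(n_genes = 50, seed = 12)
  sim2 <- simulate_maps_counts(n_genes = 50, seed = 12)
  expect_identical(sim1$counts, sim2$counts)
  expect_true(all(sim1$counts$length_bp >= 200 &
                    sim1$counts$length_bp <= 5000))
  pois <- simulate_maps_counts(n_genes = 2000, dispersion = 0,
                               spike_gene_count = 0, baseline_mean = 50,
                               seed = 13)
  cm <- as.matrix(pois$counts[, pois$samples$sample])
  expect_lt(abs(var(as.vector(cm)) / mean(cm) - 1), 0.1)  # Poisson-like
})
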