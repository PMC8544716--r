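#' Configuration for a synthetic two-channel localization scene
#'
#' The generator emulates the statistical structure of two-colour 3D
#' single-molecule FISH data from rod-shaped bacteria: per-cell Poisson
#' copy numbers, complex formation under single-site mass action, a
#' negative-binomial number of blink localizations per molecule, Gaussian
#' localization error that is worse axially, uniform nonspecific
#' background, a rigid chromatic shift of the mRNA channel, and
#' dual-labelled marker cells for registration.
#'
#' Defaults describe an induced E. coli-like condition: a 2 um x 0.8 um
#' spherocylindrical cell, ~30 sRNA and ~20 mRNA copies per cell, kd_v
#' chosen so the expected bound mRNA fraction is 0.4, NB(10, 0.25) blinks
#' per molecule (mean 30, emulating molecules carrying several dye-labelled
#' FISH probes that each blink repeatedly), 10 nm lateral / 21 nm axial
#' localization noise,
#' a 20 nm pairing offset within complexes, 5 background localizations per
#' cell and channel, and a (12, -9, 18) nm chromatic offset.
#'
#' @param n_cells Number of analysis cells.
#' @param cell_length,cell_radius Spherocylinder shaft length and radius
#'   (nm).
#' @param mean_srna,mean_mrna Mean copies per cell (Poisson).
#' @param kd_v K_D times cell volume, in copies; `NULL` derives it from
#'   `bound_fraction` via [kd_for_bound_fraction()] at the mean copy
#'   numbers.
#' @param bound_fraction Target expected bound mRNA fraction used when
#'   `kd_v` is `NULL` (default 0.4).
#' @param sigma_pair Root-mean-square 3D distance (nm) between the two
#'   molecules of a complex; the offset vector is isotropic Gaussian with
#'   per-axis SD `sigma_pair / sqrt(3)` (default 20).
#' @param spot_r,spot_p Negative-binomial localizations-per-molecule
#'   parameters (default r = 10, p = 0.25, mean 30 blinks). A degenerate model emitting a
#'   fixed spot count can be requested with `fixed_spots`.
#' @param fixed_spots If not `NULL`, every molecule emits exactly this many
#'   localizations (overrides `spot_r`/`spot_p`); used for construction
#'   tests.
#' @param sigma_xy,sigma_z Lateral and axial localization error SD in nm
#'   (defaults 10 and 21, the latter from a 50 nm axial FWHM resolution; `sigma_z >= sigma_xy` required).
#' @param background_rate Mean background localizations per cell per
#'   channel (Poisson, default 5).
#' @param shift Chromatic offset (dx, dy, dz nm) added to the mRNA
#'   channel.
#' @param n_marker_cells Dual-labelled marker cells appended for
#'   registration (default 10).
#' @param marker_molecules Molecules per marker cell (default 20).
#' @param n_replicates Cells are split evenly into this many biological-
#'   replicate labels (default 1).
#' @param seed Optional RNG seed for [simulate_scene()].
#' @return A validated `scene_config` list.
#' @export
scene_config <- function(n_cells = 200, cell_length = 2000,
                         cell_radius = 400, mean_srna = 30, mean_mrna = 20,
                         kd_v = NULL, bound_fraction = 0.4,
                         sigma_pair = 20, spot_r = 10, spot_p = 0.25,
                         fixed_spots = NULL, sigma_xy = 10, sigma_z = 21,
                         background_rate = 5, shift = c(12, -9, 18),
                         n_marker_cells = 10, marker_molecules = 20,
                         n_replicates = 1, seed = NULL) {
  if (is.null(kd_v)) {
    kd_v <- kd_for_bound_fraction(mean_srna, mean_mrna, bound_fraction)
  }
  cfg <- list(n_cells = n_cells, cell_length = cell_length,
              cell_radius = cell_radius, mean_srna = mean_srna,
              mean_mrna = mean_mrna, kd_v = kd_v,
              sigma_pair = sigma_pair, spot_r = spot_r, spot_p = spot_p,
              fixed_spots = fixed_spots, sigma_xy = sigma_xy,
              sigma_z = sigma_z, background_rate = background_rate,
              shift = shift, n_marker_cells = n_marker_cells,
              marker_molecules = marker_molecules,
              n_replicates = n_replicates, seed = seed)
  ok <- cfg$n_cells >= 1 && cfg$cell_length >= 0 && cfg$cell_radius > 0 &&
    cfg$mean_srna >= 0 && cfg$mean_mrna >= 0 && cfg$kd_v >= 0 &&
    cfg$sigma_pair >= 0 && cfg$spot_r > 0 && cfg$spot_p > 0 &&
    cfg$spot_p < 1 && cfg$sigma_xy >= 0 && cfg$sigma_z >= cfg$sigma_xy &&
    cfg$background_rate >= 0 && length(cfg$shift) == 3 &&
    cfg$n_marker_cells >= 0 && cfg$n_replicates >= 1 &&
    (is.null(cfg$fixed_spots) || cfg$fixed_spots >= 1)
  if (!ok) {
    abort("non-physical scene configuration", class = "smcoloc_config_error")
  }
  structure(cfg, class = "scene_config")
}

draw_spots <- function(n, config) {
  if (!is.null(config$fixed_spots)) rep(config$fixed_spots, n)
  else rnbinom(n, size = config$spot_r, prob = config$spot_p)
}

#' Simulate a two-channel localization scene with ground truth
#'
#' See [scene_config()] for the generative model. Cells (including marker
#' cells) are laid out on a non-overlapping grid; every molecule's
#' localizations carry its id in the truth map, so pipeline output can be
#' scored against both total truth (all molecules) and detected truth
#' (molecules with enough localizations to survive clustering).
#'
#' @param config A [scene_config()].
#' @return A list with `fov` (list: `localizations` tibble with columns
#'   `x`, `y`, `z`, `frame`, `channel`, `cell_id`, `replicate`; `rois` ROI
#'   tibble; `condition_label`) and `truth` (list: `cells` per-cell tibble
#'   with S, M, C; `molecules` tibble; `loc_molecule` molecule id per
#'   localization row, `NA` for background; `true_bound_fraction`;
#'   `shift`; `config`).
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_total <- config$n_cells + config$n_marker_cells
  pitch_x <- config$cell_length + 2 * config$cell_radius + 1000
  pitch_y <- 2 * config$cell_radius + 1000
  ncol_grid <- ceiling(sqrt(n_total))
  rois <- purrr::map_dfr(seq_len(n_total), function(i) {
    gx <- (i - 1) %% ncol_grid
    gy <- (i - 1) %/% ncol_grid
    roi_spherocylinder(
      cell_id = i, cx = gx * pitch_x, cy = gy * pitch_y, cz = 0,
      length = config$cell_length, radius = config$cell_radius,
      strain_label = if (i <= config$n_cells) "analysis" else "marker")
  })
  rep_of_cell <- rep(seq_len(config$n_replicates),
                     length.out = config$n_cells)

  mol_list <- vector("list", n_total)
  bg_list <- vector("list", n_total)
  complex_base <- 0L
  for (i in seq_len(config$n_cells)) {
    roi <- rois[i, ]
    s <- rpois(1, config$mean_srna)
    m <- rpois(1, config$mean_mrna)
    cc <- 0L
    if (min(s, m) > 0) {
      cstar <- equilibrium_complex_count(s, m, config$kd_v)
      cc <- rbinom(1, min(s, m), cstar / min(s, m))
    }
    n_mol <- 2L * cc + (s - cc) + (m - cc)
    pos <- matrix(0, 0, 3)
    channel <- character(0)
    bound <- logical(0)
    complex_id <- integer(0)
    if (cc > 0) {
      anchors <- sample_points_in_roi(cc, roi)
      # sigma_pair is the RMS 3D separation of the duplex partners
      partners <- anchors + matrix(rnorm(3 * cc, 0,
                                         config$sigma_pair / sqrt(3)),
                                   cc, 3)
      pos <- rbind(anchors, partners)
      channel <- c(rep("sRNA", cc), rep("mRNA", cc))
      bound <- rep(TRUE, 2 * cc)
      complex_id <- rep(complex_base + seq_len(cc), 2)
      complex_base <- complex_base + cc
    }
    if (s - cc > 0) {
      pos <- rbind(pos, sample_points_in_roi(s - cc, roi))
      channel <- c(channel, rep("sRNA", s - cc))
      bound <- c(bound, rep(FALSE, s - cc))
      complex_id <- c(complex_id, rep(NA_integer_, s - cc))
    }
    if (m - cc > 0) {
      pos <- rbind(pos, sample_points_in_roi(m - cc, roi))
      channel <- c(channel, rep("mRNA", m - cc))
      bound <- c(bound, rep(FALSE, m - cc))
      complex_id <- c(complex_id, rep(NA_integer_, m - cc))
    }
    mol_list[[i]] <- list(cell_id = i, S = s, M = m, C = cc, pos = pos,
                          channel = channel, bound = bound,
                          complex_id = complex_id)
    nb <- rpois(2, config$background_rate)
    bg <- list()
    for (k in 1:2) {
      if (nb[k] > 0) {
        b <- sample_points_in_roi(nb[k], roi)
        bg[[k]] <- data.frame(x = b[, 1], y = b[, 2], z = b[, 3],
                              channel = c("sRNA", "mRNA")[k], cell_id = i)
      }
    }
    bg_list[[i]] <- do.call(rbind, bg)
  }
  if (config$n_marker_cells > 0) {
    for (i in seq(config$n_cells + 1, n_total)) {
      roi <- rois[i, ]
      pos <- sample_points_in_roi(config$marker_molecules, roi)
      nm <- config$marker_molecules
      mol_list[[i]] <- list(cell_id = i, S = 0L, M = 0L, C = 0L,
                            pos = rbind(pos, pos),
                            channel = c(rep("sRNA", nm), rep("mRNA", nm)),
                            bound = rep(FALSE, 2 * nm),
                            complex_id = rep(NA_integer_, 2 * nm))
    }
  }

  molecules <- dplyr::bind_rows(purrr::map(mol_list, function(cl) {
    if (is.null(cl) || nrow(cl$pos) == 0) return(NULL)
    tibble(cell_id = cl$cell_id, channel = cl$channel,
           x = cl$pos[, 1], y = cl$pos[, 2], z = cl$pos[, 3],
           bound = cl$bound, complex_id = cl$complex_id)
  }))
  if (nrow(molecules) == 0) {
    molecules <- tibble(cell_id = integer(0), channel = character(0),
                        x = numeric(0), y = numeric(0), z = numeric(0),
                        bound = logical(0), complex_id = integer(0))
  }
  molecules$molecule_id <- seq_len(nrow(molecules))
  molecules$n_locs <- draw_spots(nrow(molecules), config)

  # expand molecules into blink localizations with Gaussian error
  idx <- rep(molecules$molecule_id, molecules$n_locs)
  n_loc <- length(idx)
  locs <- tibble(
    x = molecules$x[idx] + rnorm(n_loc, 0, config$sigma_xy),
    y = molecules$y[idx] + rnorm(n_loc, 0, config$sigma_xy),
    z = molecules$z[idx] + rnorm(n_loc, 0, config$sigma_z),
    channel = molecules$channel[idx],
    cell_id = molecules$cell_id[idx],
    molecule = idx)
  bg <- dplyr::bind_rows(bg_list)
  if (!is.null(bg) && nrow(bg) > 0) {
    bg <- as_tibble(bg)
    bg$molecule <- NA_integer_
    locs <- dplyr::bind_rows(locs, bg)
  }

  # chromatic offset: the mRNA (Alexa 568-like) channel is displaced
  sel <- locs$channel == "mRNA"
  locs$x[sel] <- locs$x[sel] + config$shift[1]
  locs$y[sel] <- locs$y[sel] + config$shift[2]
  locs$z[sel] <- locs$z[sel] + config$shift[3]

  n <- nrow(locs)
  ord <- if (n > 0) sample.int(n) else integer(0)   # shuffle blink order
  locs <- locs[ord, ]
  locs$frame <- seq_len(n) - 1L

  cells <- dplyr::bind_rows(purrr::map(
    mol_list[seq_len(config$n_cells)], function(cl) {
      tibble(cell_id = cl$cell_id, S = cl$S, M = cl$M, C = cl$C)
    }))
  cells$replicate <- rep_of_cell

  fov_locs <- tibble(x = locs$x, y = locs$y, z = locs$z,
                     frame = locs$frame, channel = locs$channel,
                     cell_id = locs$cell_id)
  fov_locs$replicate <- ifelse(fov_locs$cell_id <= config$n_cells,
                               rep_of_cell[pmin(fov_locs$cell_id,
                                                config$n_cells)],
                               NA_integer_)
  truth <- list(
    cells = cells,
    molecules = molecules,
    loc_molecule = locs$molecule,
    true_bound_fraction = if (sum(cells$M) > 0) sum(cells$C) / sum(cells$M)
                          else NA_real_,
    shift = config$shift,
    config = config)
  list(fov = list(localizations = fov_locs, rois = rois,
                  condition_label = "synthetic"),
       truth = truth)
}

#' Simulate a MAPS count matrix with spiked-in enriched genes
#'
#' Negative-binomial (Poisson when `dispersion` = 0) counts for a
#' tagged-versus-control pull-down design; `spike_gene_count` genes get
#' their tagged-group mean multiplied by `spike_fold`. Gene lengths are
#' drawn log-uniform on 200-5000 bp.
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_reps_per_group Replicates per group (default 2).
#' @param baseline_mean Mean fragments per gene per sample (default 100).
#' @param dispersion NB dispersion (variance = mu + dispersion mu^2;
#'   default 0.05; 0 = Poisson).
#' @param spike_gene_count Genes spiked in the tagged group (default 5).
#' @param spike_fold Fold-change of spiked genes (> 1, default 8).
#' @param seed Optional RNG seed.
#' @return List with `counts` (tibble for [enrichment_table()]), `samples`
#'   (sample sheet) and `truth` (tibble `gene`, `spiked`).
#' @export
simulate_maps_counts <- function(n_genes = 1000, n_reps_per_group = 2,
                                 baseline_mean = 100, dispersion = 0.05,
                                 spike_gene_count = 5, spike_fold = 8,
                                 seed = NULL) {
  stopifnot(spike_fold > 1, dispersion >= 0,
            spike_gene_count <= n_genes)
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  lengths <- round(exp(runif(n_genes, log(200), log(5000))))
  spiked <- rep(FALSE, n_genes)
  if (spike_gene_count > 0) spiked[seq_len(spike_gene_count)] <- TRUE
  draw <- function(mu) {
    if (dispersion == 0) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  counts <- tibble(gene = genes, length_bp = lengths)
  sample_names <- c(paste0("tagged_", seq_len(n_reps_per_group)),
                    paste0("control_", seq_len(n_reps_per_group)))
  groups <- rep(c("tagged", "control"), each = n_reps_per_group)
  for (j in seq_along(sample_names)) {
    mu <- rep(baseline_mean, n_genes)
    if (groups[j] == "tagged") mu[spiked] <- mu[spiked] * spike_fold
    counts[[sample_names[j]]] <- draw(mu)
  }
  list(counts = counts,
       samples = tibble(sample = sample_names, group = groups),
       truth = tibble(gene = genes, spiked = spiked))
}
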