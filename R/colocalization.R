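#' sRNA:mRNA colocalization percentage at a distance cutoff
#'
#' An mRNA cluster is colocalized iff its centroid lies within 3D Euclidean
#' distance `cutoff` of at least one sRNA cluster centroid (in the same
#' registered coordinate frame, and within the same `by` group when given).
#' The fraction is taken over ALL mRNA clusters. The default cutoff of
#' 50 nm matches the axial resolution of astigmatism-based 3D imaging.
#'
#' @param mrna_centroids,srna_centroids Tibbles with columns `x`, `y`, `z`
#'   (nm; [cluster_localizations()] output can be passed directly, its
#'   `cx`/`cy`/`cz` columns are recognised), optionally `cell_id` and
#'   `replicate`.
#' @param cutoff Distance cutoff in nm (> 0, default 50).
#' @param by Optional column name (e.g. `"cell_id"`) present in both
#'   tables; nearest-neighbour distances are then computed within matching
#'   groups only, which is the physically meaningful choice when clusters
#'   from many cells share one table.
#' @return A `coloc_result`: `n_mrna_clusters`, `n_colocalized`, `fraction`,
#'   `cutoff`, `per_replicate` (tibble, when a `replicate` column is
#'   present in the mRNA table), `baseline` (`NULL` until attached).
#' @export
colocalization_percentage <- function(mrna_centroids, srna_centroids,
                                      cutoff = 50, by = NULL) {
  stopifnot(cutoff > 0)
  m <- normalize_centroids(mrna_centroids)
  s <- normalize_centroids(srna_centroids)
  if (nrow(m) == 0) {
    warn("no mRNA clusters: colocalization fraction undefined, reported as 0")
    return(new_coloc_result(0L, 0L, 0, cutoff, NULL))
  }
  if (nrow(s) == 0) {
    warn("no sRNA clusters: colocalization fraction is 0")
    coloc <- rep(FALSE, nrow(m))
  } else if (is.null(by)) {
    coloc <- nn_within(as.matrix(m[, c("x", "y", "z")]),
                       as.matrix(s[, c("x", "y", "z")]), cutoff)
  } else {
    stopifnot(by %in% names(m), by %in% names(s))
    coloc <- rep(FALSE, nrow(m))
    sg <- split(seq_len(nrow(s)), s[[by]])
    mg <- split(seq_len(nrow(m)), m[[by]])
    for (g in names(mg)) {
      si <- sg[[g]]
      if (is.null(si)) next
      coloc[mg[[g]]] <- nn_within(
        as.matrix(m[mg[[g]], c("x", "y", "z")]),
        as.matrix(s[si, c("x", "y", "z")]), cutoff)
    }
  }
  per_rep <- NULL
  if ("replicate" %in% names(m)) {
    per_rep <- tibble(replicate = m$replicate, coloc = coloc) |>
      dplyr::group_by(.data$replicate) |>
      dplyr::summarise(n_mrna_clusters = dplyr::n(),
                       n_colocalized = sum(.data$coloc),
                       fraction = mean(.data$coloc), .groups = "drop")
  }
  new_coloc_result(nrow(m), sum(coloc), mean(coloc), cutoff, per_rep)
}

# accepts x/y/z or cluster-table cx/cy/cz naming
normalize_centroids <- function(df) {
  df <- as_tibble(df)
  if (!all(c("x", "y", "z") %in% names(df)) &&
      all(c("cx", "cy", "cz") %in% names(df))) {
    df <- dplyr::rename(df, x = "cx", y = "cy", z = "cz")
  }
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  df
}

# TRUE for each query row with a reference point within cutoff; chunked so
# the distance block never exceeds ~5e6 entries
nn_within <- function(q, ref, cutoff) {
  nq <- nrow(q)
  if (nq == 0) return(logical(0))
  if (nrow(ref) == 0) return(rep(FALSE, nq))
  out <- logical(nq)
  step <- max(1L, floor(5e6 / nrow(ref)))
  c2 <- cutoff^2
  refsq <- rowSums(ref^2)
  for (start in seq(1L, nq, by = step)) {
    idx <- start:min(start + step - 1L, nq)
    qs <- q[idx, , drop = FALSE]
    d2 <- outer(rowSums(qs^2), refsq, "+") - 2 * qs %*% t(ref)
    out[idx] <- apply(d2 <= c2 + 1e-9, 1, any)
  }
  out
}

new_coloc_result <- function(n_mrna, n_coloc, fraction, cutoff, per_rep,
                             baseline = NULL) {
  structure(list(n_mrna_clusters = n_mrna, n_colocalized = n_coloc,
                 fraction = fraction, cutoff = cutoff,
                 per_replicate = per_rep, baseline = baseline),
            class = "coloc_result")
}

#' Complete-spatial-randomness colocalization baseline
#'
#' Monte-Carlo twin of the negative-control experiment (an unregulated mRNA
#' imaged together with the sRNA): with sRNA clusters placed as a Poisson
#' process of intensity `lambda` in the cell and mRNA clusters placed
#' uniformly and independently, what colocalization fraction arises by
#' chance? Also returns the closed-form unbounded-CSR expectation
#' 1 - exp(-lambda (4/3) pi d^3).
#'
#' @param n_mrna Number of mRNA clusters per draw.
#' @param lambda sRNA cluster density per nm^3 (>= 0).
#' @param geometry One-row ROI tibble ([roi_box()] /
#'   [roi_spherocylinder()]) in which points are placed.
#' @param cutoff Distance cutoff in nm (default 50).
#' @param n_draws Monte-Carlo draws (>= 100, default 500).
#' @param seed Optional RNG seed.
#' @return A `csr_baseline`: `lambda`, `expected_fraction` (closed form),
#'   `mc_fraction`, `mc_se`, `n_draws`, `seed`.
#' @export
csr_baseline <- function(n_mrna, lambda, geometry, cutoff = 50,
                         n_draws = 500, seed = NULL) {
  stopifnot(lambda >= 0, n_draws >= 100, n_mrna >= 1)
  if (!is.null(seed)) set.seed(seed)
  vol <- roi_volume(geometry)
  expected <- 1 - exp(-lambda * 4 / 3 * pi * cutoff^3)
  fractions <- vapply(seq_len(n_draws), function(i) {
    ns <- rpois(1, lambda * vol)
    if (ns == 0) return(0)
    s <- sample_points_in_roi(ns, geometry)
    m <- sample_points_in_roi(n_mrna, geometry)
    mean(nn_within(m, s, cutoff))
  }, numeric(1))
  structure(list(lambda = lambda, expected_fraction = expected,
                 mc_fraction = mean(fractions),
                 mc_se = sd(fractions) / sqrt(n_draws),
                 n_draws = n_draws, seed = seed),
            class = "csr_baseline")
}

#' Sample points uniformly inside an ROI
#'
#' Rejection sampling from the ROI's bounding box; exact for boxes and
#' spherocylinders.
#'
#' @param n Number of points.
#' @param roi One-row ROI tibble.
#' @return Numeric matrix `n x 3`.
#' @export
sample_points_in_roi <- function(n, roi) {
  bb <- roi_bbox(roi)
  out <- matrix(numeric(0), ncol = 3)
  while (nrow(out) < n) {
    m <- max(16L, 2L * (n - nrow(out)))
    cand <- cbind(runif(m, bb[1], bb[2]), runif(m, bb[3], bb[4]),
                  runif(m, bb[5], bb[6]))
    out <- rbind(out, cand[roi_contains(roi, cand), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Attach a baseline to a colocalization result
#'
#' @param result A `coloc_result`.
#' @param baseline A [csr_baseline()] result, or a bare numeric fraction
#'   (e.g. the measured negative-control fraction).
#' @return The `coloc_result` with `baseline` set.
#' @export
set_coloc_baseline <- function(result, baseline) {
  stopifnot(inherits(result, "coloc_result"))
  result$baseline <- baseline
  result
}

# numeric value of whatever baseline is attached (0 when none)
baseline_fraction <- function(baseline) {
  if (is.null(baseline)) 0
  else if (inherits(baseline, "csr_baseline")) baseline$mc_fraction
  else if (inherits(baseline, "coloc_result")) baseline$fraction
  else as.numeric(baseline)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "Colocalization: %d / %d mRNA clusters within %.0f nm (%.1f%%)\n",
    x$n_colocalized, x$n_mrna_clusters, x$cutoff, 100 * x$fraction))
  if (!is.null(x$per_replicate)) {
    cat(sprintf("  replicates: %.1f%% +/- %.1f%% (mean +/- SD of %d)\n",
                100 * mean(x$per_replicate$fraction),
                100 * sd(x$per_replicate$fraction),
                nrow(x$per_replicate)))
  }
  if (!is.null(x$baseline)) {
    cat(sprintf("  random-colocalization baseline: %.2f%%\n",
                100 * baseline_fraction(x$baseline)))
  }
  invisible(x)
}

#' @export
tidy.coloc_result <- function(x, ...) {
  if (!is.null(x$per_replicate)) return(x$per_replicate)
  tibble(replicate = NA_character_, n_mrna_clusters = x$n_mrna_clusters,
         n_colocalized = x$n_colocalized, fraction = x$fraction)
}

#' @export
glance.coloc_result <- function(x, ...) {
  tibble(n_mrna_clusters = x$n_mrna_clusters,
         n_colocalized = x$n_colocalized, fraction = x$fraction,
         cutoff = x$cutoff,
         baseline = if (is.null(x$baseline)) NA_real_
                    else baseline_fraction(x$baseline))
}
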