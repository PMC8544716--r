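#' Estimate the chromatic shift between two dye channels
#'
#' Dual-labelled marker cells carry the same molecules in both channels, so
#' cluster centroids seen in channel A and channel B should coincide up to
#' the chromatic offset of the optics. Pairs are formed by mutual nearest
#' neighbours within `match_radius`; the shift is the component-wise median
#' of the paired displacements (B - A), which is robust to a minority of
#' mismatched pairs.
#'
#' @param markers_a,markers_b Tibbles/data frames of marker cluster
#'   centroids (`x`, `y`, `z` in nm) for channel A (reference, e.g. the
#'   Alexa 647 sRNA channel) and channel B (e.g. the Alexa 568 mRNA
#'   channel).
#' @param match_radius Maximum pairing distance in nm (default 200).
#' @return A `chromatic_shift` object: `translation` (dx, dy, dz nm, the
#'   median of B - A), `n_pairs_used`, `residual_rms` (nm, after applying
#'   the shift).
#' @export
estimate_chromatic_shift <- function(markers_a, markers_b,
                                     match_radius = 200) {
  stopifnot(match_radius > 0)
  a <- as.matrix(markers_a[, c("x", "y", "z")])
  b <- as.matrix(markers_b[, c("x", "y", "z")])
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("both marker centroid sets must be non-empty",
          class = "smcoloc_estimation_error")
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  nn_ab <- apply(d2, 1, which.min)           # nearest b for each a
  nn_ba <- apply(d2, 2, which.min)           # nearest a for each b
  ia <- seq_len(nrow(a))
  mutual <- nn_ba[nn_ab] == ia &
    d2[cbind(ia, nn_ab)] <= match_radius^2
  if (!any(mutual)) {
    abort("no mutual nearest-neighbour pairs within match_radius",
          class = "smcoloc_estimation_error")
  }
  pa <- a[mutual, , drop = FALSE]
  pb <- b[nn_ab[mutual], , drop = FALSE]
  disp <- pb - pa
  translation <- apply(disp, 2, median)
  res <- sweep(disp, 2, translation)
  structure(list(
    translation = setNames(translation, c("dx", "dy", "dz")),
    n_pairs_used = nrow(disp),
    residual_rms = sqrt(mean(rowSums(res^2)))
  ), class = "chromatic_shift")
}

#' Apply (subtract) a chromatic shift from one channel
#'
#' Subtracts the estimated translation from the named channel's coordinates,
#' mapping it into the reference channel's frame; the other channel is
#' untouched.
#'
#' @param locs Localization tibble.
#' @param shift A [estimate_chromatic_shift()] result, or a numeric
#'   `c(dx, dy, dz)`.
#' @param channel Channel name to correct (default `"mRNA"`).
#' @return Corrected localization tibble.
#' @export
apply_shift <- function(locs, shift, channel = "mRNA") {
  tr <- if (inherits(shift, "chromatic_shift")) shift$translation
        else as.numeric(shift)
  stopifnot(length(tr) == 3)
  sel <- locs$channel == channel
  locs$x[sel] <- locs$x[sel] - tr[[1]]
  locs$y[sel] <- locs$y[sel] - tr[[2]]
  locs$z[sel] <- locs$z[sel] - tr[[3]]
  locs
}

#' @export
print.chromatic_shift <- function(x, ...) {
  cat("Chromatic shift (B - A):",
      sprintf("dx=%.2f dy=%.2f dz=%.2f nm", x$translation[1],
              x$translation[2], x$translation[3]), "\n")
  cat(sprintf("  %d mutual pairs, residual RMS %.2f nm\n",
              x$n_pairs_used, x$residual_rms))
  invisible(x)
}

#' @export
tidy.chromatic_shift <- function(x, ...) {
  tibble(axis = c("x", "y", "z"), shift_nm = unname(x$translation))
}

#' @export
glance.chromatic_shift <- function(x, ...) {
  tibble(dx = x$translation[["dx"]], dy = x$translation[["dy"]],
         dz = x$translation[["dz"]], n_pairs_used = x$n_pairs_used,
         residual_rms = x$residual_rms)
}
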