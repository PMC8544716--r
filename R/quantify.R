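#' Method-of-moments initialization for the negative-binomial spot model
#'
#' For spot counts with sample mean m and sample variance v (> m), the
#' moment estimates under the parameterization
#' P(N = n) = C(n + r - 1, n) p^r (1 - p)^n (mean r(1-p)/p) are
#' p0 = m / v and r0 = m p0 / (1 - p0).
#'
#' @param counts Integer vector of localization-spot counts per cluster.
#' @return List with `r0`, `p0`, `mean`, `var`.
#' @export
nb_moment_init <- function(counts) {
  m <- mean(counts)
  v <- var(counts)
  if (!is.finite(v) || v <= m) {
    abort(paste("spot counts are under-dispersed (variance <= mean);",
                "a negative-binomial model is not identifiable --",
                "consider poisson_fallback = TRUE"),
          class = "smcoloc_underdispersion_error")
  }
  p0 <- m / v
  list(r0 = m * p0 / (1 - p0), p0 = p0, mean = m, var = v)
}

#' Calibrate the localizations-per-molecule model from basal-expression cells
#'
#' In cells expressing only basal RNA levels, clusters are sparse enough to
#' be single molecules, so their spot counts sample the per-molecule
#' localization distribution directly. Fits a negative binomial NB(r, p)
#' (parameterization as in [nb_moment_init()]) by maximum likelihood,
#' initialized at the method-of-moments estimate.
#'
#' @param spot_counts Integer vector of spot counts from basal-condition
#'   clusters (>= `min_counts` values required).
#' @param min_counts Minimum calibration sample size (default 30).
#' @param poisson_fallback If `TRUE` and the counts are under-dispersed,
#'   fit a Poisson model instead of failing.
#' @return A `single_molecule_model` object with fields `family`
#'   (`"nbinom"` or `"poisson"`), `r`, `p` (NB) or `lambda` (Poisson),
#'   `mean`, `loglik`, `n_obs`.
#' @export
fit_single_molecule_model <- function(spot_counts, min_counts = 30,
                                      poisson_fallback = FALSE) {
  spot_counts <- as.numeric(spot_counts)
  stopifnot(all(is.finite(spot_counts)), all(spot_counts >= 0),
            all(spot_counts == round(spot_counts)))
  if (length(spot_counts) < min_counts) {
    abort(sprintf("need at least %d calibration spot counts, got %d",
                  min_counts, length(spot_counts)),
          class = "smcoloc_sample_size_error")
  }
  m <- mean(spot_counts)
  v <- var(spot_counts)
  if (v <= m) {
    if (!poisson_fallback) {
      abort(paste("spot counts are under-dispersed (variance <= mean);",
                  "set poisson_fallback = TRUE to fit a Poisson model"),
            class = "smcoloc_underdispersion_error")
    }
    ll <- sum(dpois(spot_counts, m, log = TRUE))
    return(structure(list(family = "poisson", lambda = m, mean = m,
                          loglik = ll, n_obs = length(spot_counts)),
                     class = "single_molecule_model"))
  }
  init <- nb_moment_init(spot_counts)
  nll <- function(theta) {
    r <- exp(theta[1])
    p <- stats::plogis(theta[2])
    -sum(dnbinom(spot_counts, size = r, prob = p, log = TRUE))
  }
  fit <- optim(c(log(init$r0), stats::qlogis(init$p0)), nll,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  structure(list(family = "nbinom",
                 r = exp(fit$par[1]), p = stats::plogis(fit$par[2]),
                 mean = exp(fit$par[1]) *
                   (1 - stats::plogis(fit$par[2])) / stats::plogis(fit$par[2]),
                 loglik = -fit$value, n_obs = length(spot_counts)),
            class = "single_molecule_model")
}

#' Construct a single-molecule spot model from known parameters
#'
#' @param r,p Negative-binomial size and success probability.
#' @return A `single_molecule_model` object.
#' @export
single_molecule_model <- function(r, p) {
  stopifnot(r > 0, p > 0, p < 1)
  structure(list(family = "nbinom", r = r, p = p, mean = r * (1 - p) / p,
                 loglik = NA_real_, n_obs = NA_integer_),
            class = "single_molecule_model")
}

# per-molecule pmf on 0..n_max
sm_pmf <- function(model, n_max, k = 1) {
  if (model$family == "poisson") {
    dpois(0:n_max, k * model$lambda)
  } else {
    dnbinom(0:n_max, size = k * model$r, prob = model$p)
  }
}

#' Build the copy-number reference matrix P(n | k)
#'
#' Column k of the reference matrix is the probability of observing n
#' localization spots in a cluster made of k overlapping RNA molecules: the
#' k-fold convolution of the single-molecule spot-count distribution. For
#' the NB(r, p) model this convolution equals NB(k r, p) in closed form;
#' the matrix is built by explicit convolution and the closed form serves
#' as an independent check in the test-suite.
#'
#' @param model A `single_molecule_model`.
#' @param k_max Largest copy number represented (default 50).
#' @param n_max Largest spot count row; `NULL` (default) auto-grows until
#'   every column holds at least 99.9% probability mass.
#' @return A `reference_matrix` object: numeric matrix `(n_max+1) x k_max`
#'   with rows n = 0..n_max and columns k = 1..k_max, plus the model it was
#'   built from.
#' @export
build_reference_matrix <- function(model, k_max = 50, n_max = NULL) {
  stopifnot(inherits(model, "single_molecule_model"), k_max >= 1)
  auto <- is.null(n_max)
  if (auto) {
    n_max <- if (model$family == "poisson") {
      stats::qpois(1 - 1e-7, k_max * model$lambda)
    } else {
      qnbinom(1 - 1e-7, size = k_max * model$r, prob = model$p)
    }
  }
  pmf1 <- sm_pmf(model, n_max)
  ent <- matrix(0, nrow = n_max + 1, ncol = k_max)
  ent[, 1] <- pmf1
  if (k_max > 1) {
    for (k in 2:k_max) {
      full <- convolve(ent[, k - 1], rev(pmf1), type = "open")
      ent[, k] <- pmax(full[seq_len(n_max + 1)], 0)
    }
  }
  mass <- colSums(ent)
  if (any(mass < 0.999)) {
    abort(sprintf(
      "n_max = %d truncates the reference matrix: smallest column mass %.6f < 0.999",
      n_max, min(mass)), class = "smcoloc_truncation_error")
  }
  structure(list(entries = ent, k_max = as.integer(k_max),
                 n_max = as.integer(n_max), model = model),
            class = "reference_matrix")
}

#' Estimate RNA copies per cluster from its spot count
#'
#' Inverts the reference matrix by maximum likelihood: k_hat = argmax_k
#' P(n_spots | k) over k = 1..k_max, ties broken toward the smaller k.
#' Spot counts beyond the matrix's n_max are handled with the closed-form
#' pmf. A k_hat at k_max is flagged as saturated.
#'
#' @param n_spots Integer vector of per-cluster spot counts (>= 1).
#' @param ref A [build_reference_matrix()] result.
#' @param rule `"ml"` (default) or `"posterior_mean"` (uniform prior over
#'   k, rounded to the nearest integer).
#' @return Tibble with `n_spots`, `k_hat`, `saturated`.
#' @export
estimate_copy_number <- function(n_spots, ref, rule = c("ml", "posterior_mean")) {
  rule <- match.arg(rule)
  stopifnot(inherits(ref, "reference_matrix"), all(n_spots >= 1))
  n_spots <- as.integer(n_spots)
  khat <- integer(length(n_spots))
  for (i in seq_along(n_spots)) {
    n <- n_spots[i]
    lik <- if (n <= ref$n_max) {
      ref$entries[n + 1, ]
    } else {
      sm_pmf_at <- function(k) {
        if (ref$model$family == "poisson") dpois(n, k * ref$model$lambda)
        else dnbinom(n, size = k * ref$model$r, prob = ref$model$p)
      }
      vapply(seq_len(ref$k_max), sm_pmf_at, numeric(1))
    }
    khat[i] <- if (rule == "ml") {
      which.max(lik)                      # first max: ties go to smaller k
    } else {
      as.integer(round(sum(seq_len(ref$k_max) * lik) / sum(lik)))
    }
  }
  saturated <- khat == ref$k_max
  if (any(saturated)) {
    warn(sprintf("%d cluster(s) hit k_max = %d; copy numbers may be truncated",
                 sum(saturated), ref$k_max))
  }
  tibble(n_spots = n_spots, k_hat = khat, saturated = saturated)
}

#' Sum per-cluster copy estimates into per-cell copy numbers
#'
#' @param clusters Cluster tibble from [cluster_localizations()] (needs
#'   `cell_id`, `channel`, `n_spots`).
#' @param ref A [build_reference_matrix()] result.
#' @param rule Passed to [estimate_copy_number()].
#' @return Tibble `cell_id`, `channel`, `n_clusters`, `raw_copies`.
#' @export
copy_number_table <- function(clusters, ref, rule = "ml") {
  if (nrow(clusters) == 0) {
    return(tibble(cell_id = integer(0), channel = character(0),
                  n_clusters = integer(0), raw_copies = integer(0)))
  }
  est <- estimate_copy_number(clusters$n_spots, ref, rule = rule)
  clusters$k_hat <- est$k_hat
  clusters |>
    dplyr::group_by(.data$cell_id, .data$channel) |>
    dplyr::summarise(n_clusters = dplyr::n(),
                     raw_copies = sum(.data$k_hat), .groups = "drop")
}

#' Nonspecific-binding background model from a deletion-strain control
#'
#' Cells of a strain lacking the probed RNA (e.g. a deletion mutant stained
#' with the same FISH probes) measure the nonspecific probe-binding
#' background. The model is the mean apparent copy number per cell in that
#' control.
#'
#' @param copies_per_cell Numeric vector of apparent copies per background
#'   cell. Cells with zero detected clusters count as zeros and must be
#'   included.
#' @return A `background_model` with `mean_background_copies_per_cell` and
#'   `n_cells`.
#' @export
fit_background_model <- function(copies_per_cell) {
  stopifnot(length(copies_per_cell) >= 1, all(copies_per_cell >= 0))
  structure(list(
    mean_background_copies_per_cell = mean(copies_per_cell),
    n_cells = length(copies_per_cell)), class = "background_model")
}

#' Background-correct per-cell copy numbers
#'
#' Subtracts the mean background copies per cell, clamping at zero.
#'
#' @param raw_copies_per_cell Numeric vector of raw per-cell copy numbers.
#' @param background A [fit_background_model()] result (or a single number).
#' @return Numeric vector of corrected copy numbers (>= 0).
#' @export
correct_background <- function(raw_copies_per_cell, background) {
  bg <- if (inherits(background, "background_model")) {
    background$mean_background_copies_per_cell
  } else {
    as.numeric(background)
  }
  stopifnot(bg >= 0)
  pmax(0, raw_copies_per_cell - bg)
}

#' @export
print.single_molecule_model <- function(x, ...) {
  if (x$family == "poisson") {
    cat(sprintf("Single-molecule spot model: Poisson(lambda = %.3f), n = %s\n",
                x$lambda, format(x$n_obs)))
  } else {
    cat(sprintf(
      "Single-molecule spot model: NB(r = %.3f, p = %.3f), mean %.2f spots, n = %s\n",
      x$r, x$p, x$mean, format(x$n_obs)))
  }
  invisible(x)
}

#' @export
tidy.single_molecule_model <- function(x, ...) {
  if (x$family == "poisson") {
    tibble(term = "lambda", estimate = x$lambda)
  } else {
    tibble(term = c("r", "p"), estimate = c(x$r, x$p))
  }
}

#' @export
glance.single_molecule_model <- function(x, ...) {
  tibble(family = x$family,
         r = if (x$family == "nbinom") x$r else NA_real_,
         p = if (x$family == "nbinom") x$p else NA_real_,
         mean_spots = x$mean, loglik = x$loglik, n_obs = x$n_obs)
}

#' @export
print.reference_matrix <- function(x, ...) {
  cat(sprintf("Reference matrix P(n | k): n = 0..%d, k = 1..%d\n",
              x$n_max, x$k_max))
  invisible(x)
}
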