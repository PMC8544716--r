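#' Apparent dissociation constant from copies and bound fraction
#'
#' Single-site mass action: with S sRNA copies, M mRNA copies and a bound
#' fraction f of the mRNA in a cell of volume V, the complex count is f M,
#' the free counts are S - f M and M (1 - f), and
#' K_D = (S - f M)(1 - f) / (f V) in copies per volume. With V = 1
#' (default) K_D is reported in copies per cell volume, which is all that
#' ratios across conditions of equal cell size need; pass V in litres for a
#' molar-scale constant.
#'
#' @param S sRNA copies per cell (background-corrected).
#' @param M mRNA copies per cell (> 0).
#' @param f Bound (colocalized) fraction of mRNA, in (0, 1).
#' @param V Cell volume (default 1).
#' @param baseline_fraction Random-colocalization fraction subtracted from
#'   `f` before the computation (floored at 0 implicitly through the f > 0
#'   requirement); default 0.
#' @param condition_label Free-text label carried into the result.
#' @return An `affinity_estimate`: `kd`, plus the inputs.
#' @export
estimate_kd <- function(S, M, f, V = 1, baseline_fraction = 0,
                        condition_label = "") {
  stopifnot(S >= 0, M > 0, V > 0, f >= 0, f < 1, baseline_fraction >= 0)
  f_adj <- f - baseline_fraction
  if (f_adj <= 0) {
    abort("bound fraction is 0 after baseline subtraction: K_D unidentified (no complex observed)",
          class = "smcoloc_no_complex_error")
  }
  complex <- f_adj * M
  s_free <- S - complex
  if (s_free < 0) {
    warn(sprintf(
      "f*M = %.2f exceeds S = %.2f (inconsistent data); free sRNA clamped at 0, K_D = 0",
      complex, S))
    s_free <- 0
  }
  kd <- s_free * (1 - f_adj) / (f_adj * V)
  structure(list(kd = kd, S = S, M = M, f = f_adj, V = V,
                 condition_label = condition_label),
            class = "affinity_estimate")
}

#' K_D ratio between two conditions and the affinity fold-change
#'
#' `ratio = kd_test / kd_ref`; since a lower K_D means tighter binding, the
#' fold-change in affinity is the reciprocal, `fold_affinity = 1 / ratio`
#' (a ratio of 0.40 is a 2.5-fold affinity increase).
#'
#' @param kd_test,kd_ref `affinity_estimate` objects or bare K_D numbers
#'   (same volume units).
#' @return Tibble with `ratio` and `fold_affinity`.
#' @export
kd_ratio_and_fold <- function(kd_test, kd_ref) {
  kt <- if (inherits(kd_test, "affinity_estimate")) kd_test$kd
        else as.numeric(kd_test)
  kr <- if (inherits(kd_ref, "affinity_estimate")) kd_ref$kd
        else as.numeric(kd_ref)
  if (kr <= 0) {
    abort("reference K_D must be > 0", class = "smcoloc_param_error")
  }
  ratio <- kt / kr
  tibble(ratio = ratio, fold_affinity = 1 / ratio)
}

#' Equilibrium complex count under single-site mass action
#'
#' Solves (S - C)(M - C) = kd_v C for the physical root:
#' C = ((S + M + kd_v) - sqrt((S + M + kd_v)^2 - 4 S M)) / 2,
#' evaluated in the numerically stable form 2 S M / (b + sqrt(b^2 - 4SM)).
#' This is the forward model shared with the scene simulator and the
#' algebraic inverse of [estimate_kd()].
#'
#' @param S,M Total sRNA and mRNA copies (>= 0); vectorized.
#' @param kd_v K_D times volume, in copies (>= 0).
#' @return Expected complex count C with 0 <= C <= min(S, M).
#' @export
equilibrium_complex_count <- function(S, M, kd_v) {
  stopifnot(all(S >= 0), all(M >= 0), all(kd_v >= 0))
  b <- S + M + kd_v
  disc <- sqrt(pmax(b^2 - 4 * S * M, 0))
  out <- ifelse(b + disc > 0, 2 * S * M / (b + disc), 0)
  pmin(out, pmin(S, M))
}

#' K_D (times volume) that yields a target bound fraction
#'
#' Inverse of the equilibrium: the kd_v at which a cell with S sRNA and M
#' mRNA copies has a bound mRNA fraction f. Used to parameterize synthetic
#' scenes by their intended colocalized fraction.
#'
#' @param S,M Copies per cell.
#' @param f Target bound fraction of mRNA, in (0, 1), with f M <= S.
#' @return kd_v in copies.
#' @export
kd_for_bound_fraction <- function(S, M, f) {
  stopifnot(f > 0, f < 1, f * M <= S)
  (S - f * M) * (1 - f) / f
}

#' @export
print.affinity_estimate <- function(x, ...) {
  lbl <- if (nzchar(x$condition_label)) paste0(" [", x$condition_label, "]")
         else ""
  cat(sprintf(
    "K_D%s = %.3g copies/volume (S = %.1f, M = %.1f, f = %.3f, V = %g)\n",
    lbl, x$kd, x$S, x$M, x$f, x$V))
  invisible(x)
}

#' @export
tidy.affinity_estimate <- function(x, ...) {
  tibble(term = c("kd", "S", "M", "f", "V"),
         estimate = c(x$kd, x$S, x$M, x$f, x$V))
}

#' @export
glance.affinity_estimate <- function(x, ...) {
  tibble(condition = x$condition_label, kd = x$kd, S = x$S, M = x$M,
         f = x$f, V = x$V)
}
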