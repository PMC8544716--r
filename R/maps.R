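#' Fragments Per Kilobase of transcript per Million mapped reads
#'
#' fpkm = count * 1e9 / (length_bp * library_size). Vectorized.
#'
#' @param count Fragment count(s), >= 0.
#' @param length_bp Transcript length(s) in bp, > 0.
#' @param library_size Mapped fragments in the library, > 0.
#' @return FPKM value(s).
#' @export
compute_fpkm <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0)) {
    abort("length_bp must be > 0", class = "smcoloc_param_error")
  }
  if (any(library_size <= 0)) {
    abort("library_size must be > 0", class = "smcoloc_param_error")
  }
  count * 1e9 / (length_bp * library_size)
}

#' Zero-dispersion exact test for a two-group count comparison
#'
#' The dispersion-free limit of the negative-binomial exact test: with no
#' overdispersion the counts are Poisson, so after scaling every replicate
#' to a common library size (the geometric mean of all library sizes) and
#' pooling within groups, the group-A total yA is, conditional on the
#' pooled total T = yA + yB, Binomial(T, NA / (NA + NB)) under the null of
#' equal means -- here NA/(NA+NB) reduces to the share of replicates in
#' group A since all replicates are on the common scale. The two-sided
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one (minimum-likelihood method), capped at 1.
#'
#' @param counts_tagged,counts_control Non-negative integer count vectors,
#'   one entry per replicate.
#' @param lib_tagged,lib_control Library sizes per replicate (default: all
#'   equal).
#' @return Two-sided p-value.
#' @export
exact_test_nodisp <- function(counts_tagged, counts_control,
                              lib_tagged = NULL, lib_control = NULL) {
  stopifnot(all(counts_tagged >= 0), all(counts_control >= 0))
  na <- length(counts_tagged)
  nb <- length(counts_control)
  lib_tagged <- lib_tagged %||% rep(1, na)
  lib_control <- lib_control %||% rep(1, nb)
  stopifnot(length(lib_tagged) == na, length(lib_control) == nb,
            all(lib_tagged > 0), all(lib_control > 0))
  common <- exp(mean(log(c(lib_tagged, lib_control))))
  ya <- round(sum(counts_tagged * common / lib_tagged))
  yb <- round(sum(counts_control * common / lib_control))
  tot <- ya + yb
  if (tot == 0) return(1)
  prob_a <- na / (na + nb)
  pmf <- dbinom(0:tot, tot, prob_a)
  p_obs <- pmf[ya + 1]
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_i = min over j >= i (in ascending-p order) of p_(j) * m / j, capped at
#' 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Per-gene pull-down enrichment table (MAPS statistics)
#'
#' For every gene: mean FPKM in the tagged and control groups (a
#' pseudocount of `pseudocount` fragments is added at the count level
#' before FPKM, for the enrichment ratio only -- never for the test), the
#' log2 enrichment, the zero-dispersion exact-test p-value on the raw
#' counts, the BH q-value across all genes, and two flags:
#' `flag_2x` (enrichment >= 2 and q < 0.05, the volcano-plot thresholds)
#' and `flag_recovered_4x` (enrichment > 4 and q < 0.05, the efficient-
#' recovery rule).
#'
#' @param counts Tibble with columns `gene`, `length_bp`, then one numeric
#'   column per sample.
#' @param samples Tibble with columns `sample` (matching count columns),
#'   `group` (`"tagged"` or `"control"`) and optionally `library_size`
#'   (default: column sums of `counts`).
#' @param pseudocount Fragments added per count for the enrichment ratio
#'   (default 0.5).
#' @param q_cutoff Significance threshold on the q-value (default 0.05).
#' @return Tibble of per-gene enrichment records.
#' @export
enrichment_table <- function(counts, samples, pseudocount = 0.5,
                             q_cutoff = 0.05) {
  stopifnot(all(c("gene", "length_bp") %in% names(counts)),
            all(c("sample", "group") %in% names(samples)),
            all(samples$group %in% c("tagged", "control")),
            all(samples$sample %in% names(counts)))
  if (!any(samples$group == "tagged") || !any(samples$group == "control")) {
    abort("need at least one sample per group",
          class = "smcoloc_param_error")
  }
  bad_len <- !is.finite(counts$length_bp) | counts$length_bp <= 0
  if (any(bad_len)) {
    warn(sprintf("%d gene(s) without a valid length skipped", sum(bad_len)))
    counts <- counts[!bad_len, ]
  }
  cm <- as.matrix(counts[, samples$sample, drop = FALSE])
  lib <- if ("library_size" %in% names(samples) &&
             !all(is.na(samples$library_size))) {
    samples$library_size
  } else {
    colSums(cm)
  }
  tagged <- samples$group == "tagged"
  fpkm_ps <- compute_fpkm(cm + pseudocount, counts$length_bp,
                          matrix(lib, nrow(cm), ncol(cm), byrow = TRUE))
  mean_t <- rowMeans(fpkm_ps[, tagged, drop = FALSE])
  mean_c <- rowMeans(fpkm_ps[, !tagged, drop = FALSE])
  p <- vapply(seq_len(nrow(cm)), function(i) {
    exact_test_nodisp(cm[i, tagged], cm[i, !tagged],
                      lib[tagged], lib[!tagged])
  }, numeric(1))
  q <- bh_adjust(p)
  ratio <- mean_t / mean_c
  tibble(
    gene = counts$gene,
    mean_fpkm_tagged = mean_t,
    mean_fpkm_control = mean_c,
    log2_enrichment = log2(ratio),
    p_value = p,
    q_value = q,
    flag_2x = ratio >= 2 & q < q_cutoff,
    flag_recovered_4x = ratio > 4 & q < q_cutoff)
}

#' Read a gene-level count matrix from TSV
#'
#' Expects columns `gene`, `length_bp`, then one column per sample.
#'
#' @param path TSV file path.
#' @return Count tibble as used by [enrichment_table()].
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("gene", "length_bp"), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("count matrix missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "smcoloc_format_error")
  }
  df
}
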