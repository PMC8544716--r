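#' Run the full imaging analysis pipeline
#'
#' Orchestrates calibrate -> register -> cluster -> quantify -> colocalize
#' -> affinity over one or more imaging conditions and returns a
#' `pipeline_report`. Stages are pure functions of the inputs and the
#' configuration, so a config plus seed reproduces the report exactly.
#'
#' The configuration is a named list (or a path to a YAML file with the
#' same structure):
#' \describe{
#'   \item{conditions}{Named list of fields of view. Each is either a list
#'     with `localizations` (tibble or CSV path) and `rois` (tibble or
#'     JSON path), or a `simulate_scene()` `$fov` element. ROIs labelled
#'     `"marker"` in `strain_label` are used for registration, the rest
#'     for analysis.}
#'   \item{calibration}{Field of view of basal-expression cells; its sRNA
#'     clusters calibrate the single-molecule spot model.}
#'   \item{background}{Optional field of view of deletion-strain control
#'     cells; sets the nonspecific background copies per cell.}
#'   \item{reference_condition}{Optional condition name; K_D ratios and
#'     affinity fold-changes of every other condition are reported against
#'     it.}
#'   \item{params}{Optional list: `eps` (25), `npt` (2), `cutoff` (50),
#'     `volume` (1), `baseline` ("csr", "empirical" or "none"),
#'     `negative_control` (condition name for the empirical baseline),
#'     `match_radius` (200), `k_max` (50), `csr_draws` (500).}
#'   \item{seed}{RNG seed for the Monte-Carlo baseline.}
#'   \item{out_dir}{Optional directory; per-stage TSV/JSON artifacts are
#'     written there.}
#' }
#'
#' @param config Named list or YAML file path as described above.
#' @return A `pipeline_report` (see [tidy.pipeline_report()]).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "smcoloc_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  p <- config$params %||% list()
  params <- list(eps = p$eps %||% 25, npt = p$npt %||% 2,
                 cutoff = p$cutoff %||% 50, volume = p$volume %||% 1,
                 baseline = p$baseline %||% "csr",
                 negative_control = p$negative_control %||% NULL,
                 match_radius = p$match_radius %||% 200,
                 k_max = p$k_max %||% 50, csr_draws = p$csr_draws %||% 500)
  stopifnot(params$baseline %in% c("csr", "empirical", "none"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cp <- cluster_params(eps = params$eps, npt = params$npt)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  warnings_log <- character(0)
  timings <- list()
  collect <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
              class = "smcoloc_pipeline_error", parent = e)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  # ---- load ---------------------------------------------------------------
  load_fov <- function(spec_fov, label) {
    stopifnot(is.list(spec_fov))
    locs <- spec_fov$localizations
    rois <- spec_fov$rois
    if (is.character(locs)) {
      if (!file.exists(locs)) {
        abort(sprintf("localization file not found: %s", locs),
              class = "smcoloc_config_error")
      }
      locs <- read_localizations(locs)
    }
    if (is.character(rois)) {
      if (!file.exists(rois)) {
        abort(sprintf("ROI file not found: %s", rois),
              class = "smcoloc_config_error")
      }
      rois <- read_rois(rois)
    }
    locs <- as_tibble(locs)
    if (all(is.na(locs$cell_id %||% NA))) {
      locs <- assign_to_cells(locs, rois)
    }
    list(localizations = locs, rois = as_tibble(rois),
         condition_label = spec_fov$condition_label %||% label)
  }
  conditions <- config$conditions
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)))
  fovs <- collect("load", purrr::imap(conditions, load_fov))

  # ---- calibrate ----------------------------------------------------------
  if (is.null(config$calibration)) {
    abort("config$calibration (basal-expression field of view) is required",
          class = "smcoloc_config_error")
  }
  calib <- collect("calibrate", {
    cal_fov <- load_fov(config$calibration, "calibration")
    cl <- cluster_localizations(cal_fov$localizations, cp)
    spot_counts <- cl$n_spots[cl$channel == "sRNA"]
    model <- fit_single_molecule_model(spot_counts)
    ref <- build_reference_matrix(model, k_max = params$k_max)
    list(model = model, ref = ref, n_clusters = length(spot_counts))
  })

  # ---- background ---------------------------------------------------------
  background <- NULL
  if (!is.null(config$background)) {
    background <- collect("background", {
      bg_fov <- load_fov(config$background, "background")
      cl <- cluster_localizations(bg_fov$localizations, cp)
      cl <- cl[cl$channel == "sRNA", ]
      per_cell <- copy_number_table(cl, calib$ref)
      analysis_ids <- bg_fov$rois$cell_id[bg_fov$rois$strain_label != "marker"]
      copies <- setNames(rep(0, length(analysis_ids)),
                         as.character(analysis_ids))
      if (nrow(per_cell) > 0) {
        copies[as.character(per_cell$cell_id)] <- per_cell$raw_copies
      }
      fit_background_model(unname(copies))
    })
  }

  # ---- per-condition stages ----------------------------------------------
  cond_results <- list()
  for (nm in names(fovs)) {
    fov <- fovs[[nm]]
    marker_ids <- fov$rois$cell_id[fov$rois$strain_label == "marker"]
    locs <- fov$localizations

    shift <- NULL
    if (length(marker_ids) > 0) {
      shift <- collect(paste0("register:", nm), {
        mk <- locs[locs$cell_id %in% marker_ids & !is.na(locs$cell_id), ]
        mk_cl <- cluster_localizations(mk, cp)
        estimate_chromatic_shift(
          mk_cl[mk_cl$channel == "sRNA", c("cx", "cy", "cz")] |>
            dplyr::rename(x = "cx", y = "cy", z = "cz"),
          mk_cl[mk_cl$channel == "mRNA", c("cx", "cy", "cz")] |>
            dplyr::rename(x = "cx", y = "cy", z = "cz"),
          match_radius = params$match_radius)
      })
      locs <- apply_shift(locs, shift, channel = "mRNA")
    }

    analysis <- locs[!is.na(locs$cell_id) &
                       !(locs$cell_id %in% marker_ids), ]
    clusters <- collect(paste0("cluster:", nm),
                        cluster_localizations(analysis, cp))
    if (!is.null(out_dir)) {
      readr::write_tsv(dplyr::select(clusters, -"members"),
                       file.path(out_dir, paste0("clusters_", nm, ".tsv")),
                       progress = FALSE)
    }

    quant <- collect(paste0("quantify:", nm), {
      per_cell <- copy_number_table(clusters, calib$ref)
      wide <- tidyr::pivot_wider(
        per_cell, id_cols = "cell_id",
        names_from = "channel",
        values_from = c("n_clusters", "raw_copies"),
        values_fill = 0)
      for (col in c("raw_copies_sRNA", "raw_copies_mRNA",
                    "n_clusters_sRNA", "n_clusters_mRNA")) {
        if (!col %in% names(wide)) wide[[col]] <- 0
      }
      wide$corrected_srna <- if (!is.null(background)) {
        correct_background(wide$raw_copies_sRNA, background)
      } else {
        wide$raw_copies_sRNA
      }
      wide
    })
    if (!is.null(out_dir)) {
      readr::write_tsv(quant,
                       file.path(out_dir, paste0("copies_", nm, ".tsv")),
                       progress = FALSE)
    }

    coloc <- collect(paste0("colocalize:", nm), {
      mr <- clusters[clusters$channel == "mRNA", ]
      sr <- clusters[clusters$channel == "sRNA", ]
      if ("replicate" %in% names(analysis)) {
        rep_of <- analysis$replicate[!duplicated(analysis$cell_id)]
        names(rep_of) <- analysis$cell_id[!duplicated(analysis$cell_id)]
        mr$replicate <- rep_of[as.character(mr$cell_id)]
      }
      colocalization_percentage(mr, sr, cutoff = params$cutoff,
                                by = "cell_id")
    })
    cond_results[[nm]] <- list(shift = shift, clusters = clusters,
                               quant = quant, coloc = coloc)
  }

  # ---- baseline -----------------------------------------------------------
  baseline_frac <- 0
  baseline_obj <- NULL
  if (params$baseline == "empirical") {
    ncn <- params$negative_control
    if (is.null(ncn) || !ncn %in% names(cond_results)) {
      abort("empirical baseline requires params$negative_control naming a condition",
            class = "smcoloc_config_error")
    }
    baseline_obj <- cond_results[[ncn]]$coloc
    baseline_frac <- baseline_obj$fraction
  } else if (params$baseline == "csr") {
    baseline_obj <- collect("baseline", {
      first <- fovs[[1]]
      aroi <- first$rois[first$rois$strain_label != "marker", ][1, ]
      vol <- roi_volume(aroi)
      sr_per_cell <- vapply(cond_results, function(cr) {
        mean(cr$quant$n_clusters_sRNA)
      }, numeric(1))
      mr_per_cell <- vapply(cond_results, function(cr) {
        mean(cr$quant$n_clusters_mRNA)
      }, numeric(1))
      csr_baseline(n_mrna = max(1, round(mean(mr_per_cell))),
                   lambda = mean(sr_per_cell) / vol, geometry = aroi,
                   cutoff = params$cutoff, n_draws = params$csr_draws)
    })
    baseline_frac <- baseline_obj$mc_fraction
  }

  # ---- affinity -----------------------------------------------------------
  summary_tbl <- purrr::imap_dfr(cond_results, function(cr, nm) {
    coloc <- set_coloc_baseline(cr$coloc, baseline_obj)
    kd <- tryCatch(
      estimate_kd(S = mean(cr$quant$corrected_srna),
                  M = mean(cr$quant$raw_copies_mRNA),
                  f = cr$coloc$fraction, V = params$volume,
                  baseline_fraction = baseline_frac,
                  condition_label = nm),
      error = function(e) NULL)
    per_rep <- cr$coloc$per_replicate
    tibble(
      condition = nm,
      n_cells = nrow(cr$quant),
      mean_srna_copies = mean(cr$quant$corrected_srna),
      sd_srna_copies = sd(cr$quant$corrected_srna),
      mean_mrna_copies = mean(cr$quant$raw_copies_mRNA),
      coloc_fraction = cr$coloc$fraction,
      coloc_sd_replicates = if (!is.null(per_rep)) sd(per_rep$fraction)
                            else NA_real_,
      baseline_fraction = baseline_frac,
      kd = if (is.null(kd)) NA_real_ else kd$kd)
  })

  comparisons <- NULL
  refc <- config$reference_condition
  if (!is.null(refc)) {
    stopifnot(refc %in% summary_tbl$condition)
    kd_ref <- summary_tbl$kd[summary_tbl$condition == refc]
    others <- summary_tbl$condition[summary_tbl$condition != refc]
    comparisons <- purrr::map_dfr(others, function(nm) {
      kd_t <- summary_tbl$kd[summary_tbl$condition == nm]
      rf <- kd_ratio_and_fold(kd_t, kd_ref)
      tibble(condition = nm, reference = refc,
             kd_ratio = rf$ratio, fold_affinity = rf$fold_affinity)
    })
  }

  report <- structure(list(
    summary = summary_tbl,
    comparisons = comparisons,
    model = calib$model,
    background = background,
    baseline = baseline_obj,
    shifts = purrr::map(cond_results, "shift"),
    params = params,
    seed = config$seed %||% NA,
    warnings = warnings_log,
    config_hash = rlang::hash(list(conditions = names(conditions),
                                   params = params,
                                   seed = config$seed %||% NA))),
    class = "pipeline_report")
  attr(report, "timings") <- timings
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(summary = summary_tbl, comparisons = comparisons,
           warnings = warnings_log),
      file.path(out_dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("smcoloc pipeline report\n")
  cat(sprintf("  spot model: %s\n",
              if (x$model$family == "nbinom")
                sprintf("NB(r = %.2f, p = %.3f)", x$model$r, x$model$p)
              else sprintf("Poisson(%.2f)", x$model$lambda)))
  print(as.data.frame(x$summary), digits = 4, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    print(as.data.frame(x$comparisons), digits = 4, row.names = FALSE)
  }
  if (length(x$warnings) > 0) {
    cat(sprintf("  %d warning(s) collected; see $warnings\n",
                length(x$warnings)))
  }
  invisible(x)
}

#' Tidy a pipeline report into the per-condition summary table
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return The per-condition summary tibble.
#' @export
tidy.pipeline_report <- function(x, ...) x$summary

#' @export
glance.pipeline_report <- function(x, ...) {
  tibble(n_conditions = nrow(x$summary),
         baseline = x$params$baseline,
         cutoff = x$params$cutoff,
         eps = x$params$eps, npt = x$params$npt,
         seed = x$seed, config_hash = x$config_hash)
}
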