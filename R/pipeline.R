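#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end workflow in one declarative
#' object. Defaults follow the analysis protocol: 50 um neighborhood radius,
#' 15 um interaction threshold (strict), K = 10 immune niches, 75/25
#' repeated splits, Boruta at alpha 0.01.
#'
#' @param seed master seed for every stochastic stage.
#' @param radius neighborhood radius, microns.
#' @param interaction_threshold interaction distance threshold, microns.
#' @param K number of immune niches.
#' @param split_fraction training fraction of the repeated splits.
#' @param n_repeats repeated splits for the response model.
#' @param boruta_alpha Boruta decision level.
#' @param normalization interaction-matrix normalization tag.
#' @param similarity_floor phenotyping cosine floor.
#' @param grouping "patient" or "roi" split grouping.
#' @param os_cutoff,pfs_cutoff survival dichotomization cutoffs (months).
#' @return object of class `run_config` (a validated list).
#' @export
run_config <- function(seed = 1L, radius = 50, interaction_threshold = 15,
                       K = 10, split_fraction = 0.75, n_repeats = 100,
                       boruta_alpha = 0.01,
                       normalization = c("per_cell", "raw", "per_area"),
                       similarity_floor = 0.3,
                       grouping = c("patient", "roi"),
                       os_cutoff = 9.3, pfs_cutoff = 6.1) {
  normalization <- match.arg(normalization)
  grouping <- match.arg(grouping)
  stopifnot(radius > 0, interaction_threshold > 0, K >= 1,
            split_fraction > 0, split_fraction < 1, n_repeats >= 1,
            boruta_alpha > 0, boruta_alpha < 1)
  structure(list(seed = as.integer(seed), radius = radius,
                 interaction_threshold = interaction_threshold, K = K,
                 split_fraction = split_fraction, n_repeats = n_repeats,
                 boruta_alpha = boruta_alpha, normalization = normalization,
                 similarity_floor = similarity_floor, grouping = grouping,
                 os_cutoff = os_cutoff, pfs_cutoff = pfs_cutoff),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file with any subset of the configuration fields.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config field(s): ",
                          paste(extra, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full spatial TME analysis workflow
#'
#' Orchestrates the stages on a cell map and optional clinical table:
#' phenotyping (when the map carries marker intensities but no cell types),
#' neighborhood profiles and niche clustering, niche-ratio group comparison,
#' interaction graphs/matrices and their comparison, feature assembly,
#' repeated-split response modeling with Boruta selection, survival-class
#' models, and trial-level clinical summaries. Every intermediate artifact
#' is written to `out_dir` together with a plain-text log and a manifest
#' (config + package version) sufficient to reproduce the run; outputs are
#' deterministic under a fixed config.
#'
#' @param config a [run_config()].
#' @param map a [cell_map()] (or path to a cell table readable with the
#'   default panel).
#' @param clinical optional clinical table (or CSV path); when omitted the
#'   clinical and model stages that need labels are skipped with a warning.
#' @param out_dir output directory (created; one run = one directory).
#' @param panel panel used when `map` is a path (default [panel_pdac7()]).
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, map, clinical = NULL, out_dir,
                         panel = panel_pdac7()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    writeLines(log_lines, log_path)
  }
  stage <- function(name, expr) {
    say("stage ", name, ": start")
    res <- tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    say("stage ", name, ": done")
    res
  }

  if (is.character(map)) map <- read_cell_table(map, panel)
  if (is.character(clinical)) clinical <- read_clinical_table(clinical)
  res <- list(config = config)

  # phenotype: only when intensities are present and types are not
  if (is.null(map$cells$cell_type)) {
    res$gating <- stage("phenotype", {
      z <- zscore_markers(map$cells[, map$panel$markers, drop = FALSE])
      g <- assign_lineage(z, map$panel,
                          similarity_floor = config$similarity_floor)
      map$cells$cell_type <- g$cell_type
      g
    })
    map <- cell_map(map$cells, map$panel, roi_bounds = map$roi_bounds)
    write_cell_table(map, file.path(out_dir, "cells_typed.csv"))
  }

  groups <- NULL
  if (!is.null(clinical)) {
    groups <- stats::setNames(
      ifelse(clinical$responder, "responder", "non-responder"),
      clinical$patient_id)
  }

  res$profiles <- stage("niches", neighborhood_profile(map, config$radius))
  res$niche_model <- stage("niches",
    fit_niches(res$profiles, K = config$K, seed = config$seed))
  roi_groups <- NULL
  if (!is.null(groups)) {
    pat_of_roi <- vapply(split(map$cells$patient_id, map$cells$roi_id),
                         `[`, "", 1L)
    roi_groups <- stats::setNames(groups[pat_of_roi], names(pat_of_roi))
  }
  res$niche_ratios <- niche_ratios(res$niche_model, unit = "roi",
                                   groups = roi_groups)
  utils::write.csv(res$niche_ratios, file.path(out_dir, "niche_ratios.csv"),
                   row.names = FALSE)
  if (!is.null(roi_groups)) {
    num <- vapply(res$niche_ratios, is.numeric, TRUE)
    res$niche_comparison <- compare_group_ratios(
      res$niche_ratios[, num, drop = FALSE], res$niche_ratios$group,
      ref = "responder")
    utils::write.csv(res$niche_comparison,
                     file.path(out_dir, "niche_comparison.csv"),
                     row.names = FALSE)
  }

  res$graph <- stage("interactions",
    build_interaction_graph(map, config$interaction_threshold))
  res$imats <- stage("interactions",
    interaction_matrix(res$graph, map, normalization = config$normalization))
  imat_long <- do.call(rbind, lapply(names(res$imats$matrices), function(r) {
    m <- res$imats$matrices[[r]]
    data.frame(roi_id = r, type_a = rep(rownames(m), ncol(m)),
               type_b = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))
  utils::write.csv(imat_long, file.path(out_dir, "interactions_long.csv"),
                   row.names = FALSE)
  if (!is.null(roi_groups)) {
    res$interaction_comparison <- compare_interactions(
      res$imats, roi_groups[names(res$imats$matrices)],
      pairs = NULL, ref = "responder")
    utils::write.csv(res$interaction_comparison,
                     file.path(out_dir, "interaction_comparison.csv"),
                     row.names = FALSE)
  }

  res$features <- stage("features",
    assemble_features(map, res$imats, clinical = clinical))
  utils::write.csv(res$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  if (!is.null(clinical)) {
    res$response_model <- stage("model", fit_response_model(
      res$features, split_fraction = config$split_fraction,
      n_repeats = config$n_repeats, seed = config$seed,
      grouping = config$grouping))
    utils::write.csv(data.frame(repeat_id = seq_along(res$response_model$auc_values),
                                auc = res$response_model$auc_values),
                     file.path(out_dir, "auc_distribution.csv"),
                     row.names = FALSE)
    res$boruta <- stage("model", boruta_select(
      res$features, alpha = config$boruta_alpha, seed = config$seed))
    utils::write.csv(data.frame(feature = names(res$boruta$decision),
                                decision = as.character(res$boruta$decision),
                                hits = res$boruta$hits,
                                n_iter = res$boruta$n_iter,
                                p_binom = res$boruta$p_binom),
                     file.path(out_dir, "boruta_decisions.csv"),
                     row.names = FALSE)
    res$clinical_summary <- stage("clinical", {
      os <- km_estimate(clinical$os_months, clinical$os_event,
                        landmarks = 12)
      pfs <- km_estimate(clinical$pfs_months, clinical$pfs_event,
                         landmarks = 6)
      list(response = summarize_response(clinical),
           ca199 = ca199_decline(clinical),
           os = os, pfs = pfs)
    })
    cs <- res$clinical_summary
    jsonlite::write_json(list(
      n = cs$response$n,
      counts = as.list(cs$response$counts),
      orr_percent = cs$response$orr_percent,
      dcr_percent = cs$response$dcr_percent,
      ca199 = cs$ca199$table,
      median_os = cs$os$median, median_pfs = cs$pfs$median,
      os_12mo_percent = pct1(cs$os$landmarks$surv[1L] * 100, 100),
      pfs_6mo_percent = pct1(cs$pfs$landmarks$surv[1L] * 100, 100)),
      file.path(out_dir, "clinical_summary.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    warning("no clinical table: model and clinical stages skipped")
    say("stage model/clinical: skipped (no clinical table)")
  }

  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("spatialTME")),
                   n_cells = nrow(map$cells),
                   n_rois = nrow(map$roi_bounds),
                   n_patients = length(unique(map$cells$patient_id)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("run complete")
  invisible(res)
}
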