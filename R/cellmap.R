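#' Cell map container for segmented-cell tables
#'
#' A `cell_map` holds one row per segmented cell (micron-scale centroid
#' coordinates, region of interest, patient, and either an assigned cell type
#' or raw marker intensities), the axis-aligned bounds of each ROI, and the
#' marker panel. Coordinates are continuous microns with the origin at each
#' ROI's lower-left corner; distances between cells are centroid-to-centroid.
#'
#' @param cells data.frame with columns `cell_id`, `roi_id`, `patient_id`,
#'   `x`, `y`, optionally `cell_type`, and optionally one numeric column per
#'   panel marker. `cell_id` is generated when absent.
#' @param panel a [tme_panel()].
#' @param roi_bounds optional data.frame with columns `roi_id`, `xmin`,
#'   `xmax`, `ymin`, `ymax` (microns); inferred as the per-ROI coordinate
#'   extremes when omitted.
#' @param bounds_tol cells may exceed declared bounds by at most this many
#'   microns (default 0).
#' @return An object of class `cell_map` with elements `cells`, `roi_bounds`,
#'   `panel`.
#' @export
cell_map <- function(cells, panel, roi_bounds = NULL, bounds_tol = 0) {
  stopifnot(inherits(panel, "tme_panel"), is.data.frame(cells))
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (!nrow(cells))  # header-only tables read back with logical columns
    for (cc in intersect(c("x", "y", panel$markers), names(cells)))
      cells[[cc]] <- as.numeric(cells[[cc]])
  req <- c("roi_id", "patient_id", "x", "y")
  miss <- setdiff(req, names(cells))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (cc in c("x", "y")) {
    if (!is.numeric(cells[[cc]]))
      stop("non-numeric coordinate column: ", cc)
    if (nrow(cells) && any(!is.finite(cells[[cc]])))
      stop("non-finite values in coordinate column: ", cc)
  }
  cells$roi_id <- as.character(cells$roi_id)
  cells$patient_id <- as.character(cells$patient_id)
  if (is.null(cells$cell_id)) {
    cells$cell_id <- if (nrow(cells)) sprintf("cell_%d", seq_len(nrow(cells))) else character()
  } else cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id values")

  marker_cols <- intersect(panel$markers, names(cells))
  has_type <- "cell_type" %in% names(cells)
  if (nrow(cells) && !has_type && !length(marker_cols))
    stop("cells need at least one of cell_type / marker intensity columns")
  if (has_type) {
    cells$cell_type <- as.character(cells$cell_type)
    known <- c(panel$types, "other", "isolated")
    bad <- setdiff(unique(cells$cell_type[!is.na(cells$cell_type)]), known)
    if (length(bad))
      stop("cell_type value(s) not in panel: ", paste(bad, collapse = ", "))
  }
  for (m in marker_cols) {
    if (!is.numeric(cells[[m]])) stop("non-numeric marker column: ", m)
    if (nrow(cells) && any(cells[[m]] < 0, na.rm = TRUE))
      stop("negative intensities in marker column: ", m)
  }

  # one patient per ROI
  if (nrow(cells)) {
    map <- unique(cells[, c("roi_id", "patient_id")])
    dup <- map$roi_id[duplicated(map$roi_id)]
    if (length(dup))
      stop("ROI mapped to multiple patients: ", paste(unique(dup), collapse = ", "))
  }

  if (is.null(roi_bounds)) {
    roi_bounds <- infer_bounds(cells)
  } else {
    roi_bounds <- as.data.frame(roi_bounds, stringsAsFactors = FALSE)
    bn <- c("roi_id", "xmin", "xmax", "ymin", "ymax")
    if (!all(bn %in% names(roi_bounds)))
      stop("roi_bounds needs columns: ", paste(bn, collapse = ", "))
    roi_bounds <- roi_bounds[, bn]
    roi_bounds$roi_id <- as.character(roi_bounds$roi_id)
    if (anyDuplicated(roi_bounds$roi_id)) stop("duplicate roi_id in bounds")
    if (any(roi_bounds$xmax <= roi_bounds$xmin) ||
        any(roi_bounds$ymax <= roi_bounds$ymin))
      stop("degenerate ROI bounds")
    missing_roi <- setdiff(unique(cells$roi_id), roi_bounds$roi_id)
    if (length(missing_roi))
      stop("no bounds for ROI(s): ", paste(missing_roi, collapse = ", "))
    idx <- match(cells$roi_id, roi_bounds$roi_id)
    out <- cells$x < roi_bounds$xmin[idx] - bounds_tol |
      cells$x > roi_bounds$xmax[idx] + bounds_tol |
      cells$y < roi_bounds$ymin[idx] - bounds_tol |
      cells$y > roi_bounds$ymax[idx] + bounds_tol
    if (any(out))
      stop(sum(out), " cell(s) outside declared ROI bounds (first: ",
           cells$cell_id[which(out)[1L]], ")")
  }
  rownames(cells) <- NULL
  structure(list(cells = cells, roi_bounds = roi_bounds, panel = panel),
            class = "cell_map")
}

infer_bounds <- function(cells) {
  if (!nrow(cells))
    return(data.frame(roi_id = character(), xmin = numeric(),
                      xmax = numeric(), ymin = numeric(), ymax = numeric(),
                      stringsAsFactors = FALSE))
  sp <- split(seq_len(nrow(cells)), cells$roi_id)
  out <- do.call(rbind, lapply(names(sp), function(r) {
    i <- sp[[r]]
    data.frame(roi_id = r, xmin = min(cells$x[i]), xmax = max(cells$x[i]),
               ymin = min(cells$y[i]), ymax = max(cells$y[i]),
               stringsAsFactors = FALSE)
  }))
  # guard against zero-width bounds for single-cell ROIs
  eps <- 1e-9
  out$xmax <- pmax(out$xmax, out$xmin + eps)
  out$ymax <- pmax(out$ymax, out$ymin + eps)
  rownames(out) <- NULL
  out
}

#' @export
print.cell_map <- function(x, ...) {
  cat("cell_map:", nrow(x$cells), "cells,",
      nrow(x$roi_bounds), "ROIs,",
      length(unique(x$cells$patient_id)), "patients\n")
  if ("cell_type" %in% names(x$cells)) {
    tab <- sort(table(x$cells$cell_type), decreasing = TRUE)
    cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.cell_map <- function(object, ...) {
  cells <- object$cells
  per_roi <- as.data.frame(table(roi_id = cells$roi_id),
                           stringsAsFactors = FALSE)
  names(per_roi)[2L] <- "n_cells"
  per_roi$area_mm2 <- roi_areas(object)[per_roi$roi_id]
  per_roi$density_mm2 <- per_roi$n_cells / per_roi$area_mm2
  per_roi
}

#' Per-ROI area in square millimeters
#'
#' @param x a `cell_map`.
#' @return named numeric vector of ROI areas (mm^2).
#' @export
roi_areas <- function(x) {
  stopifnot(inherits(x, "cell_map"))
  b <- x$roi_bounds
  stats::setNames((b$xmax - b$xmin) * (b$ymax - b$ymin) / 1e6, b$roi_id)
}

#' Read a segmented-cell table
#'
#' Reads a delimited text file (comma-separated for `.csv`, tab-separated for
#' `.tsv`/`.txt`) with one row per cell, validates it against the panel, and
#' returns a [cell_map()]. ROI bounds are read from a key-value sidecar file
#' when given, else inferred from coordinate extremes.
#'
#' @param path path to the cell table.
#' @param panel a [tme_panel()].
#' @param bounds_path optional path to a bounds sidecar written by
#'   [write_cell_table()].
#' @return A `cell_map`.
#' @export
read_cell_table <- function(path, panel, bounds_path = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  cells <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
  bounds <- if (!is.null(bounds_path)) read_bounds_sidecar(bounds_path)
  cell_map(cells, panel, roi_bounds = bounds)
}

#' Write a segmented-cell table
#'
#' Writes the cell table as delimited text (full `%.17g` precision, so
#' [read_cell_table()] after `write_cell_table()` is the identity), and the
#' ROI bounds to a key-value sidecar when `bounds_path` is given.
#'
#' @param x a `cell_map`.
#' @param path output path (`.csv` comma-separated, `.tsv`/`.txt` tab).
#' @param bounds_path optional sidecar path for the ROI bounds.
#' @return Invisibly, `path`.
#' @export
write_cell_table <- function(x, path, bounds_path = NULL) {
  stopifnot(inherits(x, "cell_map"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- x$cells
  for (cc in names(df)) if (is.numeric(df[[cc]]) && !is.integer(df[[cc]]))
    df[[cc]] <- sprintf("%.17g", df[[cc]])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(bounds_path)) write_bounds_sidecar(x$roi_bounds, bounds_path)
  invisible(path)
}

write_bounds_sidecar <- function(bounds, path) {
  lines <- sprintf("roi_id=%s xmin=%.17g xmax=%.17g ymin=%.17g ymax=%.17g",
                   bounds$roi_id, bounds$xmin, bounds$xmax,
                   bounds$ymin, bounds$ymax)
  writeLines(lines, path)
  invisible(path)
}

read_bounds_sidecar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parse1 <- function(ln) {
    kv <- strsplit(strsplit(trimws(ln), "[[:space:]]+")[[1L]], "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    data.frame(roi_id = vals[["roi_id"]],
               xmin = as.numeric(vals[["xmin"]]),
               xmax = as.numeric(vals[["xmax"]]),
               ymin = as.numeric(vals[["ymin"]]),
               ymax = as.numeric(vals[["ymax"]]),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(lines, parse1))
}

#' Read a per-patient clinical table
#'
#' One row per patient with best overall response, survival times/events, and
#' optional CA19-9 baseline/nadir concentrations (U/mL). The `responder`
#' column (best response CR or PR) is derived and, when present in the file,
#' cross-checked.
#'
#' @param path CSV path with columns `patient_id`, `best_response`, and
#'   optionally `os_months`, `os_event`, `pfs_months`, `pfs_event`,
#'   `ca199_baseline`, `ca199_nadir`.
#' @return data.frame of class `clinical_table`.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' Validate (and derive fields of) a clinical table
#'
#' @param df data.frame as described in [read_clinical_table()].
#' @return the validated data.frame, with `responder` derived, of class
#'   `clinical_table`.
#' @export
validate_clinical <- function(df) {
  if (!all(c("patient_id", "best_response") %in% names(df)))
    stop("clinical table needs patient_id and best_response columns")
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id")
  ok <- c("CR", "PR", "SD", "PD")
  bad <- setdiff(unique(df$best_response), ok)
  if (length(bad))
    stop("unknown best_response value(s): ", paste(bad, collapse = ", "))
  resp <- df$best_response %in% c("CR", "PR")
  if (!is.null(df$responder)) {
    if (!identical(as.logical(df$responder), resp))
      stop("responder column inconsistent with best_response")
  }
  df$responder <- resp
  for (cc in c("os_months", "pfs_months")) if (!is.null(df[[cc]])) {
    if (any(df[[cc]] < 0, na.rm = TRUE)) stop("negative times in ", cc)
  }
  for (cc in c("os_event", "pfs_event")) if (!is.null(df[[cc]]))
    df[[cc]] <- as.logical(df[[cc]])
  for (cc in c("ca199_baseline", "ca199_nadir")) if (!is.null(df[[cc]])) {
    if (any(df[[cc]] < 0, na.rm = TRUE)) stop("negative concentrations in ", cc)
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' @rdname read_clinical_table
#' @param df clinical data.frame.
#' @param path output CSV path.
#' @export
write_clinical_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
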