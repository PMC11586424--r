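#' Z-score marker intensities
#'
#' Centers and scales each marker column to mean 0, SD 1 over all cells in
#' the analysis set, using the population SD convention (divisor n). Columns
#' with zero SD are set to all-zero rather than dropped.
#'
#' @param x numeric matrix or data.frame of intensities, cells x markers.
#' @return numeric matrix of z-scores with the input's dimnames.
#' @export
zscore_markers <- function(x) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("empty intensity table")
  if (nrow(x) < 2L) stop("z-scoring needs at least 2 cells")
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu)^2))  # population SD
  z <- sweep(x, 2L, mu)
  keep <- sdev > 0
  z[, keep] <- sweep(z[, keep, drop = FALSE], 2L, sdev[keep], "/")
  z[, !keep] <- 0
  z
}

# collapse panel signature rows to lineage level; split-marker columns of
# split lineages are zeroed so the split is decided after lineage assignment
lineage_signatures <- function(panel) {
  lins <- unique(panel$lineages)
  sig <- t(vapply(lins, function(l) {
    colMeans(panel$signature[panel$lineages == l, , drop = FALSE])
  }, numeric(length(panel$markers))))
  dimnames(sig) <- list(lins, panel$markers)
  if (!is.null(panel$split)) {
    split_lins <- names(panel$split$positive)
    sig[split_lins, panel$split$marker] <- 0
  }
  sig
}

#' Assign cell lineages from z-scored marker intensities
#'
#' Nearest-signature gating: each cell is assigned the lineage whose panel
#' signature row has the highest cosine similarity to the cell's z-scored
#' marker vector; cells whose best similarity falls below `similarity_floor`
#' are labeled "other". Exact similarity ties are broken by the panel's
#' declared priority order, deterministically. After lineage assignment,
#' lineages declared in the panel's split rule (macrophages, tumor cells) are
#' divided into PD-L1+/- types by a z-score threshold on the split marker,
#' and a proliferation (Ki67) flag is set when the panel declares one.
#'
#' @param z z-scored intensity matrix from [zscore_markers()] (columns must
#'   match the panel's markers).
#' @param panel a [tme_panel()].
#' @param similarity_floor minimum cosine similarity for a lineage call
#'   (default 0.3).
#' @param truth optional character vector of true types for a confusion
#'   summary.
#' @return object of class `gating_result`: list with `cell_type` (one label
#'   per cell, including "other"), `score` (best cosine), `proliferating`
#'   (logical or NULL), `confusion` and `accuracy` (when `truth` given).
#' @export
assign_lineage <- function(z, panel, similarity_floor = 0.3, truth = NULL) {
  z <- as.matrix(z)
  if (!identical(colnames(z), panel$markers)) {
    if (!all(panel$markers %in% colnames(z)))
      stop("marker columns do not match panel")
    z <- z[, panel$markers, drop = FALSE]
  }
  lsig <- lineage_signatures(panel)
  norms <- sqrt(rowSums(lsig^2))
  usable <- norms > 0
  lsig_u <- lsig[usable, , drop = FALSE] / norms[usable]
  zn <- sqrt(rowSums(z^2))
  sim <- z %*% t(lsig_u)
  sim <- sim / ifelse(zn > 0, zn, 1)  # zero-norm cells get similarity 0
  # lineage priority = order of first appearance in the type priority list
  lin_prio <- unique(panel$lineages[panel$priority])
  lin_prio <- lin_prio[lin_prio %in% colnames(sim)]
  sim <- sim[, lin_prio, drop = FALSE]
  best <- max.col(sim, ties.method = "first")  # earlier column wins ties
  score <- sim[cbind(seq_len(nrow(sim)), best)]
  lineage <- colnames(sim)[best]
  fallback <- if ("Other" %in% panel$types) "Other" else "other"
  lineage[score < similarity_floor] <- fallback

  type <- lineage
  if (!is.null(panel$split)) {
    spl <- panel$split
    zsplit <- z[, spl$marker]
    for (l in names(spl$positive)) {
      in_l <- lineage == l
      type[in_l] <- ifelse(zsplit[in_l] > spl$z_threshold,
                           spl$positive[[l]], spl$negative[[l]])
    }
  }
  # non-split lineages that name a single panel type keep that type label
  proliferating <- NULL
  if (!is.null(panel$proliferation) &&
      panel$proliferation$marker %in% colnames(z))
    proliferating <- z[, panel$proliferation$marker] >
      panel$proliferation$z_threshold

  res <- list(cell_type = unname(type), score = unname(score),
              proliferating = proliferating,
              similarity_floor = similarity_floor)
  if (!is.null(truth)) {
    res$confusion <- table(truth = truth, assigned = type)
    res$accuracy <- mean(type == truth)
  }
  structure(res, class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  tab <- sort(table(x$cell_type), decreasing = TRUE)
  cat("gating_result:", length(x$cell_type), "cells\n  ")
  cat(paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (!is.null(x$accuracy))
    cat("  accuracy vs truth:", format(x$accuracy, digits = 4), "\n")
  invisible(x)
}

#' Select target-rich hotspot windows
#'
#' Deterministic replacement for manual hotspot (CTL-rich region) selection:
#' slides a `roi_size` window over each region of the map on a `step`-micron
#' grid and greedily returns up to `k` non-overlapping windows in descending
#' order of target-type cell count. Cells are counted in half-open windows
#' `[x0, x0+w) x [y0, y0+h)` aligned to the grid.
#'
#' @param map a [cell_map()] with typed cells.
#' @param target_type cell type to maximize (default "CTL").
#' @param roi_size window `c(width, height)` in microns.
#' @param k maximum number of windows per region.
#' @param step grid step in microns (default 10).
#' @return data.frame with `region`, `roi_id`, `x0`, `y0`, `width`, `height`,
#'   `n_target`; zero rows (with a warning) when the map has no target cells.
#' @export
select_hotspot_rois <- function(map, target_type = "CTL",
                                roi_size = c(500, 500), k = 3, step = 10) {
  stopifnot(inherits(map, "cell_map"), k >= 1, step > 0)
  cells <- map$cells
  if (is.null(cells$cell_type)) stop("hotspot selection needs typed cells")
  empty <- data.frame(region = character(), roi_id = character(),
                      x0 = numeric(), y0 = numeric(), width = numeric(),
                      height = numeric(), n_target = integer(),
                      stringsAsFactors = FALSE)
  if (!any(cells$cell_type == target_type)) {
    warning("no cells of target type '", target_type, "' in map")
    return(empty)
  }
  out <- list()
  for (ri in seq_len(nrow(map$roi_bounds))) {
    b <- map$roi_bounds[ri, ]
    w <- b$xmax - b$xmin; h <- b$ymax - b$ymin
    if (roi_size[1L] > w || roi_size[2L] > h)
      stop("roi_size larger than map bounds for region ", b$roi_id)
    sel <- cells$roi_id == b$roi_id & cells$cell_type == target_type
    if (!any(sel)) next
    nwx <- ceiling(roi_size[1L] / step)
    nwy <- ceiling(roi_size[2L] / step)
    nbx <- max(nwx, floor(w / step))
    nby <- max(nwy, floor(h / step))
    ix <- pmin(floor((cells$x[sel] - b$xmin) / step) + 1L, nbx)
    iy <- pmin(floor((cells$y[sel] - b$ymin) / step) + 1L, nby)
    cnt <- matrix(0L, nbx, nby)
    for (q in seq_along(ix)) cnt[ix[q], iy[q]] <- cnt[ix[q], iy[q]] + 1L
    sat <- cnt  # summed-area table: sat[i, j] = sum(cnt[1:i, 1:j])
    if (nbx > 1L) sat <- apply(sat, 2L, cumsum)
    sat <- matrix(sat, nbx, nby)
    if (nby > 1L) sat <- t(apply(sat, 1L, cumsum))
    sat <- matrix(sat, nbx, nby)
    block_sum <- function(i0, j0) {  # bins i0..i0+nwx-1, j0..j0+nwy-1
      i1 <- i0 + nwx - 1L; j1 <- j0 + nwy - 1L
      s <- sat[i1, j1]
      if (i0 > 1L) s <- s - sat[i0 - 1L, j1]
      if (j0 > 1L) s <- s - sat[i1, j0 - 1L]
      if (i0 > 1L && j0 > 1L) s <- s + sat[i0 - 1L, j0 - 1L]
      s
    }
    no_x <- nbx - nwx + 1L; no_y <- nby - nwy + 1L
    win <- matrix(0L, no_x, no_y)
    for (i0 in seq_len(no_x)) for (j0 in seq_len(no_y))
      win[i0, j0] <- block_sum(i0, j0)
    for (pick in seq_len(k)) {
      mx <- max(win)
      if (mx <= 0) break
      hit <- which(win == mx, arr.ind = TRUE)
      hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
      i0 <- hit[[1L]]; j0 <- hit[[2L]]
      out[[length(out) + 1L]] <- data.frame(
        region = b$roi_id,
        roi_id = sprintf("%s_H%d", b$roi_id, pick),
        x0 = b$xmin + (i0 - 1L) * step, y0 = b$ymin + (j0 - 1L) * step,
        width = nwx * step, height = nwy * step,
        n_target = as.integer(mx), stringsAsFactors = FALSE)
      # mask every window origin overlapping the chosen window
      bi <- max(1L, i0 - nwx + 1L):min(no_x, i0 + nwx - 1L)
      bj <- max(1L, j0 - nwy + 1L):min(no_y, j0 + nwy - 1L)
      win[bi, bj] <- -1L
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Crop hotspot windows out of a map
#'
#' Builds a new [cell_map()] containing only the cells inside the selected
#' windows, with window-local coordinates (origin at each window's lower-left
#' corner) and the window `roi_id`s.
#'
#' @param map a [cell_map()].
#' @param windows data.frame from [select_hotspot_rois()].
#' @return A `cell_map`.
#' @export
crop_hotspots <- function(map, windows) {
  stopifnot(inherits(map, "cell_map"), nrow(windows) > 0)
  cells <- map$cells
  parts <- lapply(seq_len(nrow(windows)), function(i) {
    wn <- windows[i, ]
    sel <- cells$roi_id == wn$region &
      cells$x >= wn$x0 & cells$x < wn$x0 + wn$width &
      cells$y >= wn$y0 & cells$y < wn$y0 + wn$height
    sub <- cells[sel, , drop = FALSE]
    sub$roi_id <- wn$roi_id
    sub$x <- sub$x - wn$x0
    sub$y <- sub$y - wn$y0
    sub
  })
  out <- do.call(rbind, parts)
  bounds <- data.frame(roi_id = windows$roi_id, xmin = 0,
                       xmax = windows$width, ymin = 0, ymax = windows$height,
                       stringsAsFactors = FALSE)
  cell_map(out, map$panel, roi_bounds = bounds)
}
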