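#' Radius-based neighborhood composition profiles
#'
#' For every cell, the fraction of each cell type among its neighbors — all
#' cells of the same ROI whose centroid lies within `radius` microns (closed
#' ball, the index cell itself excluded). Cells with no neighbor get an
#' all-zero profile and `neighbor_count` 0.
#'
#' @param map a [cell_map()] with typed cells.
#' @param radius neighborhood radius in microns (default 50).
#' @return object of class `neighborhood_profiles`: list with `profiles`
#'   (cells x types fraction matrix), `neighbor_count`, `cell_id`, `roi_id`,
#'   `patient_id`, `cell_type`, `radius`.
#' @export
neighborhood_profile <- function(map, radius = 50) {
  stopifnot(inherits(map, "cell_map"), radius > 0)
  cells <- map$cells
  if (is.null(cells$cell_type) || anyNA(cells$cell_type))
    stop("neighborhood profiles need typed cells")
  types <- union(map$panel$types, sort(unique(cells$cell_type)))
  n <- nrow(cells)
  counts <- matrix(0L, n, length(types), dimnames = list(NULL, types))
  type_idx <- match(cells$cell_type, types)
  for (r in unique(cells$roi_id)) {
    idx <- which(cells$roi_id == r)
    if (length(idx) < 2L) next
    pr <- radius_pairs(cells$x[idx], cells$y[idx], radius, strict = FALSE)
    if (!nrow(pr)) next
    gi <- idx[pr[, 1L]]; gj <- idx[pr[, 2L]]
    ti <- type_idx[gi]; tj <- type_idx[gj]
    # both directions of each undirected pair, tallied by (cell, neighbor type)
    lin <- c(gi, gj) + n * (c(tj, ti) - 1L)
    counts <- counts + tabulate(lin, nbins = n * length(types))
  }
  ncount <- rowSums(counts)
  prof <- counts / ifelse(ncount > 0, ncount, 1)
  structure(list(profiles = prof, neighbor_count = as.integer(ncount),
                 cell_id = cells$cell_id, roi_id = cells$roi_id,
                 patient_id = cells$patient_id, cell_type = cells$cell_type,
                 radius = radius),
            class = "neighborhood_profiles")
}

#' @export
print.neighborhood_profiles <- function(x, ...) {
  cat("neighborhood_profiles:", nrow(x$profiles), "cells, radius",
      x$radius, "um;", sum(x$neighbor_count == 0L), "isolated\n")
  invisible(x)
}

#' Cluster neighborhood profiles into immune niches
#'
#' K-means over the neighbor-composition vectors of all cells with at least
#' one neighbor, with `n_init` random restarts under a fixed seed (lowest
#' within-cluster sum of squares wins). Niche ids are relabeled IN-0, IN-1,
#' ... in descending cluster-size order so ids are reproducible; zero-neighbor
#' cells receive the reserved label "isolated" and are excluded from fitting.
#'
#' @param profiles a [neighborhood_profile()] result.
#' @param K number of niches (default 10).
#' @param seed integer seed.
#' @param n_init number of K-means restarts (default 10).
#' @return object of class `niche_model`: `K`, `centroids` (K x types),
#'   `assignments` (per cell, "IN-0".."IN-(K-1)" or "isolated"), `inertia`,
#'   `sizes`, `seed`, plus the profile metadata.
#' @export
fit_niches <- function(profiles, K = 10, seed = 1L, n_init = 10) {
  stopifnot(inherits(profiles, "neighborhood_profiles"), K >= 1)
  keep <- profiles$neighbor_count > 0L
  x <- profiles$profiles[keep, , drop = FALSE]
  if (nrow(x) < K)
    stop("K exceeds the number of distinct neighborhood profiles")
  set.seed(sub_seed(seed, "kmeans"))
  km <- tryCatch(
    withCallingHandlers(
      stats::kmeans(x, centers = K, nstart = n_init, iter.max = 100L),
      warning = function(w) {
        # Quick-TRANSfer chatter on very large maps; restarts still pick the
        # best of n_init converged solutions
        if (grepl("Quick-TRANSfer", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) {
      if (grepl("distinct", conditionMessage(e)))
        stop("K exceeds the number of distinct neighborhood profiles",
             call. = FALSE)
      stop(e)
    })
  # deterministic relabeling: descending size, centroid columns break ties
  ord <- do.call(order, c(list(-km$size),
                          lapply(seq_len(ncol(km$centers)),
                                 function(j) km$centers[, j])))
  relabel <- integer(K); relabel[ord] <- seq_len(K)
  ids <- sprintf("IN-%d", relabel[km$cluster] - 1L)
  assignments <- rep("isolated", length(keep))
  assignments[keep] <- ids
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- sprintf("IN-%d", seq_len(K) - 1L)
  structure(list(K = K, centroids = centroids, assignments = assignments,
                 inertia = km$tot.withinss,
                 sizes = stats::setNames(km$size[ord], rownames(centroids)),
                 seed = seed, radius = profiles$radius,
                 cell_id = profiles$cell_id, roi_id = profiles$roi_id,
                 patient_id = profiles$patient_id),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat("niche_model: K =", x$K, "| radius", x$radius, "um | inertia",
      format(x$inertia, digits = 6), "\n")
  print(x$sizes)
  invisible(x)
}

#' @export
summary.niche_model <- function(object, ...) {
  cat("Niche centroids (neighbor-type fractions):\n")
  print(round(object$centroids, 3))
  invisible(object$centroids)
}

#' @export
predict.niche_model <- function(object, newdata, ...) {
  if (inherits(newdata, "neighborhood_profiles")) {
    prof <- newdata$profiles[, colnames(object$centroids), drop = FALSE]
    iso <- newdata$neighbor_count == 0L
  } else {
    prof <- as.matrix(newdata)[, colnames(object$centroids), drop = FALSE]
    iso <- rep(FALSE, nrow(prof))
  }
  d2 <- outer(rowSums(prof^2), rep(1, object$K)) -
    2 * prof %*% t(object$centroids) +
    outer(rep(1, nrow(prof)), rowSums(object$centroids^2))
  out <- rownames(object$centroids)[max.col(-d2, ties.method = "first")]
  out[iso] <- "isolated"
  out
}

#' Per-unit niche proportion table
#'
#' Proportion of each unit's cells assigned to each niche; rows sum to 1
#' (the "isolated" pseudo-niche is included as a column when present).
#'
#' @param model a [fit_niches()] result.
#' @param unit "roi" or "patient".
#' @param groups optional named vector (by unit id) of group labels to attach
#'   (e.g. responder status).
#' @return data.frame with `unit`, one proportion column per niche, and
#'   optionally `group`; class `niche_ratio_table`.
#' @export
niche_ratios <- function(model, unit = c("roi", "patient"), groups = NULL) {
  stopifnot(inherits(model, "niche_model"))
  unit <- match.arg(unit)
  uid <- if (unit == "roi") model$roi_id else model$patient_id
  niches <- rownames(model$centroids)
  if (any(model$assignments == "isolated")) niches <- c(niches, "isolated")
  tab <- table(uid, factor(model$assignments, niches))
  prop <- as.matrix(unclass(tab)) / rowSums(tab)
  out <- data.frame(unit = rownames(prop), prop, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(groups)) out$group <- unname(groups[out$unit])
  class(out) <- c("niche_ratio_table", "data.frame")
  out
}

#' Two-group comparison of per-unit variables
#'
#' Compares every variable (niche ratio, cell ratio, interaction intensity,
#' ...) between two groups of units with a two-sided Mann-Whitney test
#' (default) or Welch t test, and reports the group mean difference, its
#' direction, and Benjamini-Hochberg adjusted p values across variables.
#'
#' @param x numeric matrix/data.frame (units x variables) or a numeric
#'   vector (one variable).
#' @param groups vector of two group labels, one per unit.
#' @param method "wilcox" (Mann-Whitney, default) or "welch".
#' @param ref optional reference (first) group label; the mean difference is
#'   `mean(ref) - mean(other)`.
#' @return data.frame with `variable`, `statistic`, `p`, `p_adj`,
#'   `mean_diff`, `direction` (+1 higher in the reference group).
#' @export
compare_group_ratios <- function(x, groups, method = c("wilcox", "welch"),
                                 ref = NULL) {
  method <- match.arg(method)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L,
                                   dimnames = list(NULL, "value"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(x))
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required")
  if (!is.null(ref)) lev <- c(ref, setdiff(lev, ref))
  ga <- groups == lev[1L]
  if (sum(ga) < 2L || sum(!ga) < 2L)
    stop("each group needs at least 2 units")
  res <- lapply(seq_len(ncol(x)), function(j) {
    a <- x[ga, j]; b <- x[!ga, j]
    md <- mean(a) - mean(b)
    if (stats::sd(c(a, b)) == 0) {
      stat <- if (method == "wilcox") length(a) * length(b) / 2 else 0
      p <- 1
    } else if (method == "wilcox") {
      ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                correct = TRUE))
      stat <- unname(ht$statistic); p <- ht$p.value
    } else {
      ht <- stats::t.test(a, b, var.equal = FALSE)
      stat <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(variable = colnames(x)[j], statistic = stat, p = p,
               mean_diff = md, direction = sign(md),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out <- out[, c("variable", "statistic", "p", "p_adj", "mean_diff",
                 "direction")]
  rownames(out) <- NULL
  out
}

#' Agglomerative clustering of units by niche composition
#'
#' Ward (default) hierarchical clustering of the per-unit niche proportion
#' vectors (Euclidean distance). Units are ordered deterministically by their
#' ids before clustering, so the result does not depend on input order.
#'
#' @param ratio_table a [niche_ratios()] table.
#' @param linkage `stats::hclust` method (default "ward.D2").
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust`, `clusters` (named integer vector when `k`
#'   given), `unit`.
#' @export
cluster_units_by_niches <- function(ratio_table, linkage = "ward.D2",
                                    k = NULL) {
  stopifnot(nrow(ratio_table) >= 2L)
  num <- vapply(ratio_table, is.numeric, TRUE)
  m <- as.matrix(ratio_table[, num, drop = FALSE])
  rownames(m) <- ratio_table$unit
  m <- m[order(rownames(m)), , drop = FALSE]  # deterministic tie-break
  hc <- stats::hclust(stats::dist(m), method = linkage)
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k)
  list(hclust = hc, clusters = clusters, unit = rownames(m))
}

#' Radius sensitivity sweep for neighborhood profiles
#'
#' Recomputes neighborhood profiles over a grid of radii and summarizes how
#' neighborhood size and isolation change, to support choosing the radius.
#'
#' @param map a [cell_map()] with typed cells.
#' @param radii numeric vector of radii (microns).
#' @return data.frame with `radius`, `mean_neighbors`, `median_neighbors`,
#'   `frac_isolated`.
#' @export
neighborhood_radius_sweep <- function(map, radii = c(25, 50, 75, 100)) {
  do.call(rbind, lapply(radii, function(r) {
    pr <- neighborhood_profile(map, r)
    data.frame(radius = r,
               mean_neighbors = mean(pr$neighbor_count),
               median_neighbors = stats::median(pr$neighbor_count),
               frac_isolated = mean(pr$neighbor_count == 0L))
  }))
}

#' K-means elbow curve over niche counts
#'
#' Fits [fit_niches()] across a grid of K and returns the clustering
#' objective (total within-cluster sum of squares) for an elbow plot.
#'
#' @param profiles a [neighborhood_profile()] result.
#' @param Ks integer vector of niche counts to try.
#' @param seed,n_init passed to [fit_niches()].
#' @return data.frame with `K` and `inertia`.
#' @export
niche_elbow <- function(profiles, Ks = 2:12, seed = 1L, n_init = 5) {
  do.call(rbind, lapply(Ks, function(k) data.frame(
    K = k, inertia = fit_niches(profiles, K = k, seed = seed,
                                n_init = n_init)$inertia)))
}
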