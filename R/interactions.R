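#' Distance-threshold cell-cell interaction graph
#'
#' Two cells of the same ROI interact when their centroid distance is
#' strictly below the threshold (default 15 microns); exact ties are
#' excluded. Edges are undirected, without self-edges or duplicates, and
#' never cross ROIs.
#'
#' @param map a [cell_map()].
#' @param threshold distance threshold in microns (default 15, strict `<`).
#' @return object of class `interaction_graph`: list with `edges`
#'   (data.frame `roi_id`, `i`, `j` — cell ids with `i < j` by position) and
#'   `threshold`.
#' @export
build_interaction_graph <- function(map, threshold = 15) {
  stopifnot(inherits(map, "cell_map"), threshold > 0)
  cells <- map$cells
  parts <- list()
  for (r in unique(cells$roi_id)) {
    idx <- which(cells$roi_id == r)
    if (length(idx) < 2L) next
    pr <- radius_pairs(cells$x[idx], cells$y[idx], threshold, strict = TRUE)
    if (!nrow(pr)) next
    parts[[r]] <- data.frame(roi_id = r,
                             i = cells$cell_id[idx[pr[, 1L]]],
                             j = cells$cell_id[idx[pr[, 2L]]],
                             stringsAsFactors = FALSE)
  }
  edges <- if (length(parts)) do.call(rbind, parts)
           else data.frame(roi_id = character(), i = character(),
                           j = character(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(edges = edges, threshold = threshold),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("interaction_graph:", nrow(x$edges), "edges (<",
      x$threshold, "um) across", length(unique(x$edges$roi_id)), "ROIs\n")
  invisible(x)
}

#' Per-ROI type-by-type interaction matrices
#'
#' Counts, for every ROI, the edges joining each unordered pair of cell
#' types: entry (a, b) is the number of edges with one type-a and one type-b
#' endpoint; same-type edges count once (so the matrix total, counting the
#' off-diagonal once, equals the ROI's edge count). Normalizations:
#' `"raw"` counts; `"per_cell"` divides entry (a, b) by `min(n_a, n_b)`
#' (0/0 -> 0), so ROI size does not dominate; `"per_area"` divides by the
#' ROI area in mm^2.
#'
#' @param graph a [build_interaction_graph()] result.
#' @param map the [cell_map()] the graph was built from.
#' @param normalization "per_cell" (default), "raw" or "per_area".
#' @return object of class `interaction_matrices`: list with `matrices`
#'   (named list of symmetric type x type matrices, one per ROI),
#'   `normalization`, `threshold`, `patient` (named by ROI).
#' @export
interaction_matrix <- function(graph, map,
                               normalization = c("per_cell", "raw", "per_area")) {
  stopifnot(inherits(graph, "interaction_graph"), inherits(map, "cell_map"))
  normalization <- match.arg(normalization)
  cells <- map$cells
  if (is.null(cells$cell_type) || anyNA(cells$cell_type))
    stop("interaction matrices need typed cells")
  types <- union(map$panel$types, sort(unique(cells$cell_type)))
  nt <- length(types)
  type_of <- stats::setNames(match(cells$cell_type, types), cells$cell_id)
  areas <- roi_areas(map)
  rois <- unique(cells$roi_id)
  mats <- vector("list", length(rois)); names(mats) <- rois
  for (r in rois) {
    m <- matrix(0, nt, nt, dimnames = list(types, types))
    e <- graph$edges[graph$edges$roi_id == r, , drop = FALSE]
    if (nrow(e)) {
      ta <- type_of[e$i]; tb <- type_of[e$j]
      lo <- pmin(ta, tb); hi <- pmax(ta, tb)
      tab <- tabulate(lo + nt * (hi - 1L), nbins = nt * nt)
      m_upper <- matrix(tab, nt, nt, dimnames = list(types, types))
      m <- m_upper + t(m_upper)
      diag(m) <- diag(m_upper)  # same-type edges count once
    }
    if (normalization == "per_cell") {
      cnt <- tabulate(type_of[cells$cell_id[cells$roi_id == r]], nbins = nt)
      denom <- outer(cnt, cnt, pmin)
      m <- ifelse(denom > 0, m / denom, 0)
      dimnames(m) <- list(types, types)
    } else if (normalization == "per_area") {
      m <- m / areas[[r]]
    }
    mats[[r]] <- m
  }
  pat <- vapply(rois, function(r) cells$patient_id[match(r, cells$roi_id)], "")
  structure(list(matrices = mats, normalization = normalization,
                 threshold = graph$threshold,
                 patient = stats::setNames(pat, rois)),
            class = "interaction_matrices")
}

#' @export
print.interaction_matrices <- function(x, ...) {
  cat("interaction_matrices:", length(x$matrices), "ROIs, normalization",
      x$normalization, "\n")
  invisible(x)
}

# flatten selected unordered type pairs of each ROI matrix into a
# ROIs x pairs feature matrix; pairs default to all unordered pairs
pair_matrix <- function(imats, pairs = NULL, types = NULL) {
  stopifnot(inherits(imats, "interaction_matrices"))
  all_types <- rownames(imats$matrices[[1L]])
  if (is.null(types)) types <- all_types
  if (is.null(pairs)) {
    cmb <- utils::combn(types, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
  }
  labs <- vapply(pairs, paste, "", collapse = "|")
  out <- t(vapply(imats$matrices, function(m)
    vapply(pairs, function(p) m[p[1L], p[2L]], 0), numeric(length(pairs))))
  colnames(out) <- labs
  out
}

#' Compare interaction intensities between two groups
#'
#' Extracts the selected unordered type-pair entries of each ROI's
#' interaction matrix and delegates to [compare_group_ratios()], with
#' Benjamini-Hochberg adjustment across pairs.
#'
#' @param imats an [interaction_matrix()] result.
#' @param groups vector of two group labels, one per ROI (in the order of
#'   `imats$matrices`), or a named vector by ROI id.
#' @param pairs list of length-2 character vectors of type pairs; default all
#'   unordered pairs of the matrix's types.
#' @param method passed to [compare_group_ratios()].
#' @param ref reference group label (see [compare_group_ratios()]).
#' @return data.frame as from [compare_group_ratios()], one row per pair.
#' @export
compare_interactions <- function(imats, groups, pairs = NULL,
                                 method = c("wilcox", "welch"), ref = NULL) {
  bad <- setdiff(unlist(pairs), rownames(imats$matrices[[1L]]))
  if (length(bad)) stop("pair type(s) absent from panel: ",
                        paste(bad, collapse = ", "))
  x <- pair_matrix(imats, pairs)
  if (!is.null(names(groups))) groups <- groups[names(imats$matrices)]
  compare_group_ratios(x, groups, method = match.arg(method), ref = ref)
}

#' Label-shuffle null for interaction counts
#'
#' Holds cell positions (and hence the interaction graph) fixed and shuffles
#' cell-type labels within each ROI, recomputing the pooled raw interaction
#' matrix per permutation. Returns the observed pooled matrix, the null mean
#' and SD per entry, and the z-score of observed versus null, which
#' contextualizes raw counts against the composition-matched expectation.
#'
#' @param map a [cell_map()] with typed cells.
#' @param threshold interaction distance threshold, microns.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `observed`, `null_mean`, `null_sd`, `z` (type x type
#'   matrices), `n_perm`, `threshold`.
#' @export
interaction_permutation_null <- function(map, threshold = 15, n_perm = 200,
                                         seed = 1L) {
  stopifnot(n_perm >= 100)
  graph <- build_interaction_graph(map, threshold)
  cells <- map$cells
  types <- union(map$panel$types, sort(unique(cells$cell_type)))
  nt <- length(types)
  pooled <- function(type_idx_by_id) {
    m <- matrix(0, nt, nt)
    ta <- type_idx_by_id[graph$edges$i]; tb <- type_idx_by_id[graph$edges$j]
    if (length(ta)) {
      lo <- pmin(ta, tb); hi <- pmax(ta, tb)
      up <- matrix(tabulate(lo + nt * (hi - 1L), nbins = nt * nt), nt, nt)
      m <- up + t(up); diag(m) <- diag(up)
    }
    dimnames(m) <- list(types, types)
    m
  }
  type_idx <- stats::setNames(match(cells$cell_type, types), cells$cell_id)
  obs <- pooled(type_idx)
  set.seed(sub_seed(seed, "permnull"))
  roi_split <- split(seq_len(nrow(cells)), cells$roi_id)
  acc <- matrix(0, nt, nt); acc2 <- matrix(0, nt, nt)
  for (b in seq_len(n_perm)) {
    perm <- type_idx
    for (idx in roi_split) {
      ids <- cells$cell_id[idx]
      perm[ids] <- perm[ids][sample.int(length(idx))]
    }
    m <- pooled(perm)
    acc <- acc + m; acc2 <- acc2 + m * m
  }
  mu <- acc / n_perm
  sdv <- sqrt(pmax(acc2 / n_perm - mu^2, 0))
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  dimnames(z) <- dimnames(mu) <- dimnames(sdv) <- list(types, types)
  list(observed = obs, null_mean = mu, null_sd = sdv, z = z,
       n_perm = n_perm, threshold = threshold)
}
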