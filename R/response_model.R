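#' Assemble the per-ROI multi-layer feature table
#'
#' One row per ROI with the three feature layers used for response modeling:
#' per-type cell ratios (count / total cells), per-type cell densities
#' (cells per mm^2 of ROI area), and the interaction intensities of every
#' unordered pair among the panel's non-tumor types (15 pairs for the 7-type
#' panel), taken from the supplied interaction matrices under their
#' normalization. With the default 7-type panel this yields 29 feature
#' columns (7 + 7 + 15).
#'
#' @param map a [cell_map()] with typed cells.
#' @param imats an [interaction_matrix()] result covering the map's ROIs.
#' @param clinical optional clinical table; adds a `responder` column by
#'   patient.
#' @param panel the panel (defaults to the map's).
#' @return data.frame of class `feature_table`: `roi_id`, `patient_id`,
#'   feature columns `ratio_*`, `density_*`, `inter_*`, and optionally
#'   `responder`.
#' @export
assemble_features <- function(map, imats, clinical = NULL,
                              panel = map$panel) {
  stopifnot(inherits(map, "cell_map"), inherits(imats, "interaction_matrices"))
  cells <- map$cells
  if (is.null(cells$cell_type)) stop("feature assembly needs typed cells")
  types <- panel$types
  areas <- roi_areas(map)
  rois <- names(imats$matrices)
  missing_roi <- setdiff(unique(cells$roi_id), rois)
  if (length(missing_roi))
    stop("interaction matrices missing for ROI(s): ",
         paste(missing_roi, collapse = ", "))
  if (anyNA(areas[rois])) stop("ROI area missing")
  non_tumor <- setdiff(types, panel$tumor_types)
  cmb <- utils::combn(non_tumor, 2L)
  rows <- lapply(rois, function(r) {
    sel <- cells$roi_id == r
    cnt <- table(factor(cells$cell_type[sel], types))
    total <- sum(sel)
    ratio <- as.numeric(cnt) / max(total, 1L)
    dens <- as.numeric(cnt) / areas[[r]]
    m <- imats$matrices[[r]]
    inter <- vapply(seq_len(ncol(cmb)),
                    function(k) m[cmb[1L, k], cmb[2L, k]], 0)
    vals <- c(ratio, dens, inter)
    names(vals) <- c(paste0("ratio_", types), paste0("density_", types),
                     paste0("inter_", cmb[1L, ], ".", cmb[2L, ]))
    c(list(roi_id = r, patient_id = unname(imats$patient[[r]])),
      as.list(vals))
  })
  out <- do.call(rbind, lapply(rows, function(rr)
    as.data.frame(rr, stringsAsFactors = FALSE, check.names = FALSE)))
  if (anyNA(out)) stop("missing values after feature assembly")
  if (!is.null(clinical)) {
    idx <- match(out$patient_id, clinical$patient_id)
    if (anyNA(idx)) stop("patients missing from clinical table")
    out$responder <- clinical$responder[idx]
  }
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_columns <- function(features) {
  grep("^(ratio|density|inter)_", names(features), value = TRUE)
}

# stratified split of units into train/test; returns logical train indicator
stratified_split <- function(unit_labels, split_fraction) {
  train <- logical(length(unit_labels))
  for (lv in unique(unit_labels)) {
    idx <- which(unit_labels == lv)
    n_tr <- round(length(idx) * split_fraction)
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Repeated-split L1 logistic response model
#'
#' For each repeat: a stratified train/test split (by default grouped by
#' patient, so no patient contributes ROIs to both sides), feature
#' standardization fitted on the training rows only, L1-regularized logistic
#' regression with the regularization strength chosen by internal
#' cross-validation on the training set (one-standard-error rule), and AUC
#' evaluated on the held-out rows. Returns the full AUC distribution across
#' repeats.
#'
#' @param features a [assemble_features()] table (or numeric matrix).
#' @param labels binary labels per row; defaults to `features$responder`.
#' @param split_fraction training fraction (default 0.75).
#' @param n_repeats number of repeated splits (default 100).
#' @param seed integer master seed.
#' @param grouping "patient" (default; split by patient) or "roi" (split
#'   rows independently, the literal 149-ROI protocol).
#' @param nfolds,nlambda internal cross-validation folds (default 5) and
#'   path length (default 20).
#' @return object of class `response_model`: `auc_values`, `mean_auc`,
#'   `coefficients` (features+intercept x repeats), `lambda` per repeat,
#'   `n_redraws`, and the call parameters.
#' @export
fit_response_model <- function(features, labels = NULL, split_fraction = 0.75,
                               n_repeats = 100, seed = 1L,
                               grouping = c("patient", "roi"),
                               nfolds = 5, nlambda = 20) {
  grouping <- match.arg(grouping)
  stopifnot(split_fraction > 0, split_fraction < 1, n_repeats >= 1)
  if (is.data.frame(features)) {
    fc <- feature_columns(features)
    x <- as.matrix(features[, fc, drop = FALSE])
    pid <- if ("patient_id" %in% names(features)) features$patient_id
           else as.character(seq_len(nrow(features)))
    if (is.null(labels)) labels <- features$responder
  } else {
    x <- as.matrix(features)
    pid <- as.character(seq_len(nrow(x)))
  }
  if (is.null(labels)) stop("labels required")
  y <- as.logical(labels)
  stopifnot(length(y) == nrow(x), !anyNA(y))
  if (min(table(y)) < 5L) stop("need >= 5 rows per class")
  if (grouping == "roi") pid <- as.character(seq_len(nrow(x)))
  units <- unique(pid)
  unit_y <- y[match(units, pid)]

  auc <- numeric(n_repeats)
  lambda <- numeric(n_repeats)
  splits <- matrix(NA, nrow(x), n_repeats)
  coefs <- matrix(NA_real_, ncol(x) + 1L, n_repeats,
                  dimnames = list(c("(Intercept)", colnames(x)), NULL))
  n_redraws <- 0L
  for (rep_i in seq_len(n_repeats)) {
    for (attempt in 0:19) {
      set.seed(sub_seed(seed, "split", rep_i * 100L + attempt))
      tr_units <- units[stratified_split(unit_y, split_fraction)]
      tr <- pid %in% tr_units
      if (length(unique(y[tr])) == 2L && length(unique(y[!tr])) == 2L) break
      n_redraws <- n_redraws + 1L
    }
    mu <- colMeans(x[tr, , drop = FALSE])
    sdev <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    sdev[sdev == 0 | is.na(sdev)] <- 1
    xs <- sweep(sweep(x, 2L, mu), 2L, sdev, "/")
    nf <- max(3L, min(nfolds, min(table(y[tr]))))
    set.seed(sub_seed(seed, "cv", rep_i))
    # glmnet warns about small folds/classes at toy scale; the guards above
    # already enforce the usable minimum
    cv <- suppressWarnings(
      glmnet::cv.glmnet(xs[tr, , drop = FALSE], y[tr],
                        family = "binomial", alpha = 1,
                        nfolds = nf, nlambda = nlambda,
                        standardize = FALSE))
    lam <- cv$lambda.1se
    pred <- as.numeric(stats::predict(cv, xs[!tr, , drop = FALSE], s = lam))
    auc[rep_i] <- auc_score(pred, y[!tr])
    lambda[rep_i] <- lam
    splits[, rep_i] <- tr
    coefs[, rep_i] <- as.numeric(stats::coef(cv, s = lam))
  }
  structure(list(auc_values = auc, mean_auc = mean(auc),
                 coefficients = coefs, lambda = lambda,
                 splits = splits, patient_id = pid,
                 split_fraction = split_fraction, n_repeats = n_repeats,
                 grouping = grouping, seed = seed, n_redraws = n_redraws),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat("response_model:", x$n_repeats, "repeated", x$split_fraction,
      "splits, grouping =", x$grouping, "\n")
  cat("  mean AUC:", format(x$mean_auc, digits = 4),
      " (SD", format(stats::sd(x$auc_values), digits = 3), ")\n")
  invisible(x)
}

#' @export
summary.response_model <- function(object, n_top = 8, ...) {
  print(object)
  mc <- rowMeans(object$coefficients)[-1L]
  sel_rate <- rowMeans(object$coefficients[-1L, , drop = FALSE] != 0)
  top <- order(-abs(mc))[seq_len(min(n_top, length(mc)))]
  cat("  top coefficients (mean over repeats, selection rate):\n")
  for (i in top)
    cat(sprintf("    %-28s %8.4f  %4.0f%%\n", names(mc)[i], mc[i],
                100 * sel_rate[i]))
  invisible(data.frame(feature = names(mc), mean_coef = mc,
                       selection_rate = sel_rate, row.names = NULL))
}

#' @export
plot.response_model <- function(x, ...) {
  graphics::hist(x$auc_values, breaks = 20, col = "grey80",
                 main = "Held-out AUC across repeated splits",
                 xlab = "AUC", ...)
  graphics::abline(v = x$mean_auc, col = "red3", lwd = 2)
  invisible(x)
}

#' Boruta all-relevant feature selection
#'
#' Shadow-feature procedure: each iteration appends a permuted ("shadow")
#' copy of every still-active feature, scores the joint set with the
#' random-forest Gini importance ([rf_importance()]), and records a hit for
#' each real feature whose importance exceeds the maximum shadow importance.
#' A two-sided exact binomial test on the hit count (null: hit probability
#' 1/2) confirms or rejects features at level `alpha`; features undecided
#' after `max_iter` iterations remain tentative. Rejected features are
#' dropped from subsequent forests.
#'
#' @param x numeric matrix or [assemble_features()] table.
#' @param y binary labels (defaults to `x$responder` for feature tables).
#' @param alpha decision level (default 0.01).
#' @param max_iter maximum iterations (default 50).
#' @param num_trees trees per forest (default 300).
#' @param seed integer master seed.
#' @param min_iter first iteration at which decisions are attempted
#'   (default 5; confirmation is mathematically impossible before
#'   `ceiling(log2(1/alpha))` iterations).
#' @return object of class `boruta_result`: `decision` (named factor:
#'   confirmed/rejected/tentative), `hits`, `n_iter`, `p_binom`,
#'   `decided_at`, `importance_history`, `shadow_max`, `alpha`.
#' @export
boruta_select <- function(x, y = NULL, alpha = 0.01, max_iter = 50,
                          num_trees = 300, seed = 1L, min_iter = 5) {
  stopifnot(alpha > 0, alpha < 1, max_iter >= 1)
  if (is.data.frame(x)) {
    if (is.null(y)) y <- x$responder
    fc <- feature_columns(x)
    if (length(fc)) x <- x[, fc, drop = FALSE]
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as.logical(y)
  if (length(unique(y)) < 2L) stop("degenerate labels: one class only")
  p <- ncol(x)
  feats <- colnames(x)
  decision <- stats::setNames(rep("tentative", p), feats)
  hits <- stats::setNames(integer(p), feats)
  n_iter <- stats::setNames(integer(p), feats)
  decided_at <- stats::setNames(rep(NA_integer_, p), feats)
  imp_hist <- matrix(NA_real_, max_iter, p, dimnames = list(NULL, feats))
  shadow_max <- rep(NA_real_, max_iter)
  for (it in seq_len(max_iter)) {
    active <- decision != "rejected"
    und <- names(decision)[decision == "tentative"]
    if (!length(und)) break
    xa <- x[, active, drop = FALSE]
    set.seed(sub_seed(seed, "shadow", it))
    xs <- apply(xa, 2L, sample)
    colnames(xs) <- paste0(".shadow.", colnames(xa))
    imp <- rf_importance(cbind(xa, xs), y, num_trees = num_trees,
                         seed = sub_seed(seed, "forest", it))
    real_imp <- imp[colnames(xa)]
    smax <- max(imp[colnames(xs)])
    imp_hist[it, colnames(xa)] <- real_imp
    shadow_max[it] <- smax
    hits[und] <- hits[und] + (real_imp[und] > smax)
    n_iter[und] <- it
    if (it >= min_iter) {
      for (f in und) {
        p_conf <- stats::pbinom(hits[[f]] - 1L, it, 0.5, lower.tail = FALSE)
        p_rej <- stats::pbinom(hits[[f]], it, 0.5)
        if (p_conf < alpha) {
          decision[f] <- "confirmed"; decided_at[f] <- it
        } else if (p_rej < alpha) {
          decision[f] <- "rejected"; decided_at[f] <- it
        }
      }
    }
  }
  p_binom <- vapply(feats, function(f) {
    k <- hits[[f]]; n <- n_iter[[f]]
    min(1, 2 * min(stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE),
                   stats::pbinom(k, n, 0.5)))
  }, 0)
  structure(list(decision = factor(decision,
                                   c("confirmed", "tentative", "rejected")),
                 hits = hits, n_iter = n_iter, p_binom = p_binom,
                 decided_at = decided_at,
                 importance_history = imp_hist[seq_len(max(n_iter)), ,
                                               drop = FALSE],
                 shadow_max = shadow_max[seq_len(max(n_iter))],
                 alpha = alpha),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$decision)
  cat("boruta_result:", tab[["confirmed"]], "confirmed,",
      tab[["rejected"]], "rejected,", tab[["tentative"]], "tentative",
      sprintf("(alpha = %g)\n", x$alpha))
  conf <- names(x$decision)[x$decision == "confirmed"]
  if (length(conf)) {
    mi <- colMeans(x$importance_history[, conf, drop = FALSE], na.rm = TRUE)
    conf <- conf[order(-mi)]
    cat("  confirmed:", paste(conf, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Survival-class prediction model
#'
#' Dichotomizes patients at a survival cutoff (long: time >= cutoff;
#' short: event before cutoff; patients censored before the cutoff are
#' excluded, with a message) and delegates to [fit_response_model()] on the
#' ROI feature rows of the retained patients.
#'
#' @param features a [assemble_features()] table with `patient_id`.
#' @param times,events patient-level survival times (months) and event
#'   indicators, named by patient id (or aligned with `features` rows).
#' @param cutoff dichotomization time in months (> 0).
#' @param ... passed to [fit_response_model()].
#' @return a `response_model`; the label is `TRUE` for the long-survival
#'   class. Attribute `n_excluded` counts censored-before-cutoff patients.
#' @export
fit_survival_class_model <- function(features, times, events, cutoff, ...) {
  stopifnot(cutoff > 0)
  pid <- features$patient_id
  if (!is.null(names(times))) {
    t_row <- times[pid]; e_row <- as.logical(events[pid])
  } else {
    stopifnot(length(times) == nrow(features))
    t_row <- times; e_row <- as.logical(events)
  }
  long <- t_row >= cutoff
  excluded <- !long & !e_row  # censored before the cutoff: class unknown
  if (any(excluded))
    message(length(unique(pid[excluded])),
            " patient(s) censored before cutoff excluded")
  keep <- !excluded
  if (length(unique(long[keep])) < 2L)
    stop("one survival class empty at cutoff ", cutoff)
  fit <- fit_response_model(features[keep, , drop = FALSE],
                            labels = long[keep], ...)
  attr(fit, "n_excluded") <- length(unique(pid[excluded]))
  attr(fit, "cutoff") <- cutoff
  fit
}

#' Resolve tentative Boruta features
#'
#' Features still tentative after the iteration budget are resolved by the
#' standard rough fix: a feature is confirmed if its median importance across
#' the iterations it was tested exceeds the median of the shadow maxima over
#' the same iterations, and rejected otherwise.
#'
#' @param x a [boruta_select()] result.
#' @return the result with `decision` updated and the original decisions
#'   kept in `decision_unresolved`.
#' @export
resolve_tentative <- function(x) {
  stopifnot(inherits(x, "boruta_result"))
  x$decision_unresolved <- x$decision
  tent <- names(x$decision)[x$decision == "tentative"]
  for (f in tent) {
    hist <- x$importance_history[, f]
    tested <- !is.na(hist)
    med_imp <- stats::median(hist[tested])
    med_shadow <- stats::median(x$shadow_max[tested])
    x$decision[f] <- if (med_imp > med_shadow) "confirmed" else "rejected"
  }
  x
}
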