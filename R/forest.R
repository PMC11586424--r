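#' Random-forest feature importance
#'
#' Gini (mean decrease in impurity) importance from a compact random forest
#' for binary classification: bootstrap resampling of rows, per-node `mtry`
#' feature sampling, exhaustive best-split search, importance accumulated as
#' the sample-weighted impurity decrease of each split and averaged over
#' trees. This forest exists only to score features (it is the Boruta
#' backend); it does not predict.
#'
#' @param x numeric matrix or data.frame of features.
#' @param y binary labels (logical, 0/1, or 2-level factor).
#' @param num_trees number of trees (default 300).
#' @param mtry features tried per node (default `floor(sqrt(p))`).
#' @param min_node minimum samples per child node (default 5).
#' @param max_depth maximum tree depth (default 12).
#' @param seed optional integer seed (sets the R RNG).
#' @return named numeric vector of importances.
#' @export
rf_importance <- function(x, y, num_trees = 300, mtry = NULL, min_node = 5,
                          max_depth = 12, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("y must be binary")
    y <- as.integer(y) - 1L
  } else y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) stop("degenerate labels: one class only")
  stopifnot(length(y) == nrow(x))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (!is.null(seed)) set.seed(seed)
  imp <- .rf_importance_cpp(x, y, as.integer(num_trees), as.integer(mtry),
                            as.integer(min_node), as.integer(max_depth))
  stats::setNames(imp, colnames(x))
}
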