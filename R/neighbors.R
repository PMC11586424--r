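# Fixed-radius neighbor search by uniform grid binning.
#
# Returns all index pairs (i < j) whose Euclidean distance is <= r (closed,
# `strict = FALSE`) or < r (open, `strict = TRUE`). Cells are binned into an
# r-sized grid; only same-bin and forward-neighbor-bin pairs are compared, so
# the result is exact and each pair is produced once.
radius_pairs <- function(x, y, r, strict = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n, r > 0)
  empty <- cbind(i = integer(), j = integer())
  if (n < 2L) return(empty)
  bx <- floor((x - min(x)) / r)
  by <- floor((y - min(y)) / r)
  nbx <- max(bx) + 1L
  key <- bx * (max(by) + 3L) + by  # unique key per occupied bin
  bins <- split(seq_len(n), key)
  keys <- as.numeric(names(bins))
  stride <- max(by) + 3L
  lookup <- new.env(hash = TRUE, size = length(bins))
  for (k in seq_along(keys)) assign(as.character(keys[k]), k, envir = lookup)
  cmp <- function(d2, r2) if (strict) d2 < r2 else d2 <= r2
  r2 <- r * r
  out_i <- vector("list", length(bins) * 5L)
  out_j <- vector("list", length(bins) * 5L)
  pos <- 0L
  # forward offsets cover each bin pair once: same bin, E, NE, N, NW
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  for (k in seq_along(bins)) {
    ii <- bins[[k]]
    m <- length(ii)
    if (m > 1L) {  # within-bin pairs
      dx <- outer(x[ii], x[ii], "-"); dy <- outer(y[ii], y[ii], "-")
      d2 <- dx * dx + dy * dy
      sel <- which(upper.tri(d2) & cmp(d2, r2), arr.ind = TRUE)
      if (nrow(sel)) {
        pos <- pos + 1L
        out_i[[pos]] <- ii[sel[, 1L]]
        out_j[[pos]] <- ii[sel[, 2L]]
      }
    }
    for (o in offs) {
      k2 <- get0(as.character(keys[k] + o[1L] * stride + o[2L]),
                 envir = lookup, ifnotfound = NULL)
      if (is.null(k2)) next
      jj <- bins[[k2]]
      dx <- outer(x[ii], x[jj], "-"); dy <- outer(y[ii], y[jj], "-")
      d2 <- dx * dx + dy * dy
      sel <- which(cmp(d2, r2), arr.ind = TRUE)
      if (nrow(sel)) {
        pos <- pos + 1L
        out_i[[pos]] <- ii[sel[, 1L]]
        out_j[[pos]] <- jj[sel[, 2L]]
      }
    }
  }
  if (!pos) return(empty)
  i <- unlist(out_i[seq_len(pos)], use.names = FALSE)
  j <- unlist(out_j[seq_len(pos)], use.names = FALSE)
  swap <- i > j
  if (any(swap)) { tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp }
  ord <- order(i, j)
  cbind(i = i[ord], j = j[ord])
}
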