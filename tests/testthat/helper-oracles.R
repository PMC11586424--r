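# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's spatial-index code paths.

# all index pairs (i < j) within distance r, by full distance matrix
brute_pairs <- function(x, y, r, strict = FALSE) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  keep <- if (strict) d < r else d <= r
  sel <- which(upper.tri(d) & keep, arr.ind = TRUE)
  sel <- sel[order(sel[, 1L], sel[, 2L]), , drop = FALSE]
  cbind(i = unname(sel[, 1L]), j = unname(sel[, 2L]))
}

# brute-force neighborhood composition profiles (closed ball, self excluded)
brute_profiles <- function(cells, radius, types) {
  n <- nrow(cells)
  prof <- matrix(0, n, length(types), dimnames = list(NULL, types))
  ncount <- integer(n)
  for (i in seq_len(n)) {
    sel <- cells$roi_id == cells$roi_id[i]
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    nb <- which(sel & d <= radius)
    nb <- setdiff(nb, i)
    ncount[i] <- length(nb)
    if (length(nb)) {
      tab <- table(factor(cells$cell_type[nb], types))
      prof[i, ] <- as.numeric(tab) / length(nb)
    }
  }
  list(profiles = prof, neighbor_count = ncount)
}

# quick typed map on a window, uniform positions, given type labels
make_typed_map <- function(types_vec, seed = 1, width = 1000, height = 1000,
                           panel = panel_pdac7(), roi_id = "R1",
                           patient_id = "P1") {
  set.seed(seed)
  n <- length(types_vec)
  cell_map(data.frame(
    cell_id = paste0(roi_id, "_c", seq_len(n)), roi_id = roi_id,
    patient_id = patient_id,
    x = runif(n, 0, width), y = runif(n, 0, height),
    cell_type = types_vec, stringsAsFactors = FALSE),
    panel,
    roi_bounds = data.frame(roi_id = roi_id, xmin = 0, xmax = width,
                            ymin = 0, ymax = height))
}

# independent two-group log-rank computation (observed minus expected form)
brute_logrank <- function(ta, ea, tb, eb) {
  time <- c(ta, tb); event <- c(ea, eb) != 0
  ga <- rep(c(TRUE, FALSE), c(length(ta), length(tb)))
  ev_times <- sort(unique(time[event]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk); na <- sum(at_risk & ga)
    d <- sum(event & time == t)
    da <- sum(event & time == t & ga)
    O <- O + da
    E <- E + d * na / n
    if (n > 1)
      V <- V + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# exact two-stage operating characteristics, written independently of the
# package (direct double sum over stage-1 and stage-2 outcomes)
brute_two_stage <- function(r1, n1, r, n, p) {
  pet <- sum(dbinom(0:r1, n1, p))
  rej <- 0
  for (x1 in (r1 + 1):n1)
    for (x2 in 0:(n - n1))
      if (x1 + x2 > r)
        rej <- rej + dbinom(x1, n1, p) * dbinom(x2, n - n1, p)
  list(pet = pet, p_reject = rej, expected_n = n1 + (1 - pet) * (n - n1))
}
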