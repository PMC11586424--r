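# Deterministic seed splitting: every stochastic sub-stream of a simulation
# or model fit derives its own seed from the master seed, a stream label and
# an index, so sub-streams are independently reproducible. Kept < 2^31 - 2.
sub_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 100003 + h * 10007 + index * 101) %% 2147483629)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label names), ~0 for independent ones.
#'
#' @param a,b vectors of cluster labels (any type), same length.
#' @return numeric scalar.
#' @export
adj_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of a score for a binary label; ties in the
#' score contribute 1/2.
#'
#' @param scores numeric predictions (larger = more positive).
#' @param labels logical or 0/1 vector.
#' @return numeric scalar in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("auc_score needs both classes")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# format a percentage to one decimal, as printed in clinical reports
pct1 <- function(k, n) round(100 * k / n, 1)

#' Percentage rate to one decimal
#'
#' Trial-report convention: `100 * events / n` rounded to one decimal place
#' (e.g. 24 of 72 -> 33.3).
#'
#' @param events count of events.
#' @param n denominator.
#' @return numeric scalar.
#' @export
percent_rate <- function(events, n) {
  stopifnot(n > 0, events >= 0, events <= n)
  pct1(events, n)
}
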