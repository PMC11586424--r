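#' Summarize best overall response
#'
#' Counts of CR/PR/SD/PD with the trial-report rates to one decimal:
#' objective response rate ORR = 100 (CR+PR)/n, disease control rate
#' DCR = 100 (CR+PR+SD)/n, and per-category percentages.
#'
#' @param x a clinical table (with `best_response`) or a character vector of
#'   best responses.
#' @return object of class `response_summary`: `counts`, `percents`, `n`,
#'   `orr_percent`, `dcr_percent`.
#' @export
summarize_response <- function(x) {
  br <- if (is.data.frame(x)) x$best_response else as.character(x)
  if (!length(br)) stop("empty input")
  bad <- setdiff(unique(br), c("CR", "PR", "SD", "PD"))
  if (length(bad)) stop("unknown best_response: ", paste(bad, collapse = ", "))
  counts <- table(factor(br, c("CR", "PR", "SD", "PD")))
  n <- length(br)
  structure(list(counts = counts,
                 percents = pct1(as.numeric(counts), n),
                 n = n,
                 orr_percent = pct1(counts[["CR"]] + counts[["PR"]], n),
                 dcr_percent = pct1(counts[["CR"]] + counts[["PR"]] +
                                      counts[["SD"]], n)),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("response_summary (n = %d): CR %d, PR %d, SD %d, PD %d\n",
              x$n, x$counts[["CR"]], x$counts[["PR"]], x$counts[["SD"]],
              x$counts[["PD"]]))
  cat(sprintf("  ORR %.1f%%  DCR %.1f%%\n", x$orr_percent, x$dcr_percent))
  invisible(x)
}

#' CA19-9 decline classification
#'
#' Percent decline from baseline to nadir, `100 (baseline - nadir) /
#' baseline`, tabulated against decline thresholds. Records without a
#' positive baseline or without a nadir are non-evaluable and reported
#' separately.
#'
#' @param records clinical table with `ca199_baseline` and `ca199_nadir`
#'   (U/mL).
#' @param thresholds decline thresholds in percent (default `c(20, 90)`).
#' @return list with `n_evaluable`, `n_excluded`, `decline_percent`
#'   (per evaluable record) and `table` (one row per threshold: count and
#'   percent of evaluable records at or above it).
#' @export
ca199_decline <- function(records, thresholds = c(20, 90)) {
  base <- records$ca199_baseline
  nadir <- records$ca199_nadir
  if (any(base < 0, na.rm = TRUE) || any(nadir < 0, na.rm = TRUE))
    stop("negative concentrations")
  evaluable <- !is.na(base) & !is.na(nadir) & base > 0
  decline <- 100 * (base[evaluable] - nadir[evaluable]) / base[evaluable]
  n_ev <- sum(evaluable)
  tab <- data.frame(
    threshold = thresholds,
    count = vapply(thresholds, function(th) sum(decline >= th), 0L),
    stringsAsFactors = FALSE)
  tab$percent <- pct1(tab$count, n_ev)
  list(n_evaluable = n_ev, n_excluded = sum(!evaluable),
       decline_percent = decline, table = tab)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood variance and log-log confidence
#' intervals, median survival (first time the estimate drops to <= 0.5;
#' "not reached" when it never does), and survival rates at landmark times
#' by step-function lookup.
#'
#' @param times non-negative event/censoring times.
#' @param events event indicators (TRUE = event).
#' @param landmarks optional landmark times (e.g. 12 for 1-year rate).
#' @param conf_level confidence level (default 0.95).
#' @return object of class `km_curve`: `time`, `n_risk`, `n_event`, `surv`,
#'   `std_err`, `lower`, `upper`, `median`, `median_ci`, `landmarks`
#'   (data.frame), and the underlying `survfit` object.
#' @export
km_estimate <- function(times, events, landmarks = NULL, conf_level = 0.95) {
  if (!length(times)) stop("empty input")
  stopifnot(all(times >= 0), length(times) == length(events))
  fit <- survival::survfit(
    survival::Surv(times, as.logical(events)) ~ 1,
    conf.type = "log-log", conf.int = conf_level)
  st <- summary(fit, censored = FALSE)
  # median convention: smallest observed time with S(t) <= 0.5
  med <- if (any(st$surv <= 0.5 + 1e-12)) min(st$time[st$surv <= 0.5 + 1e-12])
         else NA_real_
  tab <- summary(fit)$table
  med_ci <- unname(c(tab["0.95LCL"], tab["0.95UCL"]))
  lm_tab <- NULL
  if (!is.null(landmarks)) {
    sm <- summary(fit, times = landmarks, extend = TRUE)
    lm_tab <- data.frame(time = sm$time, surv = sm$surv,
                         lower = sm$lower, upper = sm$upper,
                         percent = pct1(sm$surv * 100, 100))
  }
  structure(list(time = st$time, n_risk = st$n.risk, n_event = st$n.event,
                 surv = st$surv, std_err = st$std.err,
                 lower = st$lower, upper = st$upper,
                 median = med, median_ci = med_ci, landmarks = lm_tab,
                 n = length(times), survfit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else format(x$median, digits = 4)
  cat("km_curve: n =", x$n, "| events =", sum(x$n_event),
      "| median =", med, "\n")
  if (!is.null(x$landmarks)) {
    for (i in seq_len(nrow(x$landmarks)))
      cat(sprintf("  S(%g) = %.3f (%.3f-%.3f)\n", x$landmarks$time[i],
                  x$landmarks$surv[i], x$landmarks$lower[i],
                  x$landmarks$upper[i]))
  }
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$survfit, xlab = "Time (months)", ylab = "Survival probability", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square (1 df) with two-sided p value.
#' With no events in either group the statistic is 0 and p = 1.
#'
#' @param times_a,events_a times and event indicators for group A.
#' @param times_b,events_b times and event indicators for group B.
#' @return list with `statistic`, `p`, `observed`, `expected`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) stop("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0)
    return(list(statistic = 0, p = 1,
                observed = c(0, 0), expected = c(0, 0)))
  time <- c(times_a, times_b)
  event <- as.logical(c(events_a, events_b))
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- unname(sd$chisq)
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Exact operating characteristics of a two-stage design
#'
#' Exact binomial computation for a Simon two-stage design (enroll `n1`,
#' stop for futility if at most `r1` successes; else enroll to `n` total and
#' declare success if the total exceeds `r`): probability of early
#' termination, probability of declaring success (rejecting the null), and
#' expected sample size, all at true success rate `p`.
#'
#' @param design a `simon_design` or list with `r1`, `n1`, `r`, `n`.
#' @param p true success probability (vectorized).
#' @return data.frame with `p`, `pet` (early-stop probability), `p_reject`,
#'   `expected_n`.
#' @export
evaluate_two_stage <- function(design, p) {
  r1 <- design$r1; n1 <- design$n1; r <- design$r; n <- design$n
  stopifnot(r1 >= 0, n1 >= 1, n > n1, r >= r1)
  out <- lapply(p, function(pp) {
    pet <- stats::pbinom(r1, n1, pp)
    x1 <- (r1 + 1):n1
    rej <- sum(stats::dbinom(x1, n1, pp) *
                 stats::pbinom(r - x1, n - n1, pp, lower.tail = FALSE))
    data.frame(p = pp, pet = pet, p_reject = rej,
               expected_n = n1 + (1 - pet) * (n - n1))
  })
  do.call(rbind, out)
}

#' Simon two-stage phase II design search
#'
#' Exhaustive search over (r1, n1, r, n) up to `n_max` using exact binomial
#' stage probabilities, returning the design that satisfies the attained
#' type-I error (<= alpha) and power (>= 1 - beta) constraints and is
#' optimal (minimum expected sample size under p0) or minimax (minimum
#' maximum sample size, expected size breaking ties).
#'
#' The alpha supplied here is the one-sided level of the design's null-rate
#' test; a quoted "two-sided 0.05" convention corresponds to one-sided
#' 0.025, so both `alpha = 0.05` and `alpha = 0.025` are of interest when a
#' protocol states "0.05 (both sides)".
#'
#' @param p0 unacceptable (null) success rate.
#' @param p1 target (alternative) success rate; `p0 < p1`.
#' @param alpha one-sided type-I error bound.
#' @param beta type-II error bound (power >= 1 - beta).
#' @param criterion "optimal" (minimize EN under p0) or "minimax"
#'   (minimize n).
#' @param n_max largest total sample size searched (default 80).
#' @return object of class `simon_design`: `r1`, `n1`, `r`, `n`, `pet0`,
#'   `en0`, `attained_alpha`, `attained_power`, plus the search parameters.
#' @export
simon_two_stage <- function(p0, p1, alpha = 0.05, beta = 0.2,
                            criterion = c("optimal", "minimax"),
                            n_max = 80) {
  criterion <- match.arg(criterion)
  stopifnot(p0 > 0, p1 > p0, p1 < 1, alpha > 0, beta > 0)
  best <- NULL
  for (n in 2:n_max) {
    if (!is.null(best) && criterion == "minimax" && n > best$n) break
    for (n1 in 1:(n - 1)) {
      # expected size is at least n1, so a larger n1 can never improve EN0
      if (!is.null(best) && criterion == "optimal" && n1 >= best$en0) break
      n2 <- n - n1
      d0 <- stats::dbinom(0:n1, n1, p0)
      d1 <- stats::dbinom(0:n1, n1, p1)
      # M0[r + 1, x1 + 1] = P(X2 > r - x1 | p0); rows r = 0..n-1
      M0 <- stats::pbinom(outer(0:(n - 1), 0:n1, "-"), n2, p0,
                          lower.tail = FALSE)
      for (r1 in 0:(n1 - 1)) {
        pet0 <- stats::pbinom(r1, n1, p0)
        # prune: even rejecting whenever stage 2 is reached cannot reach power
        if (stats::pbinom(r1, n1, p1, lower.tail = FALSE) < 1 - beta) break
        x1 <- (r1 + 1):n1
        rej0 <- as.vector(M0[, x1 + 1L, drop = FALSE] %*% d0[x1 + 1L])
        ok <- which(rej0 <= alpha & (0:(n - 1)) >= r1)
        if (!length(ok)) next
        r <- ok[1L] - 1L  # smallest feasible r maximizes power
        pow <- sum(d1[x1 + 1L] *
                     stats::pbinom(r - x1, n2, p1, lower.tail = FALSE))
        if (pow < 1 - beta) next
        en0 <- n1 + (1 - pet0) * n2
        cand <- list(r1 = r1, n1 = n1, r = r, n = n, pet0 = pet0, en0 = en0,
                     attained_alpha = rej0[ok[1L]], attained_power = pow)
        if (is.null(best)) { best <- cand; next }
        better <- if (criterion == "optimal") {
          cand$en0 < best$en0 - 1e-12
        } else {
          cand$n < best$n || (cand$n == best$n && cand$en0 < best$en0 - 1e-12)
        }
        if (better) best <- cand
      }
    }
  }
  if (is.null(best)) stop("no feasible design with n <= ", n_max)
  structure(c(best, list(p0 = p0, p1 = p1, alpha = alpha, beta = beta,
                         criterion = criterion, n_max = n_max)),
            class = "simon_design")
}

#' @export
print.simon_design <- function(x, ...) {
  cat(sprintf("simon_design (%s): stage 1 stop if <= %d/%d; reject H0 if > %d/%d\n",
              x$criterion, x$r1, x$n1, x$r, x$n))
  cat(sprintf("  p0 = %g, p1 = %g | attained alpha %.4f, power %.4f\n",
              x$p0, x$p1, x$attained_alpha, x$attained_power))
  cat(sprintf("  PET(p0) = %.4f, E[N|p0] = %.2f\n", x$pet0, x$en0))
  invisible(x)
}
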