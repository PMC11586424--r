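test_that("response summaries reproduce the trial-report arithmetic", {
  br <- rep(c("CR", "PR", "SD", "PD"), c(1, 23, 41, 7))
  rs <- summarize_response(br)
  expect_equal(rs$n, 72L)
  expect_equal(rs$orr_percent, 33.3)
  expect_equal(rs$dcr_percent, 90.3)
  expect_equal(unname(rs$percents), c(1.4, 31.9, 56.9, 9.7))

  expect_equal(summarize_response(rep("PD", 5))$orr_percent, 0.0)
  expect_equal(summarize_response(rep("PD", 5))$dcr_percent, 0.0)
  expect_error(summarize_response(character()), "empty")

  # random 200-record table matches an independent hand tally
  set.seed(40)
  br2 <- sample(c("CR", "PR", "SD", "PD"), 200, replace = TRUE)
  rs2 <- summarize_response(br2)
  hand <- c(sum(br2 == "CR"), sum(br2 == "PR"), sum(br2 == "SD"),
            sum(br2 == "PD"))
  expect_equal(as.numeric(rs2$counts), hand)
  expect_equal(rs2$orr_percent, round(100 * (hand[1] + hand[2]) / 200, 1))
})

test_that("CA19-9 decline classification follows the threshold rules", {
  rec <- data.frame(ca199_baseline = c(100, 200, 50, NA, 80),
                    ca199_nadir = c(75, 10, 60, 20, NA))
  out <- ca199_decline(rec)
  expect_equal(out$n_evaluable, 3L)
  expect_equal(out$n_excluded, 2L)
  expect_equal(out$decline_percent, c(25, 95, -20))
  expect_equal(out$table$count[out$table$threshold == 20], 2L)
  expect_equal(out$table$count[out$table$threshold == 90], 1L)
  expect_error(ca199_decline(data.frame(ca199_baseline = -1,
                                        ca199_nadir = 0)), "negative")
})

test_that("Kaplan-Meier estimates equal hand-computed product-limit tables", {
  # no censoring: empirical survivor function, median at S <= 0.5
  km <- km_estimate(1:10, rep(TRUE, 10))
  expect_equal(km$surv, seq(0.9, 0, by = -0.1))
  expect_equal(km$median, 5)

  # all censored: flat at 1, median not reached
  km2 <- km_estimate(c(3, 5, 8), rep(FALSE, 3))
  expect_true(is.na(km2$median))
  expect_true(all(km2$surv == 1) || length(km2$surv) == 0)

  # 8-subject mixed toy set, hand-computed product-limit values
  times <- c(1, 2, 3, 4, 4, 5, 6, 7)
  events <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  km3 <- km_estimate(times, events, landmarks = 4.5)
  expect_equal(km3$time, c(1, 3, 4, 5, 7))
  expect_equal(km3$surv,
               c(7 / 8, 7 / 8 * 5 / 6, 7 / 8 * 5 / 6 * 4 / 5,
                 7 / 8 * 5 / 6 * 4 / 5 * 2 / 3, 0),
               tolerance = 1e-12)
  expect_equal(km3$median, 5)
  expect_equal(km3$landmarks$surv, 7 / 8 * 5 / 6 * 4 / 5)
  # estimate is non-increasing and starts below 1 at the first event
  expect_true(all(diff(km3$surv) <= 0))
  expect_error(km_estimate(numeric(), logical()), "empty")
})

test_that("log-rank test matches the observed-minus-expected oracle", {
  lr0 <- logrank_test(1:5, rep(TRUE, 5), 1:5, rep(TRUE, 5))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)
  # no events anywhere
  lrn <- logrank_test(c(1, 2), c(FALSE, FALSE), c(3, 4), c(FALSE, FALSE))
  expect_equal(lrn$statistic, 0)
  expect_equal(lrn$p, 1)

  ta <- c(1, 3, 5, 7); ea <- c(TRUE, TRUE, FALSE, TRUE)
  tb <- c(2, 4, 6, 8); eb <- c(TRUE, TRUE, TRUE, FALSE)
  lr <- logrank_test(ta, ea, tb, eb)
  expect_equal(lr$statistic, brute_logrank(ta, ea, tb, eb),
               tolerance = 1e-10)
})

test_that("two-stage operating characteristics are exact", {
  d <- list(r1 = 5, n1 = 17, r = 18, n = 49)
  # certain early stop at p = 0; no early stop at p = 1
  expect_equal(evaluate_two_stage(d, 0)$pet, 1)
  expect_equal(evaluate_two_stage(d, 1)$pet, 0)
  # agreement with an independent double-sum oracle
  for (p in c(0.2, 0.35, 0.55)) {
    got <- evaluate_two_stage(d, p)
    want <- brute_two_stage(d$r1, d$n1, d$r, d$n, p)
    expect_equal(got$pet, want$pet, tolerance = 1e-12)
    expect_equal(got$p_reject, want$p_reject, tolerance = 1e-12)
    expect_equal(got$expected_n, want$expected_n, tolerance = 1e-12)
  }
  # rejection probability is monotone non-decreasing in p
  pr <- evaluate_two_stage(d, seq(0.05, 0.95, by = 0.05))$p_reject
  expect_true(all(diff(pr) >= -1e-12))
})

test_that("Simon designs satisfy their constraints; optimal vs minimax order", {
  opt <- simon_two_stage(0.35, 0.55, alpha = 0.05, beta = 0.2)
  mm <- simon_two_stage(0.35, 0.55, alpha = 0.05, beta = 0.2,
                        criterion = "minimax")
  for (d in list(opt, mm)) {
    expect_lte(d$attained_alpha, 0.05)
    expect_gte(d$attained_power, 0.8)
    expect_lt(d$n1, d$n)
    # constraints re-verified by the independent exact oracle
    chk0 <- brute_two_stage(d$r1, d$n1, d$r, d$n, 0.35)
    chk1 <- brute_two_stage(d$r1, d$n1, d$r, d$n, 0.55)
    expect_lte(chk0$p_reject, 0.05)
    expect_gte(chk1$p_reject, 0.8)
    expect_equal(d$en0, chk0$expected_n, tolerance = 1e-10)
  }
  expect_lte(opt$en0, mm$en0)
  expect_lte(mm$n, opt$n)
  expect_error(simon_two_stage(0.35, 0.55, alpha = 1e-6, beta = 0.01,
                               n_max = 20), "no feasible")
})
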