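make_cohort_features <- function(seed = 5, n_r = 6, n_n = 6,
                                 effect_size = 1) {
  spec <- cohort_spec(n_responders = n_r, n_nonresponders = n_n,
                      rois_per_patient = c(1, 2), bounds = c(400, 400),
                      background_density = 1500, effect_size = effect_size,
                      seed = seed)
  sim <- simulate_cohort(spec)
  g <- build_interaction_graph(sim$cell_map, 15)
  im <- interaction_matrix(g, sim$cell_map)
  assemble_features(sim$cell_map, im, clinical = sim$clinical)
}

test_that("the feature table has the 7 + 7 + 15 layout with exact values", {
  feats <- make_cohort_features()
  fcols <- grep("^(ratio|density|inter)_", names(feats), value = TRUE)
  expect_length(fcols, 29L)
  expect_length(grep("^ratio_", fcols), 7L)
  expect_length(grep("^density_", fcols), 7L)
  expect_length(grep("^inter_", fcols), 15L)
  expect_false(anyNA(feats))
  expect_false(any(grepl("Tumor", grep("^inter_", fcols, value = TRUE))))

  # hand check: 10 cells, 4 CTL, 1 mm^2 -> ratio 0.4, density 4.0
  p <- panel_pdac7()
  cells <- data.frame(cell_id = paste0("c", 1:10), roi_id = "R1",
                      patient_id = "P1", x = seq(10, 100, 10), y = 50,
                      cell_type = rep(c("CTL", "Tumor"), c(4, 6)))
  m <- cell_map(cells, p, roi_bounds = data.frame(
    roi_id = "R1", xmin = 0, xmax = 1000, ymin = 0, ymax = 1000))
  im <- interaction_matrix(build_interaction_graph(m, 15), m)
  ft <- assemble_features(m, im)
  expect_equal(ft$ratio_CTL, 0.4)
  expect_equal(ft$density_CTL, 4.0)

  # cell order within the table does not matter
  m_sh <- cell_map(cells[sample(10), ], p, roi_bounds = m$roi_bounds)
  im_sh <- interaction_matrix(build_interaction_graph(m_sh, 15), m_sh)
  ft_sh <- assemble_features(m_sh, im_sh)
  expect_equal(ft_sh, ft)
})

test_that("a perfectly separating feature yields AUC 1 on every split", {
  feats <- make_cohort_features()
  feats$ratio_CTL <- ifelse(feats$responder, 10, -10)  # plant a separator
  fit <- fit_response_model(feats, n_repeats = 5, seed = 2)
  expect_equal(fit$auc_values, rep(1, 5))
  expect_equal(length(fit$auc_values), fit$n_repeats)
  expect_true(all(fit$auc_values >= 0 & fit$auc_values <= 1))
})

test_that("standardization and fitting never see held-out rows", {
  feats <- make_cohort_features(seed = 9, n_r = 8, n_n = 8)
  fit <- fit_response_model(feats, n_repeats = 1, seed = 7)
  test_rows <- !fit$splits[, 1]
  shifted <- feats
  fcols <- grep("^(ratio|density|inter)_", names(feats), value = TRUE)
  shifted[test_rows, fcols] <- shifted[test_rows, fcols] + 100
  fit2 <- fit_response_model(shifted, n_repeats = 1, seed = 7)
  expect_identical(fit2$splits, fit$splits)
  expect_identical(fit2$coefficients, fit$coefficients)
  expect_identical(fit2$lambda, fit$lambda)
})

test_that("patient-grouped splitting never splits a patient", {
  feats <- make_cohort_features(seed = 3, n_r = 8, n_n = 8)
  fit <- fit_response_model(feats, n_repeats = 10, seed = 4)
  for (r in seq_len(10)) {
    tr_pat <- unique(feats$patient_id[fit$splits[, r]])
    te_pat <- unique(feats$patient_id[!fit$splits[, r]])
    expect_length(intersect(tr_pat, te_pat), 0L)
  }
})

test_that("Boruta confirms a label-identical feature at the earliest iteration", {
  set.seed(1)
  n <- 60
  y <- rep(c(TRUE, FALSE), n / 2)
  x <- cbind(oracle_copy = as.numeric(y) + rnorm(n, 0, 0.01),
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  bo <- boruta_select(x, y, alpha = 0.01, max_iter = 25, num_trees = 80,
                      seed = 3)
  expect_identical(as.character(bo$decision[["oracle_copy"]]), "confirmed")
  # 0.5^k < 0.01 first at k = 7: earliest possible confirmation
  expect_identical(unname(bo$decided_at[["oracle_copy"]]), 7L)
  # noise columns are never confirmed; most are actively rejected (a noise
  # column competing against few remaining shadows can stay tentative)
  expect_true(all(bo$decision[c("noise1", "noise2", "noise3")] != "confirmed"))
  expect_gte(sum(bo$decision[c("noise1", "noise2", "noise3")] == "rejected"), 2L)
  expect_error(boruta_select(x, rep(TRUE, n)), "degenerate")
})

test_that("survival-class models dichotomize at the cutoff and delegate", {
  feats <- make_cohort_features(seed = 13, n_r = 10, n_n = 10,
                                effect_size = 4)
  pats <- unique(feats$patient_id)
  times <- setNames(rep(c(20, 2), length.out = length(pats)), pats)
  events <- setNames(rep(TRUE, length(pats)), pats)
  expect_error(fit_survival_class_model(feats, times * 0 + 50, events,
                                        cutoff = 9), "empty")
  # censored before the cutoff are excluded with a message
  ev2 <- events; ev2[pats[2]] <- FALSE
  expect_message(
    fit <- fit_survival_class_model(feats, times, ev2, cutoff = 9,
                                    n_repeats = 2, seed = 5),
    "censored before cutoff")
  expect_identical(attr(fit, "n_excluded"), 1L)
  expect_s3_class(fit, "response_model")

  # median split balances uncensored classes to within one patient
  tvec <- setNames(seq_along(pats), pats)
  long <- tvec >= median(tvec)
  expect_lte(abs(sum(long) - sum(!long)), 1)
})
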