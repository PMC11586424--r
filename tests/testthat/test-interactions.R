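test_that("interaction graphs use a strict 15-um boundary, per ROI", {
  p <- panel_pdac7()
  mk <- function(x, y, types, rois = "R1") cell_map(data.frame(
    cell_id = paste0("c", seq_along(x)), roi_id = rois, patient_id = "P1",
    x = x, y = y, cell_type = types), p,
    roi_bounds = data.frame(roi_id = unique(rois), xmin = -10, xmax = 200,
                            ymin = -10, ymax = 200))
  expect_equal(nrow(build_interaction_graph(mk(c(0, 10), c(0, 0),
                                               c("CTL", "DC")))$edges), 1L)
  # exactly 15.0 um apart: excluded
  expect_equal(nrow(build_interaction_graph(mk(c(0, 15), c(0, 0),
                                               c("CTL", "DC")))$edges), 0L)
  # no cross-ROI edges even at distance 0
  m2 <- cell_map(data.frame(
    cell_id = c("a", "b"), roi_id = c("R1", "R2"),
    patient_id = c("P1", "P2"), x = 1, y = 1,
    cell_type = "CTL"), p)
  expect_equal(nrow(build_interaction_graph(m2)$edges), 0L)
})

test_that("interaction matrices count unordered pairs once, symmetrically", {
  p <- panel_pdac7()
  # A-A edge and A-B edge; second B isolated
  m <- cell_map(data.frame(
    cell_id = paste0("c", 1:4), roi_id = "R1", patient_id = "P1",
    x = c(0, 10, 0, 100), y = c(0, 0, 12, 100),
    cell_type = c("CTL", "CTL", "B", "B")), p)
  g <- build_interaction_graph(m, 15)
  im <- interaction_matrix(g, m, normalization = "raw")
  mat <- im$matrices[["R1"]]
  expect_equal(mat["CTL", "CTL"], 1)
  expect_equal(mat["CTL", "B"], 1)
  expect_equal(mat["B", "CTL"], 1)
  expect_equal(mat["B", "B"], 0)
  # total under the once-per-edge convention equals the edge count
  expect_equal(sum(mat[upper.tri(mat, diag = TRUE)]), nrow(g$edges))
  expect_true(isSymmetric(mat))

  # per-cell min-count normalization, 0/0 -> 0
  imc <- interaction_matrix(g, m, normalization = "per_cell")
  expect_equal(imc$matrices[["R1"]]["CTL", "B"], 1 / 2)  # min(2 CTL, 2 B)
  expect_equal(imc$matrices[["R1"]]["Th", "DC"], 0)
  # per-area normalization divides by the ROI area in mm^2
  ima <- interaction_matrix(g, m, normalization = "per_area")
  area <- unname(roi_areas(m)["R1"])
  expect_equal(ima$matrices[["R1"]]["CTL", "B"], 1 / area)

  # permuting type labels permutes the matrix identically
  swap <- c(CTL = "B", B = "CTL")
  m_sw <- m; m_sw$cells$cell_type <- unname(swap[m$cells$cell_type])
  mat_sw <- interaction_matrix(build_interaction_graph(m_sw, 15), m_sw,
                               normalization = "raw")$matrices[["R1"]]
  expect_equal(mat_sw["B", "B"], mat["CTL", "CTL"])
  expect_equal(mat_sw["B", "CTL"], mat["CTL", "B"])
})

test_that("spatial-index graph equals the brute-force oracle on a 3000-cell map", {
  p <- panel_pdac7()
  set.seed(17)
  m <- make_typed_map(sample(p$types, 3000, replace = TRUE), seed = 17)
  g <- build_interaction_graph(m, 15)
  oracle <- brute_pairs(m$cells$x, m$cells$y, 15, strict = TRUE)
  got <- cbind(i = match(g$edges$i, m$cells$cell_id),
               j = match(g$edges$j, m$cells$cell_id))
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(oracle))
})

test_that("comparison of interaction features delegates with BH adjustment", {
  spec <- cohort_spec(n_responders = 4, n_nonresponders = 4,
                      rois_per_patient = c(1, 1), bounds = c(400, 400),
                      background_density = 1500, effect_size = 1, seed = 3)
  sim <- simulate_cohort(spec)
  g <- build_interaction_graph(sim$cell_map, 15)
  im <- interaction_matrix(g, sim$cell_map)
  grp <- setNames(ifelse(sim$clinical$responder, "R", "NR"),
                  sim$clinical$patient_id)
  rg <- grp[sub("_R\\d+$", "", names(im$matrices))]
  res <- compare_interactions(im, unname(rg),
                              pairs = list(c("DC", "CTL"), c("Th", "DC")))
  expect_equal(nrow(res), 2L)
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
  expect_error(compare_interactions(im, unname(rg),
                                    pairs = list(c("DC", "Treg"))), "absent")
})

test_that("label-shuffle null flags segregation and is reproducible", {
  p <- panel_pdac7()
  # two fully segregated type blocks: cross-type z must be strongly negative
  set.seed(23)
  cells <- data.frame(
    cell_id = paste0("c", 1:400), roi_id = "R1", patient_id = "P1",
    x = c(runif(200, 0, 150), runif(200, 450, 600)),
    y = runif(400, 0, 150),
    cell_type = rep(c("CTL", "Tumor"), each = 200))
  m <- cell_map(cells, p, roi_bounds = data.frame(
    roi_id = "R1", xmin = 0, xmax = 600, ymin = 0, ymax = 150))
  pn <- interaction_permutation_null(m, threshold = 15, n_perm = 100,
                                     seed = 5)
  expect_lt(pn$z["CTL", "Tumor"], -3)
  expect_gt(pn$z["CTL", "CTL"], 0)
  pn2 <- interaction_permutation_null(m, threshold = 15, n_perm = 100,
                                      seed = 5)
  expect_identical(pn$null_mean, pn2$null_mean)
  expect_error(interaction_permutation_null(m, n_perm = 10), "n_perm")
})
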