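test_that("z-scoring follows the population-SD convention", {
  expect_equal(unname(zscore_markers(cbind(m = c(1, 3)))[, 1]), c(-1, 1))
  z <- zscore_markers(cbind(a = c(5, 5, 5), b = c(1, 2, 3)))
  expect_equal(unname(z[, "a"]), c(0, 0, 0))  # degenerate SD rule
  set.seed(8)
  x <- matrix(rexp(700), 100, 7)
  z <- zscore_markers(x)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(z^2)) - 1) < 1e-9))
  expect_error(zscore_markers(matrix(numeric(), 0, 3)), "empty")
})

test_that("noise-free signatures gate perfectly; ties follow panel priority", {
  p <- panel_pdac7()
  m <- make_typed_map(rep(p$types, each = 30), seed = 4)
  mi <- simulate_marker_intensities(m, noise_sd = 0, seed = 1)
  z <- zscore_markers(mi$cells[, p$markers])
  g <- assign_lineage(z, p, truth = m$cells$cell_type)
  expect_equal(g$accuracy, 1.0)

  # exact CD4/CD8 tie (identical marker columns): priority puts Th first
  raw <- rbind(c(2, 2, 0, 0, 0, 0, 0),
               c(0, 0, 0, 0, 0, 0, 2),
               c(0, 0, 2, 0, 0, 0, 0),
               c(0, 0, 0, 0, 0, 0, 0))
  colnames(raw) <- p$markers
  zt <- zscore_markers(raw)
  expect_identical(unname(zt[, "CD4"]), unname(zt[, "CD8"]))
  g2 <- assign_lineage(zt, p)
  expect_identical(g2$cell_type[1], "Th")

  # permutation equivariance
  perm <- sample(nrow(z))
  g3 <- assign_lineage(z[perm, ], p)
  expect_identical(g3$cell_type, g$cell_type[perm])
})

test_that("noisy synthetic intensities are recovered with accuracy >= 0.9", {
  p <- panel_pdac7()
  set.seed(5)
  m <- make_typed_map(sample(rep(p$types, length.out = 5000)), seed = 5)
  mi <- simulate_marker_intensities(m, noise_sd = 0.5, seed = 6)
  z <- zscore_markers(mi$cells[, p$markers])
  g <- assign_lineage(z, p, truth = m$cells$cell_type)
  expect_gte(g$accuracy, 0.9)
})

test_that("Ki67 proliferation flag is orthogonal to lineage", {
  p <- panel_tme16()
  # representative mixture: every marker needs a positive population for
  # cohort-relative z-scores to be meaningful
  types <- setdiff(p$types, "Other")
  m <- make_typed_map(rep(types, each = 40), seed = 3, panel = p)
  mi <- simulate_marker_intensities(m, panel = p, noise_sd = 0.1, seed = 2)
  # mark alternating cells as proliferating in intensity space
  mi$cells$Ki67 <- rep(c(0, 3), length.out = nrow(mi$cells))
  z <- zscore_markers(mi$cells[, p$markers])
  g <- assign_lineage(z, p)
  expect_identical(g$proliferating, unname(z[, "Ki67"] > 1))
  expect_gt(mean(g$cell_type == m$cells$cell_type), 0.9)
  # the flag is independent of the assigned lineage
  expect_gt(min(table(g$proliferating, g$cell_type %in% types)), 0)
})

test_that("hotspot windows maximize target counts, greedily and disjointly", {
  p <- panel_pdac7()
  # dense CTL cluster in the lower-left corner of a tumor field
  set.seed(11)
  n_bg <- 400
  cells <- data.frame(
    cell_id = paste0("c", 1:(n_bg + 80)), roi_id = "S1", patient_id = "P1",
    x = c(runif(n_bg, 0, 1000), runif(80, 20, 120)),
    y = c(runif(n_bg, 0, 1000), runif(80, 20, 120)),
    cell_type = c(rep("Tumor", n_bg), rep("CTL", 80)))
  m <- cell_map(cells, p, roi_bounds = data.frame(
    roi_id = "S1", xmin = 0, xmax = 1000, ymin = 0, ymax = 1000))
  hs <- select_hotspot_rois(m, "CTL", roi_size = c(200, 200), k = 2)
  expect_gte(hs$n_target[1], 80)  # the cluster plus any bystander CTLs

  # exhaustive 10-um-grid oracle for the best window
  step <- 10
  ctl <- m$cells[m$cells$cell_type == "CTL", ]
  best <- 0
  for (x0 in seq(0, 800, by = step)) for (y0 in seq(0, 800, by = step)) {
    cnt <- sum(ctl$x >= x0 & ctl$x < x0 + 200 &
                 ctl$y >= y0 & ctl$y < y0 + 200)
    if (cnt > best) best <- cnt
  }
  expect_identical(hs$n_target[1], as.integer(best))

  # windows are pairwise non-overlapping
  if (nrow(hs) == 2) {
    sep <- abs(hs$x0[1] - hs$x0[2]) >= 200 || abs(hs$y0[1] - hs$y0[2]) >= 200
    expect_true(sep)
  }

  # uniform target: two windows with similar counts
  set.seed(12)
  mu <- make_typed_map(rep("CTL", 2000), seed = 12)
  hu <- select_hotspot_rois(mu, "CTL", roi_size = c(300, 300), k = 2)
  expect_equal(nrow(hu), 2L)
  expect_lt(abs(hu$n_target[1] - hu$n_target[2]),
            6 * sqrt(mean(hu$n_target)))

  # degenerate inputs
  expect_warning(out <- select_hotspot_rois(make_typed_map(rep("Tumor", 50)),
                                            "CTL", c(100, 100)),
                 "no cells")
  expect_equal(nrow(out), 0L)
  expect_error(select_hotspot_rois(mu, "CTL", roi_size = c(2000, 100)),
               "larger than map bounds")

  # cropping gives window-local coordinates within bounds
  cropped <- crop_hotspots(m, hs)
  expect_true(all(cropped$cells$x >= 0 & cropped$cells$x <= 200))
  expect_equal(sum(cropped$cells$cell_type == "CTL" &
                     cropped$cells$roi_id == hs$roi_id[1]), hs$n_target[1])
})
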