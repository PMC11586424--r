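test_that("neighborhood profiles match hand geometry and brute force", {
  p <- panel_pdac7()
  # three collinear cells 10 um apart: middle sees both ends, ends see middle
  m <- cell_map(data.frame(
    cell_id = c("a", "b", "c"), roi_id = "R1", patient_id = "P1",
    x = c(0, 10, 20), y = 0, cell_type = c("CTL", "B", "CTL")), p)
  pr <- neighborhood_profile(m, radius = 15)
  expect_equal(pr$neighbor_count, c(1L, 2L, 1L))
  expect_equal(unname(pr$profiles[1, "B"]), 1)
  expect_equal(unname(pr$profiles[2, "CTL"]), 1)
  expect_equal(unname(pr$profiles[3, "B"]), 1)

  # isolated cell: zero vector
  m2 <- cell_map(data.frame(
    cell_id = c("a", "b"), roi_id = "R1", patient_id = "P1",
    x = c(0, 500), y = 0, cell_type = c("CTL", "B")), p,
    roi_bounds = data.frame(roi_id = "R1", xmin = 0, xmax = 500,
                            ymin = -1, ymax = 1))
  pr2 <- neighborhood_profile(m2, radius = 50)
  expect_equal(pr2$neighbor_count, c(0L, 0L))
  expect_true(all(pr2$profiles == 0))

  # 2000-cell random map: exact agreement with the O(n^2) oracle
  set.seed(31)
  m3 <- make_typed_map(sample(p$types, 2000, replace = TRUE), seed = 31,
                       width = 800, height = 800)
  pr3 <- neighborhood_profile(m3, radius = 50)
  oracle <- brute_profiles(m3$cells, 50, colnames(pr3$profiles))
  expect_equal(pr3$neighbor_count, oracle$neighbor_count)
  expect_equal(unname(pr3$profiles), unname(oracle$profiles))

  # monotonicity of neighbor count in the radius
  pr_small <- neighborhood_profile(m3, radius = 25)
  expect_true(all(pr_small$neighbor_count <= pr3$neighbor_count))

  expect_error(neighborhood_profile(m3, radius = 0), "radius")
})

test_that("K-means niches recover planted archetypes and are deterministic", {
  p <- panel_pdac7()
  # four well-separated blobs, two per pure archetype, no background
  set.seed(7)
  centers <- data.frame(x = c(150, 650, 150, 650), y = c(150, 150, 650, 650),
                        type = c("CTL", "PDL1neg_M", "PDL1neg_M", "CTL"))
  cells <- do.call(rbind, lapply(1:4, function(b) data.frame(
    cell_id = paste0("b", b, "_", 1:80), roi_id = "R1", patient_id = "P1",
    x = rnorm(80, centers$x[b], 15), y = rnorm(80, centers$y[b], 15),
    cell_type = centers$type[b])))
  m <- cell_map(cells, p, roi_bounds = data.frame(
    roi_id = "R1", xmin = -100, xmax = 900, ymin = -100, ymax = 900))
  pr <- neighborhood_profile(m, radius = 40)
  nm <- fit_niches(pr, K = 2, seed = 5)
  expect_equal(adj_rand_index(nm$assignments, cells$cell_type), 1.0)

  # refit with the same seed is identical; K = 1 centroid is the mean profile
  nm2 <- fit_niches(pr, K = 2, seed = 5)
  expect_identical(nm$assignments, nm2$assignments)
  nm1 <- fit_niches(pr, K = 1, seed = 5)
  expect_equal(unname(nm1$centroids[1, ]), unname(colMeans(pr$profiles)))

  # centroid rows equal the means of their members' profiles
  for (id in rownames(nm$centroids)) {
    sel <- nm$assignments == id
    expect_equal(unname(nm$centroids[id, ]),
                 unname(colMeans(pr$profiles[sel, , drop = FALSE])))
  }
  expect_error(fit_niches(pr, K = 10000), "exceeds")
})

test_that("niche ratio tables are proportions with unit rows", {
  p <- panel_pdac7()
  # hand map: three niches of 2/3/5 cells via planted compositions
  cells <- data.frame(
    cell_id = paste0("c", 1:10), roi_id = "R1", patient_id = "P1",
    x = 1:10, y = 0,
    cell_type = rep(c("CTL", "B", "Tumor"), c(2, 3, 5)))
  m <- cell_map(cells, p)
  pr <- neighborhood_profile(m, radius = 2000)
  fake <- structure(list(
    K = 3, centroids = matrix(0, 3, ncol(pr$profiles),
                              dimnames = list(c("IN-0", "IN-1", "IN-2"),
                                              colnames(pr$profiles))),
    assignments = rep(c("IN-0", "IN-1", "IN-2"), c(2, 3, 5)),
    roi_id = pr$roi_id, patient_id = pr$patient_id, radius = 2000),
    class = "niche_model")
  rt <- niche_ratios(fake, unit = "roi")
  expect_equal(unname(unlist(rt[1, c("IN-0", "IN-1", "IN-2")])),
               c(0.2, 0.3, 0.5))
  expect_equal(sum(rt[1, sapply(rt, is.numeric)]), 1)

  # all cells in one niche: one-hot row
  fake$assignments <- rep("IN-0", 10)
  rt2 <- niche_ratios(fake, unit = "patient")
  expect_equal(unname(rt2[["IN-0"]]), 1)
})

test_that("group comparison matches closed-form oracles", {
  # identical groups: zero difference, p = 1
  x <- matrix(rep(c(1, 2, 3, 1, 2, 3), 2), ncol = 2)
  res <- compare_group_ratios(x, rep(c("a", "b"), each = 3))
  expect_equal(res$mean_diff, c(0, 0))
  expect_equal(res$p, c(1, 1))

  # Welch t on {1,2,3} vs {4,5,6}: hand-computed t = -3.674, p ~ 0.021
  res2 <- compare_group_ratios(c(1, 2, 3, 4, 5, 6),
                               rep(c("a", "b"), each = 3), method = "welch",
                               ref = "a")
  expect_equal(res2$statistic, -3.6742346, tolerance = 1e-6)
  expect_equal(res2$p, 0.02131164, tolerance = 1e-5)
  expect_equal(res2$direction, -1)

  # BH adjustment is applied across variables
  set.seed(2)
  xm <- matrix(rnorm(80), 8, 10)
  r3 <- compare_group_ratios(xm, rep(c("a", "b"), each = 4))
  expect_equal(r3$p_adj, p.adjust(r3$p, "BH"))
  expect_error(compare_group_ratios(xm[1:3, ], c("a", "a", "b")), "at least 2")
})

test_that("unit clustering separates planted groups and ignores row order", {
  rt <- data.frame(unit = paste0("u", 1:8),
                   `IN-0` = rep(c(0.9, 0.1), each = 4),
                   `IN-1` = rep(c(0.1, 0.9), each = 4),
                   check.names = FALSE)
  cl <- cluster_units_by_niches(rt, k = 2)
  expect_equal(adj_rand_index(cl$clusters, rep(1:2, each = 4)), 1.0)
  perm <- sample(nrow(rt))
  cl2 <- cluster_units_by_niches(rt[perm, ], k = 2)
  expect_equal(adj_rand_index(cl2$clusters[cl$unit], cl$clusters), 1.0)
  expect_error(cluster_units_by_niches(rt[1, , drop = FALSE]), "nrow")
})

test_that("radius sweep and elbow utilities behave monotonically", {
  p <- panel_pdac7()
  m <- make_typed_map(sample(p$types, 600, replace = TRUE), seed = 44,
                      width = 500, height = 500)
  sw <- neighborhood_radius_sweep(m, c(20, 40, 80))
  expect_true(all(diff(sw$mean_neighbors) > 0))
  expect_true(all(diff(sw$frac_isolated) <= 0))
  el <- niche_elbow(neighborhood_profile(m, 50), Ks = c(2, 4, 6), seed = 2)
  expect_true(all(diff(el$inertia) < 0))  # objective decreases in K
})
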