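test_that("generate_plot lays out the planting grid and is deterministic", {
  sp <- plot_preset("b")$species
  t1 <- generate_plot(sp, 5, 5, plot_size = 30, thinning = 0, seed = 3)
  expect_equal(nrow(t1$trees), 36) # floor(30/5)^2
  expect_identical(t1, generate_plot(sp, 5, 5, plot_size = 30,
                                     thinning = 0, seed = 3))
  t2 <- generate_plot(sp, 5, 5, plot_size = 30, thinning = 0.25, seed = 3)
  expect_equal(nrow(t2$trees), 36 - round(0.25 * 36))
  expect_error(generate_plot(sp, -1, 5), "positive")
  # invariants
  expect_true(all(t1$trees$x >= 0 & t1$trees$x <= 30))
  expect_true(all(t1$trees$H > 1.3), all(t1$trees$D > 0))
  lean <- sqrt(t1$trees$lean_dx^2 + t1$trees$lean_dy^2)
  expect_true(all(lean < t1$trees$crown_radius))
})

test_that("plot-b-like attribute draws match their targets within 3 SE", {
  sp <- plot_preset("b")$species # mean D 31.57 (3.95), mean H 27.30 (1.71)
  tr <- generate_plot(sp, 3, 3, plot_size = 30, thinning = 0,
                      seed = 5)$trees # 100 trees
  expect_equal(nrow(tr), 100)
  expect_lt(abs(mean(tr$D) - 31.57), 3 * 3.95 / sqrt(100))
  expect_lt(abs(mean(tr$H) - 27.30), 3 * 1.71 / sqrt(100))
})

test_that("ULS sampler meets density, hits apexes exactly, varies by seed", {
  truth <- small_truth()
  scan <- sample_uls_cloud(truth, density = 30, ground_density = 5,
                           noise_sigma = 0, seed = 2)
  area <- truth$plot_size^2
  expect_gt(nrow(scan$cloud), 0.8 * 30 * area)
  expect_lt(nrow(scan$cloud), 1.2 * 30 * area)
  # noiseless: per-tree max z - ground elevation equals H exactly
  for (i in c(1, 5, 9)) {
    tr <- truth$trees[i, ]
    pts <- scan$cloud[scan$cloud$tree_id == tr$id, ]
    expect_equal(max(pts$z) - ground_elevation(truth, tr$x, tr$y), tr$H,
                 tolerance = 1e-12)
  }
  scan2 <- sample_uls_cloud(truth, density = 30, ground_density = 5,
                            noise_sigma = 0, seed = 3)
  expect_false(isTRUE(all.equal(scan$cloud$x, scan2$cloud$x)))
})

test_that("BLS sampler respects the height cap and the configured taper", {
  truth <- small_truth()
  tr0 <- rigid2d(0, 0, 0)
  scan <- sample_bls_cloud(truth, pts_per_stem_slice = 60, noise_sigma = 0,
                           transform = tr0, height_cap = 9,
                           ground_density = 0, clutter_density = 0,
                           seed = 4)
  stems <- scan$cloud[scan$cloud$tree_id > 0, ]
  gz <- ground_elevation(truth, stems$x, stems$y)
  expect_lt(max(stems$z - gz), 9 + 1e-9)
  # noiseless slice radius equals half the true diameter (anchored taper)
  tr <- truth$trees[1, ]
  gz1 <- ground_elevation(truth, tr$x, tr$y)
  sl <- stems[stems$tree_id == 1 & stems$z - gz1 >= 1.25 &
                stems$z - gz1 < 1.35, ]
  rr <- sqrt((sl$x - tr$x)^2 + (sl$y - tr$y)^2)
  d_true <- true_stem_diameter(truth, 1, 1.3)
  expect_lt(max(abs(200 * rr - d_true)), 0.5) # taper variation over slice
})

test_that("BLS rigid offset moves stem centroids by exactly the transform", {
  truth <- small_truth()
  tr0 <- rigid2d(0, 5, -3) # pure translation
  scan <- sample_bls_cloud(truth, pts_per_stem_slice = 60,
                           noise_sigma = 0, transform = tr0,
                           ground_density = 0, clutter_density = 0,
                           seed = 4)
  stems <- scan$cloud[scan$cloud$tree_id > 0, ]
  cen_bls <- c(mean(stems$x), mean(stems$y))
  # stem columns are vertical, so their centroid sits on the stem centre
  per_tree <- aggregate(cbind(x, y) ~ tree_id, stems, mean)
  cen_true <- colMeans(truth$trees[per_tree$tree_id, c("x", "y")])
  # stratified azimuths centre each slice to ~1e-5 m
  expect_equal(colMeans(per_tree[, c("x", "y")]) - cen_true,
               c(x = 5, y = -3), tolerance = 1e-3)
})

test_that("simulated scans are byte-identical under a repeated seed", {
  truth <- small_truth()
  a <- sample_bls_cloud(truth, pts_per_stem_slice = 40, seed = 8)
  b <- sample_bls_cloud(truth, pts_per_stem_slice = 40, seed = 8)
  expect_identical(a$cloud, b$cloud)
})

test_that("every simulated point carries its source label", {
  truth <- small_truth()
  u <- sample_uls_cloud(truth, density = 20, ground_density = 4, seed = 1)
  b <- sample_bls_cloud(truth, pts_per_stem_slice = 40, seed = 1)
  expect_true(all(c("tree_id", "class") %in% names(u$cloud)))
  expect_true(all(c("tree_id", "class") %in% names(b$cloud)))
  expect_setequal(unique(u$cloud$tree_id), c(0, truth$trees$id))
})
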