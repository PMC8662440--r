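test_that("slicing uses a half-open height band", {
  cl <- as_point_cloud(data.frame(x = 1:3, y = 1:3, z = 0,
                                  zn = c(1.24, 1.25, 1.35)))
  sl <- slice_cloud(cl, center = 1.3, width = 0.10)
  expect_equal(sl$zn, 1.25)
  expect_equal(nrow(slice_cloud(cl[0, ], 1.3, 0.1)), 0)
})

test_that("DBSCAN separates dense rings and ignores sparse noise", {
  r1 <- ring_points(0, 0, 0.15, n = 60, seed = 1)
  r2 <- ring_points(4, 0, 0.15, n = 60, seed = 2)
  sl <- as_point_cloud(data.frame(x = c(r1$x, r2$x), y = c(r1$y, r2$y),
                                  z = 0, zn = 1.3))
  det <- detect_trunks(sl, eps = 0.2, minpts = 10)
  expect_equal(nrow(det$trunks), 2)
  expect_equal(sort(det$trunks$x), c(0, 4), tolerance = 0.02)
  # uniform sparse noise only: no clusters
  ns <- with_seed(3, as_point_cloud(data.frame(
    x = runif(100, 0, 30), y = runif(100, 0, 30), z = 0, zn = 1.3)))
  expect_equal(nrow(detect_trunks(ns, eps = 0.2, minpts = 10)$trunks), 0)
})

test_that("DBSCAN clustering is stable under point shuffling", {
  r1 <- ring_points(0, 0, 0.15, n = 50, seed = 4)
  r2 <- ring_points(3, 1, 0.12, n = 50, seed = 5)
  sl <- as_point_cloud(data.frame(x = c(r1$x, r2$x), y = c(r1$y, r2$y),
                                  z = 0, zn = 1.3))
  d1 <- detect_trunks(sl, 0.2, 10)
  p <- with_seed(6, sample.int(nrow(sl)))
  d2 <- detect_trunks(sl[p, ], 0.2, 10)
  o1 <- d1$trunks[order(d1$trunks$x), c("x", "y", "D", "n_points")]
  o2 <- d2$trunks[order(d2$trunks$x), c("x", "y", "D", "n_points")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("gravity-centre circle fit is exact on symmetric point sets", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  f <- fit_circle_diameter(data.frame(x = 0.15 * cos(th),
                                      y = 0.15 * sin(th)))
  expect_equal(f$D, 30.0)
  expect_equal(f$center, c(0, 0))
  f4 <- fit_circle_diameter(data.frame(x = c(0.1, -0.1, 0, 0),
                                       y = c(0, 0, 0.1, -0.1)))
  expect_equal(f4$center, c(0, 0))
  expect_equal(f4$D, 20.0)
  expect_error(fit_circle_diameter(data.frame(x = 1, y = 1)), "single")
})

test_that("circle fit is translation-equivariant and noise-tolerant", {
  pts <- ring_points(0, 0, 0.15, n = 80, seed = 7)
  a <- fit_circle_diameter(pts)
  b <- fit_circle_diameter(data.frame(x = pts$x + 12, y = pts$y - 7))
  expect_equal(b$center, a$center + c(12, -7))
  expect_equal(b$D, a$D)
  # Monte-Carlo: radial noise sigma = 1 cm, n = 200
  with_seed(8, {
    th <- runif(200, 0, 2 * pi)
    r <- 0.15 + rnorm(200, 0, 0.01)
    f <- fit_circle_diameter(data.frame(x = r * cos(th), y = r * sin(th)))
    expect_gt(f$D, 29); expect_lt(f$D, 31)
  })
})

test_that("stem profiles track the generating taper up the trunk", {
  truth <- small_truth()
  scan <- sample_bls_cloud(truth, pts_per_stem_slice = 80, noise_sigma = 0,
                           transform = rigid2d(), ground_density = 0,
                           clutter_density = 0, seed = 10)
  cl <- scan$cloud
  cl$zn <- cl$z - ground_elevation(truth, cl$x, cl$y)
  tk <- detect_trunks(slice_cloud(cl), eps = 0.2, minpts = 15)
  expect_equal(nrow(tk$trunks), nrow(truth$trees))
  tr <- tk$trunks[1, ]
  tid <- which.min((tr$x - truth$trees$x)^2 + (tr$y - truth$trees$y)^2)
  prof <- stem_profile(cl, tr)
  expect_true(all(prof$h %in% seq(1.3, 8.3, by = 1)))
  d_true <- vapply(prof$h, function(h) true_stem_diameter(truth, tid, h),
                   numeric(1))
  expect_lt(max(abs(prof$d - d_true)), 0.5)
  # monotone taper means a monotone noiseless profile
  expect_true(all(diff(prof$d) <= 0))
})

test_that("profiles respect the height ladder and the sensor cap", {
  truth <- small_truth()
  scan <- sample_bls_cloud(truth, pts_per_stem_slice = 60, noise_sigma = 0,
                           transform = rigid2d(), height_cap = 9,
                           ground_density = 0, clutter_density = 0,
                           seed = 11)
  cl <- scan$cloud
  cl$zn <- cl$z - ground_elevation(truth, cl$x, cl$y)
  tk <- detect_trunks(slice_cloud(cl), 0.2, 15)
  p1 <- stem_profile(cl, tk$trunks[1, ], heights = 1.3)
  expect_lte(nrow(p1), 1)
  pall <- stem_profile(cl, tk$trunks[1, ],
                       heights = seq(1.3, 12.3, by = 1))
  expect_lte(max(pall$h), 8.3) # nothing measurable above the cap
})
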