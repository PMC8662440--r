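test_that("k-NN outlier removal drops gross outliers and keeps structure", {
  g <- expand.grid(x = 1:12, y = 1:12)
  cl <- point_cloud(c(g$x, 6), c(g$y, 6), c(rep(0, 144), 100))
  out <- remove_outliers(cl, k = 8, n_sigma = 3)
  expect_equal(nrow(out), 144)
  expect_lt(max(out$z), 1)
  # homogeneous cloud: any removals are confined to the boundary (corner
  # points of a finite grid legitimately have larger neighbour distances),
  # and a slightly wider band keeps everything
  grid_only <- point_cloud(g$x, g$y, rep(0, 144))
  kept <- remove_outliers(grid_only, 8, 3)
  dropped <- setdiff(seq_len(144), as.integer(rownames(kept)))
  on_edge <- g$x %in% c(1, 12) | g$y %in% c(1, 12)
  expect_true(all(on_edge[dropped]))
  expect_equal(nrow(remove_outliers(grid_only, 8, 5)), 144)
  expect_warning(remove_outliers(point_cloud(1:3, 1:3, 1:3), k = 8),
                 "unchanged")
})

test_that("injected high-altitude noise is almost entirely removed", {
  truth <- small_truth()
  scan <- sample_uls_cloud(truth, density = 25, ground_density = 5,
                           noise_sigma = 0.02, seed = 6)
  n <- nrow(scan$cloud)
  n_noise <- round(0.01 * n)
  noise <- with_seed(31, data.frame(
    x = runif(n_noise, 0, 18), y = runif(n_noise, 0, 18),
    z = runif(n_noise, 50, 100), tree_id = -1L, class = "noise"))
  cl <- as_point_cloud(rbind(as.data.frame(scan$cloud), noise))
  out <- remove_outliers(cl)
  removed_noise <- n_noise - sum(out$tree_id == -1)
  expect_gte(removed_noise / n_noise, 0.99)
})

test_that("TIN densification recovers a plane and rejects stems", {
  set.seed(9)
  gx <- runif(8000, 0, 30); gy <- runif(8000, 0, 30)
  stems <- do.call(rbind, lapply(0:8, function(i) {
    sx <- (i %% 3) * 10 + 5; sy <- (i %/% 3) * 10 + 5
    th <- runif(500, 0, 2 * pi)
    data.frame(x = sx + 0.15 * cos(th), y = sy + 0.15 * sin(th),
               z = 2 + 0.001 * sx + runif(500, 0.3, 20),
               class = "vegetation")
  }))
  cl <- rbind(data.frame(x = gx, y = gy, z = 2 + 0.001 * gx,
                         class = "ground"), stems)
  truth_class <- cl$class
  cl <- point_cloud(cl$x, cl$y, cl$z)
  out <- classify_ground(cl)
  expect_false(attr(out, "fallback"))
  expect_gte(mean(out$class[truth_class == "ground"] == "ground"), 0.99)
  # conservation: every point labelled exactly once
  expect_true(all(out$class %in% c("ground", "vegetation")))
  expect_equal(nrow(out), nrow(cl))
})

test_that("a pure ground plane is labelled 100% ground", {
  set.seed(2)
  cl <- point_cloud(runif(3000, 0, 20), runif(3000, 0, 20), 5)
  out <- classify_ground(cl)
  expect_true(all(out$class == "ground"))
})

test_that("no crown point of an isolated tree is labelled ground", {
  set.seed(3)
  ground <- data.frame(x = runif(4000, 0, 20), y = runif(4000, 0, 20))
  ground$z <- 1 + 0.0004 * ground$x
  crown <- cone_points(10, 10, h_apex = 26, r_base = 2, depth = 10, n = 2000,
                       seed = 4)
  cl <- point_cloud(c(ground$x, crown$x), c(ground$y, crown$y),
                    c(ground$z, 1 + 0.0004 * crown$x + crown$zn))
  is_crown <- c(rep(FALSE, 4000), rep(TRUE, 2000))
  out <- classify_ground(cl)
  expect_equal(sum(out$class[is_crown] == "ground"), 0)
})

test_that("degenerate collinear seeds fall back to a plane fit, flagged", {
  cl <- point_cloud(seq(0, 40, length.out = 400), 0.5,
                    rep(2, 400)) # one seed row -> collinear seeds
  out <- classify_ground(cl, seed_cell = 5)
  expect_true(attr(out, "fallback"))
  expect_true(all(out$class == "ground"))
})

test_that("DEM reproduces a plane and IDW fills empty cells", {
  set.seed(4)
  g <- point_cloud(runif(9000, 0, 30), runif(9000, 0, 30), 0)
  g$z <- 2 + 0.001 * g$x
  g$class <- "ground"
  dem <- build_dem(g, cell = 1)
  cxs <- dem$origin[1] + (seq_len(nrow(dem$z)) - 0.5) * dem$cell
  tru <- matrix(2 + 0.001 * cxs, nrow(dem$z), ncol(dem$z))
  expect_lt(max(abs(dem$z - tru)), 0.05)
  # a single populated cell: every filled cell inherits its value
  one <- point_cloud(c(5.5, 5.6), c(5.5, 5.4), c(3, 3))
  dem1 <- build_dem(one, cell = 1)
  expect_true(all(abs(dem1$z - 3) < 1e-12))
  expect_error(build_dem(point_cloud(numeric(0), numeric(0), numeric(0))))
})

test_that("adding ground points never increases the IDW-filled cell count", {
  set.seed(5)
  base <- data.frame(x = runif(80, 0, 20), y = runif(80, 0, 20), z = 1)
  extra <- data.frame(x = runif(80, 0, 20), y = runif(80, 0, 20), z = 1)
  d1 <- build_dem(as_point_cloud(base), cell = 1)
  d2 <- build_dem(as_point_cloud(rbind(base, extra)), cell = 1)
  expect_lte(sum(d2$filled), sum(d1$filled))
})

test_that("height normalization subtracts the DEM and is idempotent on a
           zero DEM", {
  g <- expand.grid(x = seq(0.5, 9.5), y = seq(0.5, 9.5))
  dem <- build_dem(point_cloud(g$x, g$y, 1.2), cell = 1)
  cl <- normalize_heights(point_cloud(3.3, 4.1, 5.2), dem)
  expect_equal(cl$zn, 4.0)
  # normalizing an already-normalized cloud against a zero DEM: identity
  zero_dem <- build_dem(point_cloud(g$x, g$y, 0), cell = 1)
  cl2 <- point_cloud(runif(50, 0, 10), runif(50, 0, 10), runif(50, 0, 30))
  out <- normalize_heights(cl2, zero_dem)
  expect_equal(out$zn, cl2$z)
})

test_that("XYZ round trip preserves coordinates and tree ids", {
  f <- tempfile(fileext = ".xyz")
  cl <- point_cloud(c(1.25, 2.5), c(3, 4), c(5, 6), tree_id = c(1L, 0L))
  write_xyz(cl, f)
  back <- read_xyz(f)
  expect_equal(back$x, cl$x)
  expect_equal(back$tree_id, cl$tree_id)
  unlink(f)
})
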