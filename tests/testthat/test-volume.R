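test_that("a constant-diameter stem integrates to the cylinder volume", {
  v <- tree_volume("M5", D = 20, H = 10, method = "quadrature",
                   coefficients = c(1, 0))
  expect_equal(v, pi * 400 * 10 / 40000, tolerance = 1e-8)
})

test_that("closed-form volumes agree with adaptive quadrature", {
  a <- dawn_redwood_coefs
  for (D in c(20, 30, 40)) {
    for (H in c(20, 25, 30)) {
      va <- tree_volume("M2", D, H, "analytic", coefficients = a)
      vq <- tree_volume("M2", D, H, "quadrature", coefficients = a)
      expect_lt(abs(va - vq) / vq, 1e-6)
    }
  }
  v4a <- tree_volume("M4", 30, 25, "analytic", coefficients = 1.417)
  v4q <- tree_volume("M4", 30, 25, "quadrature", coefficients = 1.417)
  expect_lt(abs(v4a - v4q) / v4q, 1e-6)
  expect_error(tree_volume("M3", 30, 25, "analytic",
                           coefficients = c(25, 1.4)), "closed-form")
})

test_that("M2 volume scales as D^a1 at fixed height", {
  a <- dawn_redwood_coefs
  v1 <- tree_volume("M2", 20, 25, coefficients = a)
  v2 <- tree_volume("M2", 30, 25, coefficients = a)
  expect_equal(v2 / v1, (30 / 20)^a[["a1"]], tolerance = 1e-9)
})

test_that("volume tables are monotone grids matching per-cell quadrature", {
  a <- dawn_redwood_coefs
  tab <- build_volume_table("M2", dbh_classes = seq(20, 40, by = 2),
                            height_classes = seq(20, 30, by = 1),
                            coefficients = a)
  expect_true(all(apply(tab, 2, diff) > 0)) # increasing in DBH
  expect_true(all(apply(tab, 1, diff) > 0)) # increasing in height
  for (i in c(1, 6, 11)) {
    for (j in c(1, 6, 11)) {
      vq <- tree_volume("M2", seq(20, 40, by = 2)[i],
                        seq(20, 30, by = 1)[j], "quadrature",
                        coefficients = a)
      expect_lt(abs(tab[i, j] - vq), 5.1e-5) # table rounded to 4 decimals
    }
  }
  one <- build_volume_table("M2", 30, 25, coefficients = a)
  expect_equal(one[1, 1],
               round(tree_volume("M2", 30, 25, coefficients = a), 4))
  expect_error(build_volume_table("M2", c(30, 20), 25, coefficients = a),
               "ascending")
})

test_that("standard-tree expansion follows the basal-area ratio", {
  # one standard tree: M = V/g * G
  cyl <- list(model = "M5", coefficients = c(a0 = 1, a1 = 0))
  class(cyl) <- "taper_fit"
  trees <- data.frame(D = c(30, 30, 30), H = c(20, 20, 20))
  ps <- stand_volume(trees, cyl, plot_area = 900)
  # all trees are standard here, so M reduces to the sum of volumes
  V1 <- tree_volume("M5", 30, 20, coefficients = c(1, 0))
  expect_equal(ps$M, 3 * V1, tolerance = 1e-9)
  expect_equal(ps$stand_volume, ps$M / 0.09)
  expect_equal(ps$Dg, 30)
  expect_equal(ps$G, 3 * pi * (30 / 200)^2)
  # mixed plot: only one tree is standard, expansion is G / g_std
  trees2 <- data.frame(D = c(20, 40, 45), H = c(15, 25, 26))
  ps2 <- stand_volume(trees2, cyl, plot_area = 900, tolerance = 0.2)
  g <- pi * (trees2$D / 200)^2
  std <- ps2$standard_ids
  expect_equal(std, 2L)
  expect_equal(ps2$M, sum(tree_volume("M5", trees2$D[std], trees2$H[std],
                                      coefficients = c(1, 0))) /
                 sum(g[std]) * sum(g))
  expect_error(stand_volume(data.frame(D = c(10, 60), H = c(30, 5)),
                            cyl, 900, tolerance = 0.01), "widen")
})

test_that("printed plot volumes convert to the published per-hectare values", {
  # a single cylindrical tree whose volume equals the printed plot volume
  per_ha <- function(M_target) {
    H <- M_target * 40000 / (pi * 100^2)
    cyl <- list(model = "M5", coefficients = c(1, 0))
    class(cyl) <- "taper_fit"
    ps <- stand_volume(data.frame(D = 100, H = H), cyl, plot_area = 900)
    round_half_up(ps$stand_volume)
  }
  expect_equal(per_ha(19.15), 212.78)
  expect_equal(per_ha(33.42), 371.33)
})
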