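test_that("rigid transforms compose, invert, and apply consistently", {
  tr <- rigid2d(pi / 7, 3.2, -1.5, 0.4)
  xy <- with_seed(1, matrix(runif(20, -10, 10), ncol = 2))
  there_back <- apply_rigid(invert_rigid(tr), apply_rigid(tr, xy))
  expect_lt(max(abs(there_back - xy)), 1e-9)
  comp <- compose_rigid(invert_rigid(tr), tr)
  expect_equal(comp$theta, 0)
  expect_lt(max(abs(c(comp$tx, comp$ty))), 1e-12)
})

test_that("control-point registration recovers an exact rigid transform", {
  src <- data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  tr0 <- rigid2d(30 * pi / 180, 5, -3)
  d <- apply_rigid(tr0, src)
  fit <- rigid_from_control_points(src, data.frame(x = d[, 1], y = d[, 2]))
  expect_equal(fit$theta, tr0$theta, tolerance = 1e-12)
  expect_equal(c(fit$tx, fit$ty), c(5, -3), tolerance = 1e-9)
  expect_lt(attr(fit, "rms"), 1e-12)
  # identity case
  id <- rigid_from_control_points(src, src)
  expect_equal(id$theta, 0)
  expect_lt(max(abs(c(id$tx, id$ty))), 1e-12)
  expect_error(rigid_from_control_points(src[c(1, 1), ] * 0,
                                         src[c(1, 1), ] * 0),
               "degenerate|coincident")
})

test_that("survey noise of 3 cm keeps the residual RMS within 6 cm", {
  src <- data.frame(x = c(1, 29, 1, 29), y = c(1, 1, 29, 29))
  tr0 <- rigid2d(0.1, 4, 2)
  with_seed(17, {
    rms <- vapply(1:50, function(i) {
      d <- apply_rigid(tr0, src) + matrix(rnorm(8, 0, 0.03), ncol = 2)
      attr(rigid_from_control_points(src, data.frame(x = d[, 1],
                                                     y = d[, 2])), "rms")
    }, numeric(1))
    # E[rms] = sigma * sqrt(5/4) ~ 3.4 cm for 4 poles (5 residual dof);
    # individual draws scatter around it, so bound the mean tightly and
    # each draw loosely
    expect_lte(mean(rms), 0.06)
    expect_lte(max(rms), 0.12)
  })
})

test_that("assignment solver matches brute-force enumeration", {
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    do.call(rbind, lapply(seq_len(n), function(i) {
      sub <- perms(n - 1) + (perms(n - 1) >= i)
      cbind(i, matrix(sub, ncol = n - 1))
    }))
  }
  brute <- function(cost) {
    p <- perms(nrow(cost))
    tot <- apply(p, 1, function(ix) sum(cost[cbind(seq_len(nrow(cost)),
                                                   ix)]))
    min(tot)
  }
  with_seed(23, {
    for (n in c(2, 3, 5)) {
      for (rep in 1:10) {
        cost <- matrix(runif(n * n), n, n)
        asg <- stemvol:::solve_assignment(cost)
        expect_equal(sum(cost[cbind(seq_len(n), asg)]), brute(cost),
                     tolerance = 1e-12)
      }
      # rectangular: more columns than rows
      cost <- matrix(runif(n * (n + 2)), n, n + 2)
      asg <- stemvol:::solve_assignment(cost)
      expect_equal(length(unique(asg)), n) # one-to-one
    }
  })
})

test_that("tree-pattern matching recovers a known displacement exactly", {
  with_seed(29, {
    uls <- data.frame(x = runif(15, 0, 30), y = runif(15, 0, 30))
    tr0 <- rigid2d(0.04, 1.2, -0.8)
    bxy <- apply_rigid(invert_rigid(tr0), uls) # trunks in the "BLS" frame
    bls <- data.frame(x = bxy[, 1], y = bxy[, 2])
    out <- refine_by_tree_matching(uls, bls, rigid2d(), max_pair_dist = 2)
    expect_equal(out$transform$theta, tr0$theta, tolerance = 1e-9)
    expect_equal(c(out$transform$tx, out$transform$ty), c(1.2, -0.8),
                 tolerance = 1e-8)
    expect_lt(max(out$matches$dist), 1e-8)
    expect_error(refine_by_tree_matching(uls[1:2, ], bls[1:2, ]),
                 "at least 3")
  })
})

test_that("apex lean bounds the residual match distance", {
  with_seed(31, {
    stems <- data.frame(x = runif(20, 0, 30), y = runif(20, 0, 30))
    lean <- matrix(runif(40, -0.35, 0.35), ncol = 2) # |lean| <= 0.5 m
    uls <- data.frame(x = stems$x + lean[, 1], y = stems$y + lean[, 2])
    out <- refine_by_tree_matching(uls, stems, rigid2d(),
                                   max_pair_dist = 2)
    expect_lte(mean(out$matches$dist), 0.5)
    # error decreases relative to the initial transform
    init_d <- sqrt((stems$x - uls$x)^2 + (stems$y - uls$y)^2)
    expect_lte(mean(out$matches$dist), mean(init_d) + 1e-9)
  })
})

test_that("spurious trunks do not corrupt the recovered translation", {
  with_seed(37, {
    uls <- expand.grid(x = seq(2, 28, by = 5), y = seq(2, 28, by = 5))
    tr0 <- rigid2d(0, 1.0, -0.6)
    bxy <- apply_rigid(invert_rigid(tr0), as.matrix(uls))
    spur <- matrix(runif(2 * ceiling(0.2 * nrow(uls)), 0, 30), ncol = 2)
    bls <- data.frame(x = c(bxy[, 1], spur[, 1]),
                      y = c(bxy[, 2], spur[, 2]))
    out <- refine_by_tree_matching(uls, bls, rigid2d(), max_pair_dist = 2)
    expect_lt(abs(out$transform$tx - 1.0), 0.1)
    expect_lt(abs(out$transform$ty + 0.6), 0.1)
  })
})

test_that("registration error is the mean match distance in centimeters", {
  expect_equal(registration_error(c(0.84)), 84)
  expect_equal(registration_error(c(0.5, 1.5)), 100)
  expect_equal(registration_error(data.frame(dist = c(0, 0, 0))), 0)
  expect_error(registration_error(numeric(0)), "no matches")
})
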