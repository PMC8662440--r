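#' Species attribute specification for the plot generator
#'
#' Normal distributions for DBH, height and crown radius plus an apex-lean
#' scale. `"conifer-like"` trees get conical crowns with apexes nearly above
#' the stem (dawn-redwood-like); `"broadleaf-like"` trees get half-ellipsoid
#' crowns whose highest point can lean away from the trunk (poplar-like).
#'
#' @param mean_dbh,sd_dbh DBH distribution, cm.
#' @param mean_height,sd_height total-height distribution, m.
#' @param crown_radius_mean,crown_radius_sd crown radius distribution, m.
#' @param lean_sd per-axis SD of the horizontal apex offset, m.
#' @param species_tag `"conifer-like"` or `"broadleaf-like"`.
#' @return a `species_params` list.
#' @export
species_params <- function(mean_dbh, sd_dbh, mean_height, sd_height,
                           crown_radius_mean = 2.0, crown_radius_sd = 0.3,
                           lean_sd = 0.05,
                           species_tag = c("conifer-like",
                                           "broadleaf-like")) {
  species_tag <- match.arg(species_tag)
  stopifnot(mean_dbh > 0, mean_height > 1.3, crown_radius_mean > 0)
  structure(list(mean_dbh = mean_dbh, sd_dbh = sd_dbh,
                 mean_height = mean_height, sd_height = sd_height,
                 crown_radius_mean = crown_radius_mean,
                 crown_radius_sd = crown_radius_sd,
                 lean_sd = lean_sd, species_tag = species_tag),
            class = "species_params")
}

#' Preset plot configurations
#'
#' Seven 30 x 30 m plot configurations ("a".."g") mimicking surveyed
#' dawn-redwood (a-c, conifer-like) and poplar (d-g, broadleaf-like) stands:
#' the DBH/height means and SDs and the stem counts of each plot, with
#' regular planting at 3-8 m spacing. Thinning fractions are set so the
#' expected tree count matches the surveyed stem count of the corresponding
#' stand density class.
#'
#' @param name plot label `"a"`..`"g"`.
#' @return list with `species` ([species_params()]), `row_spacing`,
#'   `col_spacing`, `thinning`, `n_target`.
#' @export
plot_preset <- function(name = c("a", "b", "c", "d", "e", "f", "g")) {
  name <- match.arg(name)
  tab <- list(
    a = list(dbh = c(29.11, 5.97), h = c(25.30, 2.47), n = 27, sp = 5,
             conifer = TRUE),
    b = list(dbh = c(31.57, 3.95), h = c(27.30, 1.71), n = 26, sp = 5,
             conifer = TRUE),
    c = list(dbh = c(27.11, 6.42), h = c(23.22, 2.41), n = 57, sp = 3.5,
             conifer = TRUE),
    d = list(dbh = c(33.30, 10.32), h = c(27.84, 3.59), n = 18, sp = 7,
             conifer = FALSE),
    e = list(dbh = c(34.57, 5.22), h = c(31.46, 1.90), n = 21, sp = 6,
             conifer = FALSE),
    f = list(dbh = c(38.15, 7.57), h = c(33.16, 2.41), n = 22, sp = 6,
             conifer = FALSE),
    g = list(dbh = c(24.69, 5.44), h = c(23.20, 2.14), n = 44, sp = 4,
             conifer = FALSE)
  )[[name]]
  grid_n <- floor(30 / tab$sp)^2
  sp <- species_params(
    mean_dbh = tab$dbh[1], sd_dbh = tab$dbh[2],
    mean_height = tab$h[1], sd_height = tab$h[2],
    crown_radius_mean = if (tab$conifer) 2.0 else 2.6,
    crown_radius_sd = if (tab$conifer) 0.3 else 0.4,
    lean_sd = if (tab$conifer) 0.05 else 0.45,
    species_tag = if (tab$conifer) "conifer-like" else "broadleaf-like")
  list(species = sp, row_spacing = tab$sp, col_spacing = tab$sp,
       thinning = max(0, (grid_n - tab$n) / grid_n), n_target = tab$n)
}

#' Generate a ground-truth planted-forest plot
#'
#' Stems sit on a regular planting grid (small position jitter), a random
#' fraction of grid positions is thinned, and per-tree attributes are drawn
#' from the species distributions. The ground is a plane with a configurable
#' slope (default 0.04%, i.e. nearly flat alluvial terrain), and stems are
#' shaped by a configurable taper equation; the default is the anchored
#' one-parameter exponent form (`M4`, exponent 1.417), so the simulated stem
#' diameter at 1.3 m equals the tree's DBH exactly.
#'
#' @param species a [species_params()] object.
#' @param row_spacing,col_spacing planting spacing, m (3-8 m is realistic).
#' @param plot_size square plot side, m.
#' @param thinning fraction of grid positions removed at random.
#' @param jitter_sd SD of the planting-position jitter, m.
#' @param ground list `z0`, `slope_x`, `slope_y` (plane coefficients).
#' @param taper list with `model` and `coefficients` shaping the stems.
#' @param seed integer seed; the same seed reproduces the plot exactly.
#' @return a `plot_truth` list: `trees` data frame (`id`, `x`, `y`, `H`,
#'   `D`, `crown_radius`, `lean_dx`, `lean_dy`, `species_tag`), plus the
#'   layout, ground and taper configuration.
#' @export
#' @examples
#' truth <- generate_plot(plot_preset("b")$species, 5, 5, thinning = 0, seed = 1)
#' nrow(truth$trees) # 36 on the full 6 x 6 grid
generate_plot <- function(species, row_spacing = 5, col_spacing = 5,
                          plot_size = 30, thinning = 0.1, jitter_sd = 0.1,
                          ground = list(z0 = 4.5, slope_x = 4e-4,
                                        slope_y = 0),
                          taper = list(model = "M4", coefficients = 1.417),
                          seed = 1) {
  if (plot_size <= 0 || row_spacing <= 0 || col_spacing <= 0)
    stop("plot_size and spacings must be positive")
  stopifnot(inherits(species, "species_params"))
  nx <- floor(plot_size / row_spacing)
  ny <- floor(plot_size / col_spacing)
  if (nx < 1 || ny < 1) stop("spacing exceeds plot size")
  with_seed(seed, {
    gx <- (seq_len(nx) - 0.5) * row_spacing
    gy <- (seq_len(ny) - 0.5) * col_spacing
    pos <- expand.grid(x = gx, y = gy)
    n0 <- nrow(pos)
    n_thin <- round(thinning * n0)
    if (n_thin > 0) pos <- pos[-sample.int(n0, n_thin), , drop = FALSE]
    n <- nrow(pos)
    jitter <- function(v) pmin(pmax(v + stats::rnorm(n, 0, jitter_sd), 0.2),
                               plot_size - 0.2)
    x <- jitter(pos$x); y <- jitter(pos$y)
    draw_pos <- function(mean, sd, lo) {
      v <- stats::rnorm(n, mean, sd)
      bad <- v <= lo
      while (any(bad)) {
        v[bad] <- stats::rnorm(sum(bad), mean, sd)
        bad <- v <= lo
      }
      v
    }
    D <- draw_pos(species$mean_dbh, species$sd_dbh, 5)
    H <- draw_pos(species$mean_height, species$sd_height, 2)
    cr <- draw_pos(species$crown_radius_mean, species$crown_radius_sd, 0.5)
    lean_dx <- stats::rnorm(n, 0, species$lean_sd)
    lean_dy <- stats::rnorm(n, 0, species$lean_sd)
    # apex must stay inside the crown
    ll <- sqrt(lean_dx^2 + lean_dy^2)
    too_far <- ll >= 0.95 * cr
    scl <- ifelse(too_far, 0.95 * cr / pmax(ll, 1e-9), 1)
    lean_dx <- lean_dx * scl
    lean_dy <- lean_dy * scl
    trees <- data.frame(id = seq_len(n), x = x, y = y, H = H, D = D,
                        crown_radius = cr, lean_dx = lean_dx,
                        lean_dy = lean_dy,
                        species_tag = species$species_tag,
                        stringsAsFactors = FALSE)
    structure(list(trees = trees, plot_size = plot_size,
                   row_spacing = row_spacing, col_spacing = col_spacing,
                   ground = ground, taper = taper, seed = seed),
              class = "plot_truth")
  })
}

#' Ground elevation of a truth plot at given positions
#' @param truth a [generate_plot()] result.
#' @param x,y positions, m.
#' @return elevations, m.
#' @export
ground_elevation <- function(truth, x, y) {
  g <- truth$ground
  g$z0 + g$slope_x * x + g$slope_y * y
}

#' True stem diameter of a simulated tree at a given height
#'
#' Evaluates the taper configured in the truth object for one tree.
#'
#' @param truth a [generate_plot()] result.
#' @param id tree id.
#' @param h height along the stem, m (vectorized).
#' @return diameter, cm.
#' @export
true_stem_diameter <- function(truth, id, h) {
  tr <- truth$trees[truth$trees$id == id, ]
  if (nrow(tr) != 1) stop("unknown tree id ", id)
  eval_taper(truth$taper$model, D = tr$D, H = tr$H, h = h,
             coefficients = truth$taper$coefficients)
}

#' Simulate an above-canopy (ULS) scan of a truth plot
#'
#' Points are drawn on crown surfaces — cones for conifer-like trees,
#' upper half-ellipsoids for broadleaf-like trees — plus uniformly scattered
#' ground returns; crowns receive points in proportion to their projected
#' area so the requested overall density is met exactly before noise. One
#' exact apex point per tree guarantees that, without noise, the maximum
#' height over a tree's points equals its true height. Isotropic Gaussian
#' noise of scale `noise_sigma` is then added to every coordinate.
#'
#' @param truth a [generate_plot()] result.
#' @param density total point density, points per m^2.
#' @param ground_density part of `density` allocated to ground returns,
#'   points per m^2 (canopy gets the rest).
#' @param crown_ratio crown depth as a fraction of tree height.
#' @param noise_sigma coordinate noise SD, m.
#' @param seed integer seed.
#' @return a `simulated_scan` list: `cloud` ([point_cloud()] with `tree_id`
#'   and `class`), `scan_kind = "ULS"`, `applied_transform` (identity),
#'   `noise_sigma`, `density`.
#' @export
sample_uls_cloud <- function(truth, density = 84, ground_density = 9,
                             crown_ratio = 0.4, noise_sigma = 0.03,
                             seed = 1) {
  if (density <= 0) stop("density must be positive")
  area <- truth$plot_size^2
  trees <- truth$trees
  n_total <- round(density * area)
  n_ground <- min(round(ground_density * area), n_total - nrow(trees))
  n_crown <- n_total - n_ground - nrow(trees) # one exact apex pt per tree

  with_seed(seed, {
    w <- trees$crown_radius^2
    alloc <- floor(n_crown * w / sum(w))
    left <- n_crown - sum(alloc)
    if (left > 0) {
      extra <- sample.int(nrow(trees), left, replace = TRUE)
      for (i in extra) alloc[i] <- alloc[i] + 1
    }
    parts <- vector("list", nrow(trees) + 2)
    for (i in seq_len(nrow(trees))) {
      tr <- trees[i, ]
      m <- alloc[i]
      gz <- ground_elevation(truth, tr$x, tr$y)
      depth <- crown_ratio * tr$H
      theta <- stats::runif(m, 0, 2 * pi)
      if (tr$species_tag == "conifer-like") {
        s <- sqrt(stats::runif(m)) # 0 = apex, 1 = crown base
        r <- tr$crown_radius * s
        cx <- tr$x + tr$lean_dx * (1 - s)
        cy <- tr$y + tr$lean_dy * (1 - s)
        z <- gz + tr$H - depth * s
      } else {
        cphi <- stats::runif(m) # upper half-ellipsoid, 1 = apex
        r <- tr$crown_radius * sqrt(1 - cphi^2)
        cx <- tr$x + tr$lean_dx * cphi
        cy <- tr$y + tr$lean_dy * cphi
        z <- gz + tr$H - depth + depth * cphi
      }
      parts[[i]] <- data.frame(x = cx + r * cos(theta),
                               y = cy + r * sin(theta), z = z,
                               tree_id = tr$id, class = "vegetation")
    }
    # exact apex points
    parts[[nrow(trees) + 1]] <- data.frame(
      x = trees$x + trees$lean_dx, y = trees$y + trees$lean_dy,
      z = ground_elevation(truth, trees$x, trees$y) + trees$H,
      tree_id = trees$id, class = "vegetation")
    gxy <- matrix(stats::runif(2 * n_ground, 0, truth$plot_size),
                  ncol = 2)
    parts[[nrow(trees) + 2]] <- data.frame(
      x = gxy[, 1], y = gxy[, 2],
      z = ground_elevation(truth, gxy[, 1], gxy[, 2]),
      tree_id = 0L, class = "ground")
    cloud <- do.call(rbind, parts)
    if (noise_sigma > 0) {
      cloud$x <- cloud$x + stats::rnorm(nrow(cloud), 0, noise_sigma)
      cloud$y <- cloud$y + stats::rnorm(nrow(cloud), 0, noise_sigma)
      cloud$z <- cloud$z + stats::rnorm(nrow(cloud), 0, noise_sigma)
    }
    structure(list(cloud = as_point_cloud(cloud), scan_kind = "ULS",
                   applied_transform = rigid2d(0, 0, 0),
                   noise_sigma = noise_sigma, density = density,
                   truth = truth),
              class = "simulated_scan")
  })
}

#' Simulate an under-canopy (BLS) scan of a truth plot
#'
#' Stem returns are sampled on circular cross-sections whose radius at
#' height `h` follows the truth object's taper equation, from 0.05 m above
#' ground up to `height_cap` (the sensor's vertical reach, default 9 m) but
#' never above the tree itself. Ground returns and optional understory
#' clutter (uniform below 1.5 m) are added, isotropic Gaussian noise is
#' applied, and the whole cloud is expressed in a scanner frame displaced
#' from the plot frame by `transform`, which is recorded as ground truth.
#'
#' @param truth a [generate_plot()] result.
#' @param pts_per_stem_slice stem returns per 10-cm height band per tree.
#' @param noise_sigma coordinate noise SD, m.
#' @param transform a [rigid2d()]: plot frame -> scanner frame.
#' @param height_cap maximum normalized height of stem returns, m.
#' @param ground_density ground returns per m^2.
#' @param clutter_density understory clutter points per m^2 (0 disables).
#' @param seed integer seed.
#' @return a `simulated_scan` list (`scan_kind = "BLS"`), with
#'   `applied_transform` and `height_cap` recorded.
#' @export
sample_bls_cloud <- function(truth, pts_per_stem_slice = 200,
                             noise_sigma = 0.01,
                             transform = rigid2d(0, 0, 0),
                             height_cap = 9, ground_density = 5,
                             clutter_density = 2, seed = 1) {
  if (height_cap <= 1.3) stop("height_cap must exceed 1.3 m")
  area <- truth$plot_size^2
  trees <- truth$trees
  slice_w <- 0.1

  with_seed(seed, {
    parts <- list()
    for (i in seq_len(nrow(trees))) {
      tr <- trees[i, ]
      hmax <- min(height_cap, 0.95 * tr$H)
      h0 <- 0.25 # scanners rarely resolve the stem base inside ground litter
      # 10-cm bands; azimuths are stratified within each band (with jitter),
      # mimicking the regular angular sampling of a scanning sensor rather
      # than iid azimuths, which would add artificial angular clumping
      band_lo <- seq(h0, hmax - slice_w, by = slice_w)
      m <- pts_per_stem_slice
      nb <- length(band_lo)
      h <- rep(band_lo, each = m) + stats::runif(nb * m, 0, slice_w)
      theta <- as.vector(vapply(seq_len(nb), function(b)
        2 * pi * (sample.int(m) - stats::runif(m)) / m, numeric(m)))
      d_cm <- eval_taper(truth$taper$model, D = tr$D, H = tr$H, h = h,
                         coefficients = truth$taper$coefficients)
      r <- d_cm / 200
      gz <- ground_elevation(truth, tr$x, tr$y)
      parts[[length(parts) + 1]] <- data.frame(
        x = tr$x + r * cos(theta), y = tr$y + r * sin(theta),
        z = gz + h, tree_id = tr$id, class = "vegetation")
    }
    n_ground <- round(ground_density * area)
    if (n_ground > 0) {
      gxy <- matrix(stats::runif(2 * n_ground, 0, truth$plot_size), ncol = 2)
      parts[[length(parts) + 1]] <- data.frame(
        x = gxy[, 1], y = gxy[, 2],
        z = ground_elevation(truth, gxy[, 1], gxy[, 2]),
        tree_id = 0L, class = "ground")
    }
    n_cl <- round(clutter_density * area)
    if (n_cl > 0) {
      cxy <- matrix(stats::runif(2 * n_cl, 0, truth$plot_size), ncol = 2)
      parts[[length(parts) + 1]] <- data.frame(
        x = cxy[, 1], y = cxy[, 2],
        z = ground_elevation(truth, cxy[, 1], cxy[, 2]) +
          stats::runif(n_cl, 0, 1.5),
        tree_id = 0L, class = "vegetation")
    }
    cloud <- do.call(rbind, parts)
    if (noise_sigma > 0) {
      cloud$x <- cloud$x + stats::rnorm(nrow(cloud), 0, noise_sigma)
      cloud$y <- cloud$y + stats::rnorm(nrow(cloud), 0, noise_sigma)
      cloud$z <- cloud$z + stats::rnorm(nrow(cloud), 0, noise_sigma)
    }
    xy <- apply_rigid(transform, cbind(cloud$x, cloud$y))
    cloud$x <- xy[, 1]
    cloud$y <- xy[, 2]
    cloud$z <- cloud$z + transform$dz
    structure(list(cloud = as_point_cloud(cloud), scan_kind = "BLS",
                   applied_transform = transform,
                   noise_sigma = noise_sigma,
                   pts_per_stem_slice = pts_per_stem_slice,
                   height_cap = height_cap, truth = truth),
              class = "simulated_scan")
  })
}

#' Simulate surveyed control points for coarse registration
#'
#' Four 2-m reference poles near the plot corners, surveyed in the ULS
#' (plot) frame with small RTK error, and observed exactly in the scanner
#' frame of the BLS cloud.
#'
#' @param truth a [generate_plot()] result.
#' @param transform the rigid transform applied to the BLS cloud.
#' @param survey_sd RTK survey error SD, m (default 0.03 m).
#' @param inset pole distance from the plot edges, m.
#' @param seed integer seed.
#' @return list of data frames `uls` and `bls` (`label`, `x`, `y`, `z`).
#' @export
simulate_control_points <- function(truth, transform, survey_sd = 0.03,
                                    inset = 1, seed = 1) {
  s <- truth$plot_size
  px <- c(inset, inset, s - inset, s - inset)
  py <- c(inset, s - inset, inset, s - inset)
  pz <- ground_elevation(truth, px, py) + 2
  with_seed(seed, {
    uls <- data.frame(label = paste0("P", 1:4),
                      x = px + stats::rnorm(4, 0, survey_sd),
                      y = py + stats::rnorm(4, 0, survey_sd),
                      z = pz)
    bxy <- apply_rigid(transform, cbind(px, py))
    bls <- data.frame(label = paste0("P", 1:4), x = bxy[, 1], y = bxy[, 2],
                      z = pz + transform$dz)
    list(uls = uls, bls = bls)
  })
}
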