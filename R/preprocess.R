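#' Statistical outlier removal
#'
#' Classic k-nearest-neighbour denoising: a point is dropped when its mean
#' distance to its `k` nearest neighbours exceeds the cloud-wide mean of
#' that statistic by more than `n_sigma` standard deviations (isolated
#' returns such as birds or multipath artefacts).
#'
#' @param cloud a [point_cloud()].
#' @param k neighbour count (>= 1).
#' @param n_sigma threshold in standard deviations.
#' @return the filtered cloud; the number of removed points is attached as
#'   attribute `n_removed`.
#' @export
remove_outliers <- function(cloud, k = 8, n_sigma = 3) {
  stopifnot(k >= 1)
  if (nrow(cloud) < k + 1) {
    warning("cloud has fewer than k+1 points; returned unchanged")
    attr(cloud, "n_removed") <- 0L
    return(cloud)
  }
  md <- cpp_knn_mean_dist(cloud$x, cloud$y, cloud$z, as.integer(k))
  keep <- md <= mean(md) + n_sigma * stats::sd(md)
  out <- cloud[keep, , drop = FALSE]
  attr(out, "n_removed") <- as.integer(sum(!keep))
  out
}

#' Ground/vegetation classification by progressive TIN densification
#'
#' Starts from the lowest point in each `seed_cell` x `seed_cell` block,
#' triangulates the seeds, and then iteratively adds any point whose
#' perpendicular distance to its facet plane is at most `max_dist` and
#' whose maximum angle to the facet vertices is at most `max_angle`,
#' re-triangulating after every round until no point is added. Two
#' robustness refinements are built in: the TIN vertices are thinned to the
#' lowest accepted point per `tin_cell` block (keeps the triangulation
#' well-conditioned on stem-dominated under-canopy clouds), and points
#' within `tight_tol` of their facet plane are accepted on distance alone,
#' since the vertex-angle criterion degenerates immediately above a vertex.
#' With collinear (degenerate) seeds the filter falls back to a
#' least-squares plane through the seed points (flagged in attribute
#' `fallback`).
#'
#' @param cloud a [point_cloud()].
#' @param seed_cell seed-block size, m.
#' @param max_angle densification angle threshold, degrees.
#' @param max_dist densification distance threshold, m.
#' @param max_iter maximum densification rounds.
#' @param tin_cell TIN vertex thinning cell, m.
#' @param tight_tol distance below which a point is ground regardless of
#'   angle, m.
#' @return the cloud with a `class` column set to `"ground"`/`"vegetation"`.
#' @export
classify_ground <- function(cloud, seed_cell = 5, max_angle = 8,
                            max_dist = 0.5, max_iter = 30, tin_cell = 0.5,
                            tight_tol = 0.15) {
  if (nrow(cloud) == 0) stop("empty cloud")
  cx <- floor((cloud$x - min(cloud$x)) / seed_cell)
  cy <- floor((cloud$y - min(cloud$y)) / seed_cell)
  cellid <- paste(cx, cy)
  seeds <- vapply(split(seq_len(nrow(cloud)), cellid),
                  function(ix) ix[which.min(cloud$z[ix])], integer(1))
  seeds <- unname(seeds)

  xy <- cbind(cloud$x[seeds], cloud$y[seeds])
  degenerate <- length(seeds) < 3 ||
    qr(sweep(xy, 2, colMeans(xy)))$rank < 2
  if (degenerate) {
    # lowest-plane fallback
    sdf <- data.frame(x = cloud$x[seeds], y = cloud$y[seeds],
                      z = cloud$z[seeds])
    fit <- stats::lm(z ~ x + y, data = sdf)
    pred <- stats::coef(fit)[1] + stats::coef(fit)[2] * cloud$x +
      stats::coef(fit)[3] * cloud$y
    pred[is.na(pred)] <- mean(sdf$z)
    ground <- abs(cloud$z - pred) <= max_dist
    cloud$class <- ifelse(ground, "ground", "vegetation")
    attr(cloud, "fallback") <- TRUE
    return(cloud)
  }
  ground <- cpp_iptd(cloud$x, cloud$y, cloud$z, as.integer(seeds),
                     max_angle, max_dist, as.integer(max_iter), tin_cell,
                     tight_tol)
  cloud$class <- ifelse(ground, "ground", "vegetation")
  attr(cloud, "fallback") <- FALSE
  cloud
}

#' Build a digital elevation model from ground points
#'
#' Rasterizes the ground returns to `cell`-sized cells (default 1 m) by the
#' mean elevation per cell. Cells without returns — and cells whose mean
#' stands out from their neighbourhood by more than three standard
#' deviations of the neighbour residuals (missed low-vegetation noise) —
#' are filled by inverse-distance-weighted interpolation over the `idw_k`
#' nearest populated cell centres with exponent `idw_power`.
#'
#' @param cloud a [point_cloud()]; rows with `class == "ground"` are used,
#'   or all rows if there is no `class` column.
#' @param cell cell size, m.
#' @param idw_power IDW exponent.
#' @param idw_k IDW neighbour count.
#' @return a `dem_grid`: `origin`, `cell`, elevation matrix `z`
#'   (rows = x index, cols = y index), and logical `filled` mask.
#' @export
build_dem <- function(cloud, cell = 1, idw_power = 2, idw_k = 12) {
  stopifnot(cell > 0)
  g <- if ("class" %in% names(cloud))
    cloud[cloud$class == "ground", , drop = FALSE] else cloud
  if (nrow(g) == 0) stop("no ground points")
  x0 <- floor(min(g$x) / cell) * cell
  y0 <- floor(min(g$y) / cell) * cell
  nx <- max(1L, ceiling((max(g$x) - x0) / cell))
  ny <- max(1L, ceiling((max(g$y) - y0) / cell))
  ix <- pmin(pmax(floor((g$x - x0) / cell), 0), nx - 1)
  iy <- pmin(pmax(floor((g$y - y0) / cell), 0), ny - 1)
  idx <- ix + nx * iy + 1
  sums <- tapply(g$z, idx, mean)
  z <- matrix(NA_real_, nx, ny)
  z[as.integer(names(sums))] <- as.numeric(sums)

  # flag populated cells standing off their neighbourhood (residual vs the
  # 8-neighbour median, scaled robustly) — typically cells whose mean was
  # dragged up by misclassified stem or understory returns
  has <- !is.na(z)
  if (sum(has) > 8) {
    nb_med <- matrix(NA_real_, nx, ny)
    for (i in which(has)) {
      r <- (i - 1) %% nx + 1
      c <- (i - 1) %/% nx + 1
      rr <- max(1, r - 1):min(nx, r + 1)
      cc <- max(1, c - 1):min(ny, c + 1)
      nb <- z[rr, cc]
      nb <- nb[!is.na(nb)]
      nb <- nb[-which.max(nb == z[r, c])[1]] # drop one copy of self
      if (length(nb) >= 3) nb_med[r, c] <- stats::median(nb)
    }
    resid <- z - nb_med
    rs <- stats::mad(resid[!is.na(resid)])
    if (is.finite(rs)) {
      bad <- !is.na(resid) & abs(resid) > max(4 * rs, 0.1)
      z[bad] <- NA_real_
    }
  }

  filled <- is.na(z)
  if (all(filled)) stop("all DEM cells empty")
  if (any(filled)) {
    cxs <- x0 + (seq_len(nx) - 0.5) * cell
    cys <- y0 + (seq_len(ny) - 0.5) * cell
    pop <- which(!is.na(z), arr.ind = TRUE)
    px <- cxs[pop[, 1]]; py <- cys[pop[, 2]]; pz <- z[pop]
    emp <- which(is.na(z), arr.ind = TRUE)
    k <- min(idw_k, length(pz))
    for (j in seq_len(nrow(emp))) {
      ex <- cxs[emp[j, 1]]; ey <- cys[emp[j, 2]]
      d2 <- (px - ex)^2 + (py - ey)^2
      nn <- order(d2)[seq_len(k)]
      w <- 1 / pmax(d2[nn]^(idw_power / 2), 1e-12)
      z[emp[j, 1], emp[j, 2]] <- sum(w * pz[nn]) / sum(w)
    }
  }
  structure(list(origin = c(x0, y0), cell = cell, z = z, filled = filled),
            class = "dem_grid")
}

#' DEM elevation at arbitrary positions
#'
#' Looks up the cell containing each position; positions outside the grid
#' use the nearest cell.
#'
#' @param dem a [build_dem()] result.
#' @param x,y positions, m.
#' @return elevations, m.
#' @export
dem_elevation <- function(dem, x, y) {
  nx <- nrow(dem$z); ny <- ncol(dem$z)
  ix <- pmin(pmax(floor((x - dem$origin[1]) / dem$cell), 0), nx - 1) + 1
  iy <- pmin(pmax(floor((y - dem$origin[2]) / dem$cell), 0), ny - 1) + 1
  dem$z[cbind(ix, iy)]
}

#' Normalize point heights against a DEM
#'
#' Stores each point's height above the DEM surface in column `zn`; ground
#' points normalize to approximately zero and treetop heights become tree
#' heights. Stored heights are never clamped; negative values are preserved.
#'
#' @param cloud a [point_cloud()].
#' @param dem a [build_dem()] result covering the cloud extent.
#' @return the cloud with a `zn` column.
#' @export
normalize_heights <- function(cloud, dem) {
  cloud$zn <- cloud$z - dem_elevation(dem, cloud$x, cloud$y)
  cloud
}

#' Export a DEM as an ESRI ASCII grid
#' @param dem a [build_dem()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dem_asc <- function(dem, path) {
  nx <- nrow(dem$z); ny <- ncol(dem$z)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", nx), paste("nrows", ny),
               paste("xllcorner", dem$origin[1]),
               paste("yllcorner", dem$origin[2]),
               paste("cellsize", dem$cell),
               "NODATA_value -9999"), con)
  for (row in ny:1) # ASCII grids run north to south
    writeLines(paste(dem$z[, row], collapse = " "), con)
  invisible(path)
}
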