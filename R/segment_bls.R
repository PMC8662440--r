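#' Extract a horizontal slice of a normalized cloud
#'
#' Returns the points whose normalized height lies in the half-open band
#' `[center - width/2, center + width/2)`.
#'
#' @param cloud a height-normalized [point_cloud()].
#' @param center slice centre height, m (1.3 m for breast height).
#' @param width slice thickness, m.
#' @return the sliced [point_cloud()] (possibly empty).
#' @export
slice_cloud <- function(cloud, center = 1.3, width = 0.1) {
  stopifnot(width > 0)
  if (!"zn" %in% names(cloud))
    stop("cloud must be height-normalized first")
  lo <- center - width / 2
  hi <- center + width / 2
  cloud[cloud$zn >= lo & cloud$zn < hi, , drop = FALSE]
}

#' Detect trunks in a breast-height slice by density clustering
#'
#' DBSCAN in the horizontal (x, y) projection of the slice: a point with at
#' least `minpts` points (itself included) within radius `eps` is a core
#' point of a trunk; clusters are maximal density-connected sets and
#' everything else (sparse understory, grass) is noise. Each cluster is
#' summarized by its gravity-centre circle fit.
#'
#' @param slice a [slice_cloud()] result.
#' @param eps neighbourhood radius, m.
#' @param minpts density threshold (points, inclusive of the point itself).
#' @return list with `trunks` (data frame `id`, `x`, `y`, `D`, `n_points`;
#'   DBH in cm) and `labels` (per-point cluster id, 0 = noise).
#' @export
detect_trunks <- function(slice, eps = 0.2, minpts = 15) {
  stopifnot(eps > 0, minpts >= 1)
  if (nrow(slice) == 0)
    return(list(trunks = data.frame(id = integer(), x = numeric(),
                                    y = numeric(), D = numeric(),
                                    n_points = integer()),
                labels = integer(0)))
  lab <- cpp_dbscan2d(slice$x, slice$y, eps, as.integer(minpts))
  ids <- sort(unique(lab[lab > 0]))
  rows <- lapply(ids, function(k) {
    ix <- which(lab == k)
    fit <- fit_circle_diameter(slice[ix, c("x", "y")])
    data.frame(x = fit$center[1], y = fit$center[2], D = fit$D,
               n_points = length(ix))
  })
  trunks <- do.call(rbind, rows)
  if (is.null(trunks))
    trunks <- data.frame(x = numeric(), y = numeric(), D = numeric(),
                         n_points = integer())
  trunks <- cbind(id = seq_len(nrow(trunks)), trunks)
  rownames(trunks) <- NULL
  list(trunks = trunks, labels = lab)
}

#' Gravity-centre circle fit of a trunk cross-section
#'
#' The centre is the mean (x, y) of the points and the radius the mean
#' Euclidean distance of the points from that centre; the diameter is
#' reported in centimeters (the package's single meters-to-centimeters
#' conversion for diameters).
#'
#' @param points data frame with columns `x`, `y` (meters).
#' @return list `center` (x, y in m) and `D` (diameter, cm).
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 100)
#' fit_circle_diameter(data.frame(x = 0.15 * cos(th), y = 0.15 * sin(th)))
fit_circle_diameter <- function(points) {
  if (nrow(points) == 0) stop("empty cluster")
  if (nrow(points) == 1) stop("diameter undefined for a single point")
  cx <- mean(points$x); cy <- mean(points$y)
  r <- mean(sqrt((points$x - cx)^2 + (points$y - cy)^2))
  list(center = c(cx, cy), D = 200 * r)
}

#' Upper-stem diameter profile of one detected trunk
#'
#' Slices the normalized cloud at each requested height (10-cm bands),
#' keeps the points within `2 * eps` of the trunk axis — tracked upward
#' slice to slice, allowing the centre to drift by at most 0.5 m between
#' consecutive slices — and circle-fits each band. Heights with fewer than
#' `minpts` points are omitted from the profile.
#'
#' @param cloud the height-normalized BLS [point_cloud()].
#' @param trunk one row of [detect_trunks()]'s `trunks` (or a list with
#'   `id`, `x`, `y`).
#' @param heights slice centres, m; the canonical ladder is
#'   `seq(1.3, 8.3, by = 1)`.
#' @param eps DBSCAN radius used for the axis window, m.
#' @param minpts minimum points per retained sample.
#' @param width slice thickness, m.
#' @return a `stem_profile`: data frame `tree_id`, `h` (m), `d` (cm),
#'   `n_points`; empty (with attribute `flagged = TRUE`) when no height
#'   yields a valid sample.
#' @export
stem_profile <- function(cloud, trunk, heights = seq(1.3, 8.3, by = 1),
                         eps = 0.2, minpts = 15, width = 0.1) {
  cx <- trunk$x; cy <- trunk$y
  rows <- list()
  for (h in sort(heights)) {
    sl <- slice_cloud(cloud, center = h, width = width)
    if (nrow(sl) == 0) next
    d2 <- sqrt((sl$x - cx)^2 + (sl$y - cy)^2)
    sel <- d2 <= 2 * eps
    if (sum(sel) < minpts) next
    fit <- fit_circle_diameter(sl[sel, c("x", "y")])
    # track the axis upward; a jump beyond 0.5 m is not this stem
    if (sqrt((fit$center[1] - cx)^2 + (fit$center[2] - cy)^2) > 0.5) next
    cx <- fit$center[1]; cy <- fit$center[2]
    rows[[length(rows) + 1]] <- data.frame(tree_id = trunk$id, h = h,
                                           d = fit$D,
                                           n_points = sum(sel))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tree_id = integer(), h = numeric(), d = numeric(),
                      n_points = integer())
    attr(out, "flagged") <- TRUE
  } else {
    attr(out, "flagged") <- FALSE
  }
  class(out) <- c("stem_profile", class(out))
  out
}
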