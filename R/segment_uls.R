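#' Top-down individual-tree segmentation of a normalized ULS cloud
#'
#' Point-cloud distance-judgement clustering: points above `h_min` are
#' processed in strictly descending normalized height (ties broken by point
#' index). The highest unassigned point seeds a new tree (its treetop)
#' unless it lies within `t2` of an existing treetop; any other point joins
#' the tree owning its nearest already-assigned point when that horizontal
#' distance is at most `t1`. `t1` should be close to the planting spacing
#' and `t2` close to the average crown radius. Trees ending up with fewer
#' than `min_points` points are dissolved.
#'
#' @param cloud a height-normalized [point_cloud()] (column `zn`).
#' @param t1 spacing threshold, m.
#' @param t2 treetop exclusion radius, m.
#' @param h_min minimum normalized height considered, m.
#' @param min_points minimum points per retained tree.
#' @return list with `trees` (data frame `id`, `x`, `y`, `H`,
#'   `crown_radius`, `n_points`; apex position and height per tree) and
#'   `labels` (per-point tree id aligned with `cloud` rows, 0 =
#'   unassigned / below `h_min`).
#' @export
segment_trees <- function(cloud, t1 = 2, t2 = 2.5, h_min = 2,
                          min_points = 30) {
  stopifnot(t1 > 0, t2 > 0, h_min >= 0)
  if (!"zn" %in% names(cloud))
    stop("cloud must be height-normalized first (see normalize_heights)")
  sel <- which(cloud$zn >= h_min)
  labels <- integer(nrow(cloud))
  if (length(sel) == 0)
    return(list(trees = data.frame(id = integer(), x = numeric(),
                                   y = numeric(), H = numeric(),
                                   crown_radius = numeric(),
                                   n_points = integer()),
                labels = labels))
  lab <- cpp_uls_segment(cloud$x[sel], cloud$y[sel], cloud$zn[sel], t1, t2)
  # dissolve fragments and renumber by descending apex height
  cnt <- tabulate(lab)
  keep <- which(cnt >= min_points)
  rows <- lapply(keep, function(tid) {
    ix <- sel[lab == tid]
    att <- tree_attributes(cloud[ix, , drop = FALSE])
    data.frame(x = att$apex[1], y = att$apex[2], H = att$H,
               crown_radius = att$crown_radius, n_points = length(ix))
  })
  trees <- do.call(rbind, rows)
  if (is.null(trees)) {
    trees <- data.frame(x = numeric(), y = numeric(), H = numeric(),
                        crown_radius = numeric(), n_points = integer())
  }
  ord <- order(-trees$H)
  trees <- trees[ord, , drop = FALSE]
  trees <- cbind(id = seq_len(nrow(trees)), trees)
  rownames(trees) <- NULL
  relabel <- integer(max(lab, 1))
  relabel[keep[ord]] <- seq_along(keep)
  labels[sel] <- ifelse(lab > 0, relabel[pmax(lab, 1)], 0L)
  list(trees = trees, labels = labels)
}

#' Height and crown radius of one segmented tree
#'
#' The tree height is the maximum normalized height over the tree's points
#' (its apex); the crown radius is the mean horizontal distance from the
#' apex position over the tree's other points (a single-point tree has
#' crown radius 0).
#'
#' @param points the tree's points: data frame with `x`, `y`, `zn`.
#' @return list `H`, `crown_radius`, `apex` (x, y, zn).
#' @export
tree_attributes <- function(points) {
  stopifnot(nrow(points) >= 1)
  i <- which.max(points$zn)
  ax <- points$x[i]; ay <- points$y[i]
  cr <- if (nrow(points) > 1)
    mean(sqrt((points$x[-i] - ax)^2 + (points$y[-i] - ay)^2)) else 0
  list(H = points$zn[i], crown_radius = cr, apex = c(ax, ay, points$zn[i]))
}
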