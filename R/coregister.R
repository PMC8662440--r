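#' 2D rigid transform
#'
#' Rotation by `theta` about the origin followed by translation, with an
#' optional vertical offset: `(x, y) -> R(theta) (x, y) + (tx, ty)`,
#' `z -> z + dz`.
#'
#' @param theta rotation, radians.
#' @param tx,ty translation, m.
#' @param dz vertical offset, m.
#' @return a `rigid2d` object.
#' @export
rigid2d <- function(theta = 0, tx = 0, ty = 0, dz = 0) {
  structure(list(theta = theta, tx = tx, ty = ty, dz = dz),
            class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("rigid2d: theta = %.6f rad, t = (%.3f, %.3f) m, dz = %.3f m\n",
              x$theta, x$tx, x$ty, x$dz))
  invisible(x)
}

#' Apply a rigid transform to 2D points
#' @param tr a [rigid2d()].
#' @param xy two-column matrix (or data frame) of positions.
#' @return transformed matrix of the same shape.
#' @export
apply_rigid <- function(tr, xy) {
  xy <- as.matrix(xy)
  ct <- cos(tr$theta); st <- sin(tr$theta)
  cbind(ct * xy[, 1] - st * xy[, 2] + tr$tx,
        st * xy[, 1] + ct * xy[, 2] + tr$ty)
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid2d()] objects.
#' @return the composite transform `a o b`.
#' @export
compose_rigid <- function(a, b) {
  ct <- cos(a$theta); st <- sin(a$theta)
  rigid2d(a$theta + b$theta,
          ct * b$tx - st * b$ty + a$tx,
          st * b$tx + ct * b$ty + a$ty,
          a$dz + b$dz)
}

#' Invert a rigid transform
#' @param tr a [rigid2d()].
#' @return the inverse transform.
#' @export
invert_rigid <- function(tr) {
  ct <- cos(tr$theta); st <- sin(tr$theta)
  rigid2d(-tr$theta, -(ct * tr$tx + st * tr$ty),
          -(-st * tr$tx + ct * tr$ty), -tr$dz)
}

#' Least-squares rigid transform from control points
#'
#' Estimates the rotation + translation (no scale) mapping `src` onto `dst`
#' by the closed-form orthogonal-Procrustes (Kabsch) solution, as used for
#' coarse registration from surveyed reference poles.
#'
#' @param src,dst data frames or matrices with columns `x`, `y`; equal row
#'   counts >= 2.
#' @return a [rigid2d()] with attributes `rms` (residual root-mean-square,
#'   m) and `residuals`.
#' @export
rigid_from_control_points <- function(src, dst) {
  src <- as.matrix(as.data.frame(src)[, c("x", "y")])
  dst <- as.matrix(as.data.frame(dst)[, c("x", "y")])
  if (nrow(src) != nrow(dst) || nrow(src) < 2)
    stop("need equal counts of at least 2 control points")
  cs <- colMeans(src); cd <- colMeans(dst)
  s0 <- sweep(src, 2, cs); d0 <- sweep(dst, 2, cd)
  if (max(abs(s0)) < 1e-12 || max(abs(d0)) < 1e-12)
    stop("degenerate configuration: control points are coincident")
  H <- crossprod(s0, d0)
  sv <- svd(H)
  R <- sv$v %*% diag(c(1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  theta <- atan2(R[2, 1], R[1, 1])
  t <- unname(cd - as.numeric(R %*% cs))
  tr <- rigid2d(theta, t[1], t[2])
  res <- apply_rigid(tr, src) - dst
  attr(tr, "residuals") <- res
  attr(tr, "rms") <- sqrt(mean(rowSums(res^2)))
  tr
}

# Optimal one-to-one assignment minimizing total cost (Jonker-Volgenant
# style shortest augmenting paths). cost: n x m matrix, n <= m is not
# required (the matrix is transposed internally when n > m). Returns, for
# each row, the assigned column (NA when the row ends on a forbidden cell).
solve_assignment <- function(cost, forbidden = Inf) {
  big <- max(cost[is.finite(cost)], 0) * (nrow(cost) + ncol(cost) + 1) + 1
  cost[!is.finite(cost)] <- big
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) {
    cost <- t(cost)
    transposed <- TRUE
  }
  n <- nrow(cost); m <- ncol(cost)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1) # p[j+1]: row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- -1
      for (j in seq_len(m)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) {
          minv[j + 1] <- cur
          way[j + 1] <- j0
        }
        if (minv[j + 1] < delta) {
          delta <- minv[j + 1]
          j1 <- j
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign_row <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign_row[p[j + 1]] <- j
  # assignments that land on forbidden (big) cells are no matches
  for (i in seq_len(n))
    if (!is.na(assign_row[i]) && cost[i, assign_row[i]] >= big)
      assign_row[i] <- NA_integer_
  if (!transposed) return(assign_row)
  out <- rep(NA_integer_, m)
  for (i in seq_len(n))
    if (!is.na(assign_row[i])) out[assign_row[i]] <- i
  out
}

#' Fine co-registration by tree-pattern matching
#'
#' Refines an initial rigid transform by alternating (a) an optimal
#' one-to-one assignment of BLS trunk positions to ULS treetop positions,
#' restricted to pairs closer than `max_pair_dist` under the current
#' transform, and (b) re-estimation of the rigid transform from the matched
#' pairs; iteration stops when the transform update moves the trunks by
#' less than `tol` or after `max_iter` rounds.
#'
#' @param uls_trees data frame of treetop positions (`x`, `y`, optional
#'   `id`).
#' @param bls_trunks data frame of trunk positions in the BLS frame (`x`,
#'   `y`, optional `id`).
#' @param init initial [rigid2d()] (e.g. from
#'   [rigid_from_control_points()]).
#' @param max_pair_dist gating distance for candidate pairs, m.
#' @param max_iter maximum refinement rounds.
#' @param tol convergence tolerance on the induced point motion, m.
#' @return list with `transform` (BLS frame -> ULS frame), `matches` (data
#'   frame `uls_id`, `bls_id`, `dist` in m after alignment), `iterations`.
#' @export
refine_by_tree_matching <- function(uls_trees, bls_trunks,
                                    init = rigid2d(),
                                    max_pair_dist = 2, max_iter = 50,
                                    tol = 1e-6) {
  if (nrow(uls_trees) < 3 || nrow(bls_trunks) < 3)
    stop("need at least 3 trees on each side")
  uid <- if ("id" %in% names(uls_trees)) uls_trees$id
         else seq_len(nrow(uls_trees))
  bid <- if ("id" %in% names(bls_trunks)) bls_trunks$id
         else seq_len(nrow(bls_trunks))
  u_xy <- as.matrix(uls_trees[, c("x", "y")])
  b_xy <- as.matrix(bls_trunks[, c("x", "y")])
  tr <- init
  it <- 0
  repeat {
    it <- it + 1
    b_cur <- apply_rigid(tr, b_xy)
    dx <- outer(b_cur[, 1], u_xy[, 1], "-")
    dy <- outer(b_cur[, 2], u_xy[, 2], "-")
    dist <- sqrt(dx^2 + dy^2)
    cost <- dist
    cost[dist > max_pair_dist] <- Inf
    asg <- solve_assignment(cost)
    matched <- which(!is.na(asg))
    if (length(matched) < 3)
      stop("tree-pattern matching failed: only ", length(matched),
           " pair(s) within ", max_pair_dist,
           " m; check the initial transform")
    new_tr <- rigid_from_control_points(
      data.frame(x = b_xy[matched, 1], y = b_xy[matched, 2]),
      data.frame(x = u_xy[asg[matched], 1], y = u_xy[asg[matched], 2]))
    new_tr$dz <- tr$dz
    shift <- max(sqrt(rowSums(
      (apply_rigid(new_tr, b_xy) - apply_rigid(tr, b_xy))^2)))
    tr <- new_tr
    if (shift < tol || it >= max_iter) break
  }
  b_fin <- apply_rigid(tr, b_xy)
  dist <- sqrt((b_fin[matched, 1] - u_xy[asg[matched], 1])^2 +
               (b_fin[matched, 2] - u_xy[asg[matched], 2])^2)
  matches <- data.frame(uls_id = uid[asg[matched]], bls_id = bid[matched],
                        dist = dist)
  list(transform = tr, matches = matches, iterations = it)
}

#' Mean registration error of a match set
#'
#' The arithmetic mean of the horizontal treetop-to-trunk distances after
#' alignment, reported in centimeters.
#'
#' @param matches the `matches` data frame of [refine_by_tree_matching()]
#'   (column `dist`, m), or a numeric vector of distances in m.
#' @return mean distance, cm.
#' @export
#' @examples
#' registration_error(c(0.5, 1.5)) # 100 cm
registration_error <- function(matches) {
  d <- if (is.data.frame(matches)) matches$dist else matches
  if (length(d) == 0) stop("no matches")
  mean(d) * 100
}
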