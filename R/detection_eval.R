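#' Round half-up
#'
#' Plain decimal rounding where a final 5 always rounds away from zero,
#' matching how the detection tables report ratios (R's `round()` rounds
#' half to even).
#'
#' @param x non-negative numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-12) / p
}

#' Match detected trees to a reference tree list
#'
#' A detection is correct when it falls inside the crown of a reference
#' tree: candidate pairs are all (detection, reference) pairs whose
#' horizontal distance is at most that reference's crown radius, and they
#' are matched one-to-one greedily in ascending distance order (ties broken
#' by detection index). Unmatched detections are commissions, unmatched
#' references omissions.
#'
#' @param detected data frame with columns `x`, `y` (detected positions).
#' @param reference data frame with columns `x`, `y`, `crown_radius` (m).
#' @return list with counts `Nt`, `No`, `Nc` and a `pairs` data frame
#'   (`det`, `ref`, `dist`).
#' @export
match_detections <- function(detected, reference) {
  nd <- nrow(detected)
  nr <- nrow(reference)
  if (nr > 0 && (!("crown_radius" %in% names(reference)) ||
                 any(reference$crown_radius <= 0)))
    stop("reference requires positive crown_radius")
  if (nr == 0 || nd == 0) {
    return(list(Nt = 0L, No = nr, Nc = nd,
                pairs = data.frame(det = integer(), ref = integer(),
                                   dist = numeric())))
  }
  dx <- outer(detected$x, reference$x, "-")
  dy <- outer(detected$y, reference$y, "-")
  dist <- sqrt(dx^2 + dy^2)
  ok <- dist <= matrix(reference$crown_radius, nd, nr, byrow = TRUE)
  cand <- which(ok, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(list(Nt = 0L, No = nr, Nc = nd,
                pairs = data.frame(det = integer(), ref = integer(),
                                   dist = numeric())))
  }
  d <- dist[cand]
  ord <- order(d, cand[, 1], cand[, 2])
  used_d <- logical(nd)
  used_r <- logical(nr)
  pd <- integer(0); pr <- integer(0); pv <- numeric(0)
  for (i in ord) {
    di <- cand[i, 1]; ri <- cand[i, 2]
    if (used_d[di] || used_r[ri]) next
    used_d[di] <- TRUE; used_r[ri] <- TRUE
    pd <- c(pd, di); pr <- c(pr, ri); pv <- c(pv, dist[di, ri])
  }
  list(Nt = length(pd), No = as.integer(nr - length(pd)),
       Nc = as.integer(nd - length(pd)),
       pairs = data.frame(det = pd, ref = pr, dist = pv))
}

#' Tree-detection accuracy metrics
#'
#' Recall \eqn{r = N_t/(N_t+N_o)} (detection rate), precision
#' \eqn{p = N_t/(N_t+N_c)}, and overall accuracy
#' \eqn{F = 2rp/(r+p)}, the harmonic mean of the two. Reported values are
#' rounded half-up to two decimals (exact values are kept alongside).
#'
#' @param Nt matched detections; `No` omitted references; `Nc` commissions.
#' @param No,Nc see above.
#' @return a `detection_metrics` list: `Nt`, `No`, `Nc`, rounded `r`, `p`,
#'   `F`, and unrounded `r_exact`, `p_exact`, `F_exact`.
#' @export
#' @examples
#' detection_metrics(25, 2, 4) # r 0.93, p 0.86, F 0.89
detection_metrics <- function(Nt, No, Nc) {
  if (Nt + No <= 0 || Nt + Nc <= 0)
    stop("metrics undefined: need Nt+No > 0 and Nt+Nc > 0")
  r <- Nt / (Nt + No)
  p <- Nt / (Nt + Nc)
  F <- 2 * r * p / (r + p)
  out <- list(Nt = Nt, No = No, Nc = Nc,
              r = round_half_up(r), p = round_half_up(p),
              F = round_half_up(F),
              r_exact = r, p_exact = p, F_exact = F)
  class(out) <- "detection_metrics"
  out
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("Nt=%d No=%d Nc=%d  r=%.2f p=%.2f F=%.2f\n",
              x$Nt, x$No, x$Nc, x$r, x$p, x$F))
  invisible(x)
}

#' Species-level overall accuracy
#'
#' The arithmetic mean of the plot-level overall accuracies (each already
#' rounded to two decimals), rounded half-up to two decimals — the
#' convention under which the species columns of the published detection
#' tables are reproducible from their counts.
#'
#' @param plot_metrics a list of [detection_metrics()] objects, or a numeric
#'   vector of plot-level `F` values.
#' @return species mean overall accuracy (2 decimals).
#' @export
species_summary <- function(plot_metrics) {
  f <- if (is.numeric(plot_metrics)) plot_metrics
       else vapply(plot_metrics, function(m) m$F, numeric(1))
  if (length(f) == 0) stop("need at least one plot")
  round_half_up(mean(round_half_up(f)))
}

#' Regression accuracy statistics
#'
#' \eqn{R^2 = 1 - SSE/SST}, mean absolute error, root-mean-square error, and
#' the relative RMSE in percent of the observed mean.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2).
#' @return a list with `R2`, `MAE`, `RMSE`, `rRMSE` (percent).
#' @export
regression_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("observed and predicted must have equal length >= 2")
  if (mean(observed) == 0) stop("rRMSE undefined: mean(observed) is zero")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("R2 undefined: observed values have zero variance")
  e <- observed - predicted
  rmse <- sqrt(mean(e^2))
  list(R2 = 1 - sum(e^2) / sst,
       MAE = mean(abs(e)),
       RMSE = rmse,
       rRMSE = 100 * rmse / mean(observed))
}
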