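#' Taper model registry
#'
#' Five classical stem taper equations, all expressed as
#' \eqn{d^2 = f(D, H, h)} with the stem diameter \eqn{d} (cm) at height
#' \eqn{h} (m) along the trunk, breast-height diameter \eqn{D} (cm) and
#' total height \eqn{H} (m):
#'
#' * `M1`: \eqn{d^2 = D^{b_0} (H/(H-h))^{a_2 + a_3 D/H}} — the
#'   variable-exponent form; the two size exponents are only identifiable as
#'   their sum, fitted as the single parameter \eqn{b_0}.
#' * `M2`: \eqn{d^2 = a_0 D^{a_1} (H-h)^{a_2} / H^{a_3}} — the modified
#'   Schumacher form.
#' * `M3`: \eqn{d^2 = a_0 D ((H-h)/(H-1.3))^{a_1}}.
#' * `M4`: \eqn{d^2 = D^2 ((H-h)/(H-1.3))^{a_0}} — anchored so that
#'   \eqn{d(1.3) = D} for any coefficient.
#' * `M5`: \eqn{d^2 = D^2 (a_0 + a_1 (H-h)/h)}.
#'
#' @return a named list of model descriptors (`npar`, parameter names,
#'   default initial values, the \eqn{d^2} function, and an analytic volume
#'   integral where one exists).
#' @export
taper_models <- function() {
  list(
    M1 = list(
      npar = 3L, par_names = c("b0", "a2", "a3"), init = c(2, -1, 0.1),
      d2 = function(a, D, H, h) D^(a[1]) * (H / (H - h))^(a[2] + a[3] * D / H)
    ),
    M2 = list(
      npar = 4L, par_names = c("a0", "a1", "a2", "a3"), init = c(1, 1, 1, 1),
      d2 = function(a, D, H, h) a[1] * D^a[2] * (H - h)^a[3] / H^a[4],
      # K * integral_0^H d^2 dh  = K a0 D^a1 H^(a2+1-a3) / (a2+1)
      volume = function(a, D, H, K) K * a[1] * D^a[2] * H^(a[3] + 1 - a[4]) /
        (a[3] + 1)
    ),
    M3 = list(
      npar = 2L, par_names = c("a0", "a1"), init = c(1, 1),
      d2 = function(a, D, H, h) a[1] * D * ((H - h) / (H - 1.3))^a[2]
    ),
    M4 = list(
      npar = 1L, par_names = "a0", init = 1,
      d2 = function(a, D, H, h) D^2 * ((H - h) / (H - 1.3))^a[1],
      volume = function(a, D, H, K) K * D^2 * H^(a[1] + 1) /
        ((a[1] + 1) * (H - 1.3)^a[1])
    ),
    M5 = list(
      npar = 2L, par_names = c("a0", "a1"), init = c(1, 0.5),
      d2 = function(a, D, H, h) D^2 * (a[1] + a[2] * (H - h) / h)
    )
  )
}

get_taper_model <- function(model) {
  reg <- taper_models()
  if (!model %in% names(reg))
    stop("unknown taper model '", model, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[model]]
}

#' Evaluate a taper equation
#'
#' Returns the stem diameter \eqn{d} (cm) predicted at height `h` along the
#' trunk. Vectorized over `D`, `H` and `h`.
#'
#' @param model a model id (`"M1"`..`"M5"`) or a [fit_taper()] result.
#' @param D breast-height diameter, cm.
#' @param H total tree height, m.
#' @param h height along the trunk, m, with `0 <= h < H`.
#' @param coefficients coefficient vector (ignored when `model` is a fit).
#' @return predicted diameter(s), cm.
#' @export
#' @examples
#' eval_taper("M4", D = 30, H = 25, h = 1.3, coefficients = 2) # exactly 30
eval_taper <- function(model, D, H, h, coefficients = NULL) {
  if (inherits(model, "taper_fit")) {
    coefficients <- model$coefficients
    model <- model$model
  }
  m <- get_taper_model(model)
  if (length(coefficients) != m$npar)
    stop("model ", model, " needs ", m$npar, " coefficients")
  if (any(h < 0) || any(h >= H))
    stop("h must satisfy 0 <= h < H")
  if (any(D <= 0) || any(H <= 1.3)) stop("require D > 0 and H > 1.3")
  d2 <- m$d2(unname(coefficients), D, H, h)
  if (any(!is.finite(d2)) || any(d2 < 0))
    stop("taper equation evaluates to a negative or non-finite d^2 ",
         "under these coefficients")
  unname(sqrt(d2))
}

# guarded evaluator used inside the optimizer: negative/invalid d^2 is
# clamped to zero instead of erroring so LM can move through bad regions
eval_taper_guarded <- function(model_fn, a, D, H, h) {
  d2 <- model_fn(a, D, H, h)
  d2[!is.finite(d2) | d2 < 0] <- 0
  sqrt(d2)
}

#' Fit a taper equation by Levenberg-Marquardt
#'
#' Minimizes the sum of squared residuals on the diameter scale (cm),
#' \eqn{\sum (d_{obs} - d(D, H, h; a))^2}, with the Levenberg-Marquardt
#' algorithm. Standard errors come from the Gauss-Newton covariance
#' \eqn{\hat\sigma^2 (J^T J)^{-1}} with the Jacobian taken by central
#' differences at the solution; 95% confidence intervals use the t
#' distribution with \eqn{n - k} degrees of freedom.
#'
#' @param samples data frame with columns `D` (cm), `H` (m), `h` (m),
#'   `d` (cm); one row per diameter-height observation.
#' @param model model id, see [taper_models()].
#' @param init optional initial coefficient vector.
#' @param tol convergence tolerance on the parameter update.
#' @param max_iter maximum LM iterations.
#' @return an object of class `taper_fit`: coefficients, `se`, `ci_lower`,
#'   `ci_upper`, fit statistics ([regression_metrics()] on `d`), `n`.
#' @export
fit_taper <- function(samples, model = "M2", init = NULL, tol = 1e-10,
                      max_iter = 200) {
  m <- get_taper_model(model)
  req <- c("D", "H", "h", "d")
  if (!all(req %in% names(samples)))
    stop("samples must have columns D, H, h, d")
  samples <- samples[stats::complete.cases(samples[req]), , drop = FALSE]
  n <- nrow(samples)
  k <- m$npar
  if (n < k + 1)
    stop("need at least ", k + 1, " samples to fit ", model)
  if (any(samples$h < 0 | samples$h >= samples$H) || any(samples$D <= 0) ||
      any(samples$H <= 1.3))
    stop("samples outside the taper domain (0 <= h < H, D > 0, H > 1.3)")
  if (is.null(init)) init <- m$init

  D <- samples$D; H <- samples$H; h <- samples$h; dobs <- samples$d
  resid_fn <- function(a) dobs - eval_taper_guarded(m$d2, a, D, H, h)
  ctl <- minpack.lm::nls.lm.control(maxiter = max_iter, ptol = tol,
                                    ftol = .Machine$double.eps)
  fit <- minpack.lm::nls.lm(par = init, fn = resid_fn, control = ctl)
  if (fit$info == 0 || fit$info == 5)
    stop("Levenberg-Marquardt did not converge for model ", model,
         " (info = ", fit$info, "); last iterate: ",
         paste(signif(fit$par, 6), collapse = ", "))
  a_hat <- fit$par

  # central-difference Jacobian of the prediction at the solution
  pred_fn <- function(a) eval_taper_guarded(m$d2, a, D, H, h)
  J <- matrix(0, n, k)
  for (j in seq_len(k)) {
    step <- max(1e-6, abs(a_hat[j]) * 1e-6)
    ap <- a_hat; am <- a_hat
    ap[j] <- ap[j] + step; am[j] <- am[j] - step
    J[, j] <- (pred_fn(ap) - pred_fn(am)) / (2 * step)
  }
  d_pred <- pred_fn(a_hat)
  rss <- sum((dobs - d_pred)^2)
  s2 <- rss / (n - k)
  JtJ <- crossprod(J)
  qrJ <- qr(JtJ)
  if (qrJ$rank < k)
    stop("rank-deficient Jacobian for model ", model,
         "; parameters are not identifiable from these samples")
  covm <- s2 * solve(JtJ)
  se <- sqrt(pmax(diag(covm), 0))
  tcrit <- stats::qt(0.975, df = n - k)

  out <- list(
    model = model,
    coefficients = stats::setNames(a_hat, m$par_names),
    se = stats::setNames(se, m$par_names),
    ci_lower = stats::setNames(a_hat - tcrit * se, m$par_names),
    ci_upper = stats::setNames(a_hat + tcrit * se, m$par_names),
    stats = regression_metrics(dobs, d_pred),
    n = n,
    rss = rss,
    iterations = fit$niter,
    info = fit$info
  )
  class(out) <- "taper_fit"
  out
}

#' @export
print.taper_fit <- function(x, ...) {
  cat("Taper fit:", x$model, " (n =", x$n, ")\n")
  tab <- rbind(Estimate = x$coefficients, `Std. error` = x$se,
               `CI 2.5%` = x$ci_lower, `CI 97.5%` = x$ci_upper)
  print(round(tab, 4))
  cat(sprintf("R2 = %.3f  RMSE = %.3f cm  rRMSE = %.2f%%\n",
              x$stats$R2, x$stats$RMSE, x$stats$rRMSE))
  invisible(x)
}

#' Select the best taper fit
#'
#' Picks the fit with the smallest RMSE; ties are broken by higher R-squared,
#' then by fewer parameters.
#'
#' @param fits a list of [fit_taper()] results on the same samples.
#' @return the selected `taper_fit`.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1)
  rmse <- vapply(fits, function(f) f$stats$RMSE, numeric(1))
  r2 <- vapply(fits, function(f) f$stats$R2, numeric(1))
  np <- vapply(fits, function(f) length(f$coefficients), numeric(1))
  ord <- order(rmse, -r2, np)
  fits[[ord[1]]]
}
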