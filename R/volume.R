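#' Tree volume by integrating a taper equation
#'
#' Stem volume is \eqn{V = K \int_0^H d(h)^2 \, dh} with
#' \eqn{K = \pi/40000}, which converts a diameter in centimeters and a
#' height in meters into cubic meters. Closed forms exist for models `M2`
#' and `M4`; the other models (and the cross-check) use adaptive quadrature
#' at a relative tolerance of 1e-8. Model `M5` has a non-integrable
#' singularity at the stem base whenever its slope coefficient is positive,
#' so only quadrature on a truncated domain would be meaningful for it;
#' requesting its full-stem volume is an error.
#'
#' @param fit a [fit_taper()] result, or a model id combined with
#'   `coefficients`.
#' @param D breast-height diameter, cm.
#' @param H total tree height, m.
#' @param method `"auto"` (analytic where available), `"analytic"`, or
#'   `"quadrature"`.
#' @param coefficients coefficients when `fit` is a model id.
#' @return stem volume, cubic meters.
#' @export
#' @examples
#' # a cylinder: constant d = D, so V = pi * D^2 * H / 40000
#' tree_volume("M5", D = 20, H = 10, coefficients = c(1, 0), method = "quadrature")
tree_volume <- function(fit, D, H, method = c("auto", "analytic",
                                              "quadrature"),
                        coefficients = NULL) {
  method <- match.arg(method)
  if (inherits(fit, "taper_fit")) {
    model <- fit$model
    coefficients <- fit$coefficients
  } else {
    model <- fit
    if (is.null(coefficients)) stop("coefficients required with a model id")
  }
  m <- get_taper_model(model)
  coefficients <- unname(coefficients)
  if (any(D <= 0) || any(H <= 1.3)) stop("require D > 0 and H > 1.3")
  K <- pi / 40000

  if (length(D) > 1 || length(H) > 1) {
    nn <- max(length(D), length(H))
    D <- rep_len(D, nn); H <- rep_len(H, nn)
    return(vapply(seq_len(nn), function(i)
      tree_volume(model, D[i], H[i], method, coefficients), numeric(1)))
  }

  analytic_ok <- !is.null(m$volume)
  if (method == "analytic" && !analytic_ok)
    stop("no closed-form volume for model ", model)
  if (method %in% c("analytic", "auto") && analytic_ok)
    return(m$volume(coefficients, D, H, K))

  integrand <- function(h) m$d2(coefficients, D, H, h)
  probe <- integrand(seq(1e-6, H - 1e-6, length.out = 257))
  if (any(!is.finite(probe)) || any(probe < -1e-9))
    stop("taper integrand is negative or non-finite on [0, H] for model ",
         model, "; volume undefined")
  K * stats::integrate(integrand, 0, H, rel.tol = 1e-8,
                       subdivisions = 500L)$value
}

#' Compile a standard (two-way) volume table
#'
#' Tabulates [tree_volume()] over DBH and height classes, rounded to four
#' decimals, for field use.
#'
#' @param fit a [fit_taper()] result (or model id, with `coefficients`).
#' @param dbh_classes ascending DBH class midpoints, cm.
#' @param height_classes ascending height class midpoints, m (all > 1.3).
#' @param species optional species label stored with the table.
#' @param coefficients coefficients when `fit` is a model id.
#' @return a `volume_table`: matrix of volumes (m^3), DBH classes in rows.
#' @export
build_volume_table <- function(fit, dbh_classes, height_classes,
                               species = NULL, coefficients = NULL) {
  if (is.unsorted(dbh_classes, strictly = TRUE) ||
      is.unsorted(height_classes, strictly = TRUE))
    stop("classes must be strictly ascending")
  if (any(height_classes <= 1.3)) stop("height classes must exceed 1.3 m")
  vols <- outer(dbh_classes, height_classes,
                Vectorize(function(D, H)
                  tree_volume(fit, D, H, coefficients = coefficients)))
  vols <- round(vols, 4)
  dimnames(vols) <- list(DBH_cm = format(dbh_classes),
                         H_m = format(height_classes))
  structure(vols, class = c("volume_table", class(vols)),
            species = species,
            model = if (inherits(fit, "taper_fit")) fit$model else fit)
}

#' Plot and stand volume from standard trees
#'
#' Computes the quadratic mean diameter \eqn{D_g = \sqrt{\bar{D^2}}} and the
#' mean height \eqn{H_g}, selects the "standard trees" whose DBH and height
#' both lie within `(1 - tolerance, 1 + tolerance)` of \eqn{D_g} and
#' \eqn{H_g}, and expands their integrated volumes to the plot by the
#' basal-area ratio
#' \eqn{M = G \sum V_i / \sum g_i}, with \eqn{g_i = \pi (D_i/200)^2} the
#' basal area (m^2) of standard tree i and \eqn{G} the plot total. The stand
#' volume is `M` scaled to a hectare.
#'
#' @param trees data frame with per-tree columns `D` (cm) and `H` (m).
#' @param fit taper fit used for the standard trees' volumes.
#' @param plot_area plot area, square meters.
#' @param tolerance relative half-width of the standard-tree window.
#' @return a `plot_summary` list: `Dg`, `Hg`, `standard_ids`, `G`, `M`,
#'   `stand_volume` (m^3/ha), `plot_area_ha`.
#' @export
stand_volume <- function(trees, fit, plot_area = 900, tolerance = 0.05) {
  stopifnot(nrow(trees) >= 1, all(c("D", "H") %in% names(trees)))
  Dg <- sqrt(mean(trees$D^2))
  Hg <- mean(trees$H)
  std <- which(trees$D >= Dg * (1 - tolerance) &
               trees$D <= Dg * (1 + tolerance) &
               trees$H >= Hg * (1 - tolerance) &
               trees$H <= Hg * (1 + tolerance))
  if (length(std) == 0)
    stop("no standard tree within ", tolerance * 100,
         "% of Dg = ", round(Dg, 1), " cm and Hg = ", round(Hg, 1),
         " m; widen the tolerance")
  g <- pi * (trees$D / 200)^2
  G <- sum(g)
  V_std <- tree_volume(fit, trees$D[std], trees$H[std])
  M <- sum(V_std) / sum(g[std]) * G
  out <- list(Dg = Dg, Hg = Hg, standard_ids = std, n_standard = length(std),
              G = G, M = M, plot_area_ha = plot_area / 10000,
              stand_volume = M / (plot_area / 10000))
  class(out) <- "plot_summary"
  out
}

#' @export
print.plot_summary <- function(x, ...) {
  cat(sprintf(
    "Plot summary: Dg = %.2f cm, Hg = %.2f m, %d standard tree(s)\n",
    x$Dg, x$Hg, x$n_standard))
  cat(sprintf("G = %.3f m2, M = %.2f m3, stand volume = %.2f m3/ha\n",
              x$G, x$M, x$stand_volume))
  invisible(x)
}
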