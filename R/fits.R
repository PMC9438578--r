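#' Fit an origin-anchored exponential to a stress-strain curve
#'
#' Least-squares fit of `sigma(eps) = a (exp(b eps) - 1)`, the standard
#' two-parameter convex model for collagen-recruiting soft tissue that
#' passes through the origin. Starting values are deterministic: `b0` is the
#' log-stress slope over the upper third of the strain range (where the
#' exponential dominates) and `a0` places the curve through the last point.
#'
#' @param curve a [stress_strain_curve()] with at least 5 points.
#' @param control passed to [minpack.lm::nlsLM()].
#' @return object of class `expfit` with components `a` (Pa), `b`, `r2`,
#'   the underlying `nls` fit and the data; supports `coef()`, `predict()`,
#'   `residuals()`, `summary()`, `plot()`.
#' @examples
#' cur <- sim_stress_strain(a = 20e3, b = 6, n_points = 30)
#' fit <- fit_exponential(cur)
#' coef(fit)
#' @export
fit_exponential <- function(curve, control = minpack.lm::nls.lm.control(maxiter = 200)) {
  if (!inherits(curve, "stress_strain_curve"))
    abort_domain("'curve' must be a stress_strain_curve")
  eps <- curve$strain; sig <- curve$stress
  if (length(eps) < 5L) abort_domain("need at least 5 points to fit")

  upper <- eps >= min(eps) + 2 / 3 * diff(range(eps)) & sig > 0
  b0 <- if (sum(upper) >= 2) {
    stats::coef(stats::lm(log(sig[upper]) ~ eps[upper]))[[2]]
  } else 1
  if (!is.finite(b0) || b0 <= 0) b0 <- 1
  a0 <- sig[length(sig)] / max(expm1(b0 * eps[length(eps)]), 1e-12)
  if (!is.finite(a0) || a0 <= 0) a0 <- max(sig) / 2

  fit <- tryCatch(
    minpack.lm::nlsLM(sig ~ a * (exp(b * eps) - 1),
                      start = list(a = a0, b = b0),
                      lower = c(a = 1e-12, b = 1e-12),
                      control = control),
    error = function(e) abort_fit(
      sprintf("exponential fit did not converge: %s (start a0 = %.4g, b0 = %.4g)",
              conditionMessage(e), a0, b0),
      data = list(a0 = a0, b0 = b0)))
  cf <- stats::coef(fit)
  res <- sig - stats::predict(fit)
  r2 <- 1 - sum(res^2) / sum((sig - mean(sig))^2)
  structure(list(a = cf[["a"]], b = cf[["b"]], r2 = r2,
                 fit = fit, curve = curve),
            class = "expfit")
}

#' @export
print.expfit <- function(x, ...) {
  cat(sprintf("Exponential stress-strain fit: sigma = a (exp(b eps) - 1)\n"))
  cat(sprintf("  a = %.6g Pa, b = %.6g, R^2 = %.6f\n", x$a, x$b, x$r2))
  invisible(x)
}

#' @export
coef.expfit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.expfit <- function(object, strain = NULL, ...) {
  if (is.null(strain)) strain <- object$curve$strain
  object$a * (exp(object$b * strain) - 1)
}

#' @export
residuals.expfit <- function(object, ...) {
  object$curve$stress - predict(object)
}

#' @export
summary.expfit <- function(object, ...) {
  s <- summary(object$fit)
  s$r2 <- object$r2
  s
}

#' @export
plot.expfit <- function(x, ...) {
  plot(x$curve, ...)
  eg <- seq(min(x$curve$strain), max(x$curve$strain), length.out = 200)
  graphics::lines(eg, predict(x, eg) / 1000, col = 2)
}

#' Linear approximation of a stress-strain curve over a window
#'
#' Either the chord connecting the stresses interpolated at the window
#' endpoints (the dashed-line construction used to linearise the
#' physiological pressure range), or an ordinary least-squares line through
#' the points inside the window.
#'
#' @param curve a [stress_strain_curve()].
#' @param window `c(eps_lo, eps_hi)` inside the curve's strain domain.
#' @param method `"chord"` (default) or `"least_squares"`.
#' @return object of class `linfit` with `E_lin` (Pa), `intercept` (Pa),
#'   `window`, `method`.
#' @export
fit_linear_window <- function(curve, window, method = c("chord", "least_squares")) {
  method <- match.arg(method)
  if (!inherits(curve, "stress_strain_curve"))
    abort_domain("'curve' must be a stress_strain_curve")
  lo <- window[1]; hi <- window[2]
  if (!(lo < hi)) abort_domain("empty window: eps_lo must be < eps_hi")
  if (lo < min(curve$strain) || hi > max(curve$strain))
    abort_domain("window outside the curve's strain domain")
  if (method == "chord") {
    s_lo <- stats::approx(curve$strain, curve$stress, xout = lo)$y
    s_hi <- stats::approx(curve$strain, curve$stress, xout = hi)$y
    E_lin <- (s_hi - s_lo) / (hi - lo)
    intercept <- s_lo - E_lin * lo
  } else {
    inside <- curve$strain >= lo & curve$strain <= hi
    if (sum(inside) < 2L) abort_domain("fewer than 2 points inside the window")
    cf <- stats::coef(stats::lm(curve$stress[inside] ~ curve$strain[inside]))
    intercept <- cf[[1]]; E_lin <- cf[[2]]
  }
  structure(list(E_lin = E_lin, intercept = intercept,
                 window = c(lo, hi), method = method),
            class = "linfit")
}

#' @export
print.linfit <- function(x, ...) {
  cat(sprintf("Linear window fit (%s) on [%.4g, %.4g]: E_lin = %.6g Pa, intercept = %.4g Pa\n",
              x$method, x$window[1], x$window[2], x$E_lin, x$intercept))
  invisible(x)
}

#' @export
coef.linfit <- function(object, ...) {
  c(intercept = object$intercept, E_lin = object$E_lin)
}

#' @export
predict.linfit <- function(object, strain, ...) {
  object$intercept + object$E_lin * strain
}

#' Strain energy density by integration of a stress-strain relation
#'
#' The area under the stress-strain relation between two strains: composite
#' trapezoid on tabulated curves (window endpoints interpolated onto the
#' grid), exact antiderivative `a (exp(b eps) - 1)/b - a eps` for
#' exponential fits.
#'
#' @param x a [stress_strain_curve()] or [expfit()] object.
#' @param lower,upper integration bounds (strains).
#' @param ... unused.
#' @return energy density, J/m^3.
#' @export
strain_energy_integral <- function(x, lower, upper, ...) {
  UseMethod("strain_energy_integral")
}

#' @export
strain_energy_integral.stress_strain_curve <- function(x, lower, upper, ...) {
  if (lower > upper) abort_domain("lower bound above upper bound")
  if (lower < min(x$strain) || upper > max(x$strain))
    abort_domain("integration bounds outside the curve domain")
  if (lower == upper) return(0)
  inside <- x$strain > lower & x$strain < upper
  eps <- c(lower, x$strain[inside], upper)
  sig <- c(stats::approx(x$strain, x$stress, xout = lower)$y,
           x$stress[inside],
           stats::approx(x$strain, x$stress, xout = upper)$y)
  sum(diff(eps) * (utils::head(sig, -1) + utils::tail(sig, -1)) / 2)
}

#' @export
strain_energy_integral.expfit <- function(x, lower, upper, ...) {
  if (lower > upper) abort_domain("lower bound above upper bound")
  anti <- function(e) x$a * (exp(x$b * e) - 1) / x$b - x$a * e
  anti(upper) - anti(lower)
}

#' Percent difference between the linear and the integral strain energy
#'
#' Compares the stored energy over a strain window estimated two ways, both
#' measured above the baseline stress at the lower endpoint (the same
#' convention as the diastole-to-systole energy increment, which is a
#' triangle above the diastolic stress): the chord (linear) estimate
#' `(sigma_hi - sigma_lo)(eps_hi - eps_lo)/2`, and the curve integral
#' `int sigma d eps - sigma_lo (eps_hi - eps_lo)`. Returns
#' `100 (linear - integral)/integral`; positive for convex curves, 0 for a
#' straight line.
#'
#' @param curve a [stress_strain_curve()].
#' @param window `c(eps_lo, eps_hi)`.
#' @return percent difference.
#' @export
linear_vs_integral_ratio <- function(curve, window) {
  lo <- window[1]; hi <- window[2]
  if (!(lo < hi)) abort_domain("empty window")
  s_lo <- stats::approx(curve$strain, curve$stress, xout = lo)$y
  s_hi <- stats::approx(curve$strain, curve$stress, xout = hi)$y
  lin <- (s_hi - s_lo) * (hi - lo) / 2
  int <- strain_energy_integral(curve, lo, hi) - s_lo * (hi - lo)
  if (int == 0) abort_domain("integral strain energy is zero over the window")
  100 * (lin - int) / int
}

#' Expansion constraint coefficient from arterial compliance
#'
#' Inverts the segment compliance implied by the constrained area strain:
#' integrating `dA/dp = phi A D / (E h)` over a segment of length `L` gives
#' `C = L A phi D / (E h)`, so `phi = C E h / (L A D)`.
#'
#' @param C volumetric compliance, m^3/Pa.
#' @param E circumferential modulus, Pa.
#' @param h wall thickness, m.
#' @param A lumen area, m^2.
#' @param D inner diameter, m.
#' @param L segment length, m.
#' @return dimensionless phi.
#' @export
phi_from_compliance <- function(C, E, h, A, D, L) {
  for (nm in c("C", "E", "h", "A", "D", "L"))
    stopifnot_scalar(get(nm), nm)
  C * E * h / (L * A * D)
}

#' @rdname phi_from_compliance
#' @param phi expansion constraint coefficient.
#' @export
compliance_from_phi <- function(phi, E, h, A, D, L) {
  phi * L * A * D / (E * h)
}
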