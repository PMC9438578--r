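#' Systolic/diastolic pressure state
#'
#' Bundles systolic and diastolic pressure and the derived mean and pulse
#' pressures. The mean uses the clinical weighting p = (2 p_d + p_s)/3,
#' reflecting that the heart spends about two thirds of the cycle in diastole.
#'
#' @param p_s systolic pressure.
#' @param p_d diastolic pressure.
#' @param unit pressure unit of the inputs (default `"mmHg"`).
#' @return an object of class `pressure_state` with fields `p_s`, `p_d`,
#'   `p_mean`, `pp`, all in Pa.
#' @examples
#' ps <- pressure_state(120, 80)
#' pressure_as(ps$p_mean, "mmHg")   # 93.33 mmHg
#' @export
pressure_state <- function(p_s, p_d, unit = "mmHg") {
  stopifnot_scalar(p_s, "p_s")
  stopifnot_scalar(p_d, "p_d")
  p_s <- convert_pressure(p_s, unit)
  p_d <- convert_pressure(p_d, unit)
  if (p_s < p_d)
    abort_domain(sprintf("systolic pressure (%g Pa) below diastolic (%g Pa)", p_s, p_d))
  structure(
    list(p_s = p_s, p_d = p_d,
         p_mean = (2 * p_d + p_s) / 3,
         pp = p_s - p_d),
    class = "pressure_state")
}

#' @export
print.pressure_state <- function(x, ...) {
  cat(sprintf("Pressure state: %.4g/%.4g mmHg (mean %.4g, pulse %.4g mmHg)\n",
              pressure_as(x$p_s, "mmHg"), pressure_as(x$p_d, "mmHg"),
              pressure_as(x$p_mean, "mmHg"), pressure_as(x$pp, "mmHg")))
  invisible(x)
}

#' Mean blood pressure of a pressure state
#'
#' @param ps a [pressure_state()].
#' @return mean pressure in Pa, `(2 p_d + p_s)/3`.
#' @export
mean_pressure <- function(ps) {
  if (!inherits(ps, "pressure_state")) abort_domain("'ps' must be a pressure_state")
  (2 * ps$p_d + ps$p_s) / 3
}

#' Aortic wall geometry
#'
#' Reference (unstressed) outer diameter and wall thickness plus the
#' diastolic and systolic outer diameters and thicknesses. When the
#' state thicknesses are not given they are filled in from wall
#' incompressibility, `h_i * D_i = h * D_o` (constant wall cross-section of
#' the thin ring). The lumen flow area `A_f` is built from the reference
#' inner diameter `D_o - 2 h`.
#'
#' @param D_o reference (unstressed) outer diameter.
#' @param h reference wall thickness.
#' @param D_d,D_s diastolic and systolic outer diameters (default: reference).
#' @param h_d,h_s diastolic and systolic wall thicknesses (default: from
#'   incompressibility).
#' @param unit length unit of all inputs (default `"mm"`).
#' @return object of class `vessel_geometry`; all lengths in m, plus
#'   `D_in` (reference inner diameter) and `A_f` (lumen area, m^2).
#' @examples
#' vessel_geometry(D_o = 32, h = 1.46)
#' @export
vessel_geometry <- function(D_o, h, D_d = NULL, D_s = NULL,
                            h_d = NULL, h_s = NULL, unit = "mm") {
  D_o <- convert_length(stopifnot_scalar(D_o, "D_o"), unit)
  h   <- convert_length(stopifnot_scalar(h, "h"), unit)
  D_d <- if (is.null(D_d)) D_o else convert_length(stopifnot_scalar(D_d, "D_d"), unit)
  D_s <- if (is.null(D_s)) D_o else convert_length(stopifnot_scalar(D_s, "D_s"), unit)
  h_d <- if (is.null(h_d)) h * D_o / D_d else convert_length(stopifnot_scalar(h_d, "h_d"), unit)
  h_s <- if (is.null(h_s)) h * D_o / D_s else convert_length(stopifnot_scalar(h_s, "h_s"), unit)
  if (D_s < D_d)
    abort_domain(sprintf("systolic outer diameter (%g m) below diastolic (%g m)", D_s, D_d))
  if (D_o <= 2 * h)
    abort_domain("reference lumen is closed: D_o <= 2 h")
  if (D_o / h < 10)
    warn_model(sprintf("D_o/h = %.2f < 10: thin-walled (Laplace) approximation is doubtful", D_o / h))
  D_in <- D_o - 2 * h
  structure(
    list(D_o = D_o, D_d = D_d, D_s = D_s,
         h = h, h_d = h_d, h_s = h_s,
         D_in = D_in, A_f = pi / 4 * D_in^2),
    class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("Vessel geometry (outer diameters, mm): ref %.3f, dia %.3f, sys %.3f\n",
              1000 * x$D_o, 1000 * x$D_d, 1000 * x$D_s))
  cat(sprintf("  wall (mm): ref %.4f, dia %.4f, sys %.4f;  lumen area %.4g mm^2\n",
              1000 * x$h, 1000 * x$h_d, 1000 * x$h_s, 1e6 * x$A_f))
  invisible(x)
}

#' Distend a reference vessel to a pressure state
#'
#' Builds the diastolic and systolic geometry of a reference vessel by
#' applying the area strain of the constrained wall at each pressure,
#' `eps_A(p) = phi * p * D_in / (E * h)`: `D_i = D_o * sqrt(1 + eps_A(p_i))`,
#' with wall thicknesses from incompressibility. This is the rule used by all
#' worked examples and sweeps, so that a vessel quoted by its unstressed
#' diameter responds consistently to any pressure state.
#'
#' @param D_o reference outer diameter.
#' @param h reference wall thickness.
#' @param material a [wall_material()].
#' @param pressure a [pressure_state()].
#' @param unit length unit for `D_o`, `h`.
#' @return a [vessel_geometry()].
#' @export
distend_geometry <- function(D_o, h, material, pressure, unit = "mm") {
  if (!inherits(material, "wall_material")) abort_domain("'material' must be a wall_material")
  if (!inherits(pressure, "pressure_state")) abort_domain("'pressure' must be a pressure_state")
  ref <- vessel_geometry(D_o = D_o, h = h, unit = unit)
  eps_d <- area_strain(material, pressure$p_d, ref$D_in, ref$h)
  eps_s <- area_strain(material, pressure$p_s, ref$D_in, ref$h)
  vessel_geometry(D_o = ref$D_o, h = ref$h,
                  D_d = ref$D_o * sqrt(1 + eps_d),
                  D_s = ref$D_o * sqrt(1 + eps_s),
                  unit = "m")
}

#' Circumferential wall material
#'
#' @param E circumferential (secant) elastic modulus, Pa.
#' @param phi expansion constraint coefficient in (0, 1]: the fraction of the
#'   free Laplace dilation that the surrounding soft tissue permits.
#' @return object of class `wall_material`.
#' @export
wall_material <- function(E, phi) {
  stopifnot_scalar(E, "E")
  stopifnot_scalar(phi, "phi")
  if (phi > 1) abort_domain(sprintf("phi must be in (0, 1], got %g", phi))
  structure(list(E = E, phi = phi), class = "wall_material")
}

#' @export
print.wall_material <- function(x, ...) {
  cat(sprintf("Wall material: E = %.4g Pa, phi = %.4g\n", x$E, x$phi))
  invisible(x)
}

#' Blood properties
#'
#' Density, viscosity, the laminar kinetic-energy correction factor
#' (`eta = 2`) and dissipation coefficient (`K = 1`), and the per-unit-volume
#' weight `gamma` used by the characteristic-velocity formula.
#'
#' Two `gamma` conventions are supported. The calibrated default,
#' `"kgf"`, expresses weight in kilogram-force per cubic metre so that
#' `gamma` is numerically equal to the density; `"SI"` uses `rho * g`
#' (newton per cubic metre). See `CALIBRATION.md` at the repository root and
#' the methods vignette for how the convention was fixed.
#'
#' @param rho density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @param eta kinetic-energy correction factor (2 for laminar flow).
#' @param K dissipation coefficient (1 for laminar flow).
#' @param g gravitational acceleration, m/s^2.
#' @param gamma per-unit-volume weight; overrides the convention if given.
#' @param convention `"kgf"` (default) or `"SI"`.
#' @return object of class `blood_properties`.
#' @export
blood_properties <- function(rho = 1050, mu = 3.5e-3, eta = 2, K = 1,
                             g = 9.80665, gamma = NULL,
                             convention = c("kgf", "SI")) {
  convention <- match.arg(convention)
  stopifnot_scalar(rho, "rho"); stopifnot_scalar(mu, "mu")
  stopifnot_scalar(eta, "eta"); stopifnot_scalar(K, "K")
  stopifnot_scalar(g, "g")
  if (is.null(gamma)) gamma <- if (convention == "kgf") rho else rho * g
  stopifnot_scalar(gamma, "gamma")
  structure(list(rho = rho, mu = mu, eta = eta, K = K, g = g,
                 gamma = gamma, convention = convention),
            class = "blood_properties")
}

#' @export
print.blood_properties <- function(x, ...) {
  cat(sprintf("Blood: rho = %g kg/m^3, mu = %g Pa s, eta = %g, K = %g, gamma = %g (%s)\n",
              x$rho, x$mu, x$eta, x$K, x$gamma, x$convention))
  invisible(x)
}

#' Cohort-level clinical parameters
#'
#' @param p_s,p_d systolic/diastolic pressure, mmHg (`p_d` may be `NA` for a
#'   subject whose diastolic pressure is to be solved for).
#' @param hr pulse (heart) rate, 1/min.
#' @param compliance volumetric arterial compliance, ml/mmHg.
#' @param label free-text cohort label.
#' @return object of class `cohort_params`; compliance is stored both as
#'   given (`compliance_ml_mmHg`) and in SI (`compliance`, m^3/Pa).
#' @export
cohort_params <- function(p_s, p_d = NA, hr, compliance, label = "") {
  stopifnot_scalar(p_s, "p_s")
  stopifnot_scalar(hr, "hr")
  stopifnot_scalar(compliance, "compliance")
  if (!is.na(p_d)) stopifnot_scalar(p_d, "p_d")
  structure(list(p_s = p_s, p_d = p_d, hr = hr,
                 compliance_ml_mmHg = compliance,
                 compliance = compliance * 1e-6 / MMHG_PA,
                 label = label),
            class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf("Cohort %s: %s/%s mmHg, %.3g bpm, compliance %.3g ml/mmHg\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              format(x$p_s), format(x$p_d), x$hr, x$compliance_ml_mmHg))
  invisible(x)
}
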