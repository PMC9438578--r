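#' Thin-walled (Laplace) hoop stress with tissue constraint
#'
#' `sigma = phi * p * D / (2 h)`. The constraint coefficient `phi` scales the
#' free-wall Laplace stress down to the part actually carried as recoverable
#' circumferential load by the constrained vessel.
#'
#' @param p internal pressure, Pa.
#' @param D outer diameter, m.
#' @param h wall thickness, m.
#' @param phi expansion constraint coefficient.
#' @return stress, Pa.
#' @export
laplace_stress <- function(p, D, h, phi) {
  stopifnot_scalar(D, "D"); stopifnot_scalar(h, "h")
  phi * p * D / (2 * h)
}

#' Secant circumferential modulus from an expansion test
#'
#' `E = D * p / (2 h eps_theta)`: the modulus implied by a relative
#' circumferential strain `eps_theta` measured under pressure `p`.
#'
#' @param D inner diameter, m.
#' @param p pressure, Pa.
#' @param h wall thickness, m.
#' @param eps_theta relative circumferential strain (> 0).
#' @return modulus, Pa.
#' @export
modulus_from_expansion <- function(D, p, h, eps_theta) {
  stopifnot_scalar(D, "D"); stopifnot_scalar(h, "h")
  if (!is.numeric(eps_theta) || length(eps_theta) != 1L || is.na(eps_theta) || eps_theta <= 0)
    abort_domain("eps_theta must be > 0: an undeformed vessel has no finite secant modulus")
  D * p / (2 * h * eps_theta)
}

#' Wall ratio alpha = D/h - 2
#'
#' @param D outer diameter, m.
#' @param h wall thickness, m.
#' @return dimensionless ratio.
#' @export
alpha_ratio <- function(D, h) {
  stopifnot_scalar(D, "D"); stopifnot_scalar(h, "h")
  if (D <= 2 * h) abort_domain("lumen closed: D <= 2 h")
  D / h - 2
}

#' Strain energy density increment from stresses and strains
#'
#' The elastic energy per unit wall volume stored between the diastolic and
#' systolic states under the linear approximation:
#' `delta_u = (sigma_s - sigma_d) (eps_s - eps_d) / 2`.
#'
#' @param sigma_s,sigma_d systolic/diastolic circumferential stress, Pa.
#' @param eps_s,eps_d systolic/diastolic engineering strain.
#' @return energy density, J/m^3 (always >= 0).
#' @export
sedi_linear <- function(sigma_s, sigma_d, eps_s, eps_d) {
  if (sigma_s < sigma_d || eps_s < eps_d)
    abort_domain("systolic stress/strain must not be below diastolic")
  (sigma_s - sigma_d) * (eps_s - eps_d) / 2
}

#' Strain energy density increment from pressures
#'
#' The pressure form `delta_u = phi^2 (alpha_s p_s - alpha_d p_d)^2 / (8 E)`,
#' which expresses the stored energy directly in terms of clinical pressures
#' and the wall ratios `alpha_i = D_i/h_i - 2`.
#'
#' @param material a [wall_material()].
#' @param alpha_s,alpha_d systolic/diastolic wall ratios.
#' @param ps a [pressure_state()].
#' @return energy density, J/m^3.
#' @export
sedi_pressure_form <- function(material, alpha_s, alpha_d, ps) {
  if (!inherits(material, "wall_material")) abort_domain("'material' must be a wall_material")
  if (!inherits(ps, "pressure_state")) abort_domain("'ps' must be a pressure_state")
  if (material$E <= 0) abort_domain("E must be > 0")
  material$phi^2 * (alpha_s * ps$p_s - alpha_d * ps$p_d)^2 / (8 * material$E)
}

#' Constrained area strain of the lumen at a pressure
#'
#' `eps_A(p) = phi * p * D / (E * h)`: the relative increase of the
#' cross-sectional area of the constrained vessel at internal pressure `p`.
#'
#' @param material a [wall_material()].
#' @param p pressure, Pa.
#' @param D inner diameter, m.
#' @param h wall thickness, m.
#' @return dimensionless area strain.
#' @export
area_strain <- function(material, p, D, h) {
  if (!inherits(material, "wall_material")) abort_domain("'material' must be a wall_material")
  stopifnot_scalar(D, "D"); stopifnot_scalar(h, "h")
  material$phi * p * D / (material$E * h)
}

#' Reynolds number of the per-pulse characteristic velocity
#'
#' The characteristic velocity is a flow distance per pulse; it is converted
#' to a velocity in m/s through the pulse frequency (`V * n / 60`) before the
#' Reynolds number `Re = rho v D / mu` is formed. Above `Re = 2100` a warning
#' is issued because the laminar assumption (and `lambda = 64/Re`) fails.
#'
#' @param V_char characteristic velocity, m per pulse.
#' @param n pulse frequency, 1/min.
#' @param D diameter, m.
#' @param mu dynamic viscosity, Pa s.
#' @param rho density, kg/m^3.
#' @return Reynolds number (dimensionless).
#' @export
reynolds_number <- function(V_char, n, D, mu, rho = 1050) {
  stopifnot_scalar(n, "n"); stopifnot_scalar(D, "D")
  stopifnot_scalar(mu, "mu"); stopifnot_scalar(rho, "rho")
  Re <- rho * (V_char * n / 60) * D / mu
  if (!is.na(Re) && Re > RE_LAMINAR_MAX)
    warn_model(sprintf("Re = %.0f exceeds the laminar threshold %d; lambda = 64/Re is not valid",
                       Re, RE_LAMINAR_MAX))
  Re
}

# critical Reynolds number below which aortic flow is treated as laminar
RE_LAMINAR_MAX <- 2100

#' Darcy friction factor for laminar flow
#'
#' @param Re Reynolds number (> 0).
#' @return `64 / Re`.
#' @export
friction_factor <- function(Re) {
  if (!is.numeric(Re) || length(Re) != 1L || is.na(Re) || Re <= 0)
    abort_domain("Re must be > 0")
  if (Re > RE_LAMINAR_MAX)
    warn_model(sprintf("Re = %.0f exceeds the laminar threshold %d", Re, RE_LAMINAR_MAX))
  64 / Re
}

#' Coupling energy dissipation coefficient
#'
#' `beta = 4 E lambda (h_d - h_s) / (D (p_s - p_d) phi)`: the dimensionless
#' coefficient folding wall-shear friction losses into the characteristic
#' velocity. It vanishes when the wall does not thin between diastole and
#' systole; a wall that thickens in systole (h_d < h_s) contradicts
#' incompressibility of an expanding wall and yields a negative beta with a
#' warning.
#'
#' @param material a [wall_material()].
#' @param lam friction loss factor (e.g. `64/Re`).
#' @param geom a [vessel_geometry()].
#' @param ps a [pressure_state()].
#' @return dimensionless beta.
#' @export
beta_coefficient <- function(material, lam, geom, ps) {
  if (!inherits(geom, "vessel_geometry")) abort_domain("'geom' must be a vessel_geometry")
  if (!inherits(ps, "pressure_state")) abort_domain("'ps' must be a pressure_state")
  if (ps$pp <= 0) abort_domain("pulse pressure must be > 0 for beta")
  if (geom$h_d < geom$h_s)
    warn_model("h_d < h_s: wall thickening in systole contradicts incompressibility; beta < 0")
  4 * material$E * lam * (geom$h_d - geom$h_s) / (geom$D_in * ps$pp * material$phi)
}

#' Characteristic per-pulse velocity
#'
#' Solves `V (1 + beta) = phi h (alpha_s p_s - alpha_d p_d) / (D gamma)`
#' for the flow distance per pulse `V`, under one of three treatments of the
#' friction coupling:
#'
#' * `fixed_beta`: `beta` supplied directly (worked-example default);
#' * `fixed_Re`: `Re` supplied, `lambda = 64/Re`, `beta` from
#'   [beta_coefficient()];
#' * `self_consistent`: `lambda = 64/Re(V)` with `Re` formed from `V` itself.
#'   Because `beta(V)` is proportional to `1/V`, the fixed point has the
#'   closed form `V = c - b`, where `c` is the driving term
#'   `phi h (alpha_s p_s - alpha_d p_d)/(D gamma)` and
#'   `b = V * beta(V)` is velocity-independent.
#'
#' @param geom a [vessel_geometry()].
#' @param material a [wall_material()].
#' @param ps a [pressure_state()].
#' @param blood a [blood_properties()].
#' @param n pulse frequency, 1/min (used to convert V to m/s for Re).
#' @param mode one of `"fixed_beta"`, `"fixed_Re"`, `"self_consistent"`.
#' @param beta coupling coefficient for `fixed_beta`.
#' @param Re Reynolds number for `fixed_Re`.
#' @return list with `V` (m per pulse), `beta`, `lam`, `Re`, and the driving
#'   term `c_drive`.
#' @export
characteristic_velocity <- function(geom, material, ps, blood = blood_properties(),
                                    n = 60,
                                    mode = c("fixed_beta", "fixed_Re", "self_consistent"),
                                    beta = NULL, Re = NULL) {
  mode <- match.arg(mode)
  if (!inherits(geom, "vessel_geometry")) abort_domain("'geom' must be a vessel_geometry")
  if (!inherits(material, "wall_material")) abort_domain("'material' must be a wall_material")
  if (!inherits(ps, "pressure_state")) abort_domain("'ps' must be a pressure_state")
  if (!inherits(blood, "blood_properties")) abort_domain("'blood' must be blood_properties")
  stopifnot_scalar(n, "n")

  a_s <- alpha_ratio(geom$D_s, geom$h_s)
  a_d <- alpha_ratio(geom$D_d, geom$h_d)
  drive <- a_s * ps$p_s - a_d * ps$p_d
  c_drive <- material$phi * geom$h * drive / (geom$D_in * blood$gamma)

  if (mode == "fixed_beta") {
    if (is.null(beta)) abort_config("mode 'fixed_beta' requires 'beta'")
    V <- c_drive / (1 + beta)
    Re_out <- reynolds_number(V, n, geom$D_in, blood$mu, blood$rho)
    lam <- if (Re_out > 0) 64 / Re_out else NA_real_
  } else if (mode == "fixed_Re") {
    if (is.null(Re)) abort_config("mode 'fixed_Re' requires 'Re'")
    lam <- friction_factor(Re)
    beta <- beta_coefficient(material, lam, geom, ps)
    V <- c_drive / (1 + beta)
    Re_out <- Re
  } else {
    if (ps$pp <= 0) abort_domain("pulse pressure must be > 0 in self_consistent mode")
    # beta(V) = b / V, so V (1 + beta(V)) = c  <=>  V = c - b
    b <- 4 * material$E * (geom$h_d - geom$h_s) * 64 * 60 * blood$mu /
      (blood$rho * n * geom$D_in^2 * ps$pp * material$phi)
    V <- c_drive - b
    if (V < 0)
      abort_regime(sprintf(
        "dissipation exceeds the driving term (c = %.4g m, b = %.4g m): no physical velocity",
        c_drive, b), data = list(c_drive = c_drive, b = b))
    beta <- if (V > 0) b / V else Inf
    Re_out <- reynolds_number(V, n, geom$D_in, blood$mu, blood$rho)
    lam <- if (Re_out > 0) 64 / Re_out else NA_real_
  }
  list(V = V, beta = beta, lam = lam, Re = Re_out,
       c_drive = c_drive, alpha_s = a_s, alpha_d = a_d)
}

#' Per-pulse energy budget of the coupled wall-blood system
#'
#' Assembles, per unit vessel length and per pulse: the lumen area increment
#' `delta_A`, the kinetic energy increment `delta_K = delta_A gamma V^2`, the
#' (negative) wall-shear dissipation `delta_w_tau = -gamma lambda (D_s - D_d)
#' K^2 V^2`, the stored strain energy density `delta_u`, and the Hamilton
#' functional value `chi` whose stationarity in the wall kinematics yields
#' the characteristic velocity.
#'
#' The printed driving term of the kinetic and functional expressions pairs
#' `alpha_d` with the diastolic *stress* in the source material; the default
#' here uses the diastolic pressure (the only dimensionally consistent
#' choice); set `sigma_d_variant = TRUE` to audit the literal stress pairing.
#'
#' @param geom a [vessel_geometry()].
#' @param material a [wall_material()].
#' @param ps a [pressure_state()].
#' @param blood a [blood_properties()].
#' @param V characteristic velocity, m per pulse.
#' @param lam friction loss factor (default 64/1000).
#' @param sigma_d_variant pair `alpha_d` with diastolic stress instead of
#'   diastolic pressure in `delta_K` and `chi`.
#' @return object of class `energy_budget`.
#' @export
energy_budget <- function(geom, material, ps, blood = blood_properties(), V,
                          lam = 64 / 1000, sigma_d_variant = FALSE) {
  if (V < 0) abort_domain("V must be >= 0")
  a_s <- alpha_ratio(geom$D_s, geom$h_s)
  a_d <- alpha_ratio(geom$D_d, geom$h_d)
  E <- material$E; phi <- material$phi
  gam <- blood$gamma; K <- blood$K
  D <- geom$D_in

  delta_A <- phi * (geom$D_s * ps$p_s / geom$h_s - geom$D_d * ps$p_d / geom$h_d) *
    geom$A_f / E
  d_term <- if (sigma_d_variant) {
    a_s * ps$p_s - a_d * laplace_stress(ps$p_d, geom$D_d, geom$h_d, phi)
  } else {
    a_s * ps$p_s - a_d * ps$p_d
  }
  delta_K <- delta_A * gam * V^2
  delta_w_tau <- -gam * lam * (geom$D_s - geom$D_d) * K^2 * V^2
  k_unit <- blood$eta * V^2 / (2 * blood$g)

  chi <- pi * D^2 * phi * gam * d_term * V^2 / (4 * E) -
    pi * D * geom$h * phi^2 * d_term^2 / (8 * E) -
    pi * (geom$D_s - geom$D_d) * phi * gam * lam * D * K^2 * V^2

  structure(list(
    delta_u = sedi_pressure_form(material, a_s, a_d, ps),
    delta_A = delta_A, delta_K = delta_K, delta_w_tau = delta_w_tau,
    chi = chi, k_unit = k_unit, V = V, lam = lam,
    sigma_d_variant = sigma_d_variant), class = "energy_budget")
}

#' @export
print.energy_budget <- function(x, ...) {
  cat("Per-pulse energy budget (per unit vessel length)\n")
  cat(sprintf("  strain energy density increment  %.6g J/m^3\n", x$delta_u))
  cat(sprintf("  lumen area increment             %.6g m^2\n", x$delta_A))
  cat(sprintf("  kinetic energy increment         %.6g\n", x$delta_K))
  cat(sprintf("  wall-shear dissipation           %.6g\n", x$delta_w_tau))
  cat(sprintf("  Hamilton functional chi          %.6g\n", x$chi))
  invisible(x)
}
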