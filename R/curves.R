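#' Pressure-outer-diameter curve from an expansion test
#'
#' Stores the recorded internal pressure vs. external diameter relation of a
#' tubular artery segment held at its in vivo axial stretch, together with
#' the unstressed outer diameter used as the strain reference.
#'
#' Pressures must be strictly increasing; diameters are expected to be
#' non-decreasing (a saturating dilation) and violations are flagged with a
#' warning rather than silently accepted.
#'
#' @param pressure numeric vector of internal pressures (>= 3 points).
#' @param diameter numeric vector of outer diameters, same length.
#' @param D_o unstressed outer diameter (strain reference).
#' @param axial_stretch in vivo axial stretch ratio held during the test.
#' @param segment one of `"ascending"`, `"proximal_descending"`,
#'   `"distal_descending"`.
#' @param pressure_unit,diameter_unit input units (defaults mmHg, mm).
#' @return object of class `pressure_diameter_curve` (SI internally) with
#'   fields `pressure` (Pa), `diameter` (m), `D_o`, `axial_stretch`,
#'   `segment`, `monotone`.
#' @export
pressure_diameter_curve <- function(pressure, diameter, D_o,
                                    axial_stretch = 1.2,
                                    segment = c("ascending",
                                                "proximal_descending",
                                                "distal_descending"),
                                    pressure_unit = "mmHg",
                                    diameter_unit = "mm") {
  segment <- match.arg(segment)
  if (length(pressure) != length(diameter))
    abort_domain("pressure and diameter must have the same length")
  if (length(pressure) < 3L) abort_domain("need at least 3 points")
  p <- convert_pressure(pressure, pressure_unit)
  d <- convert_length(diameter, diameter_unit)
  D_o <- convert_length(stopifnot_scalar(D_o, "D_o"), diameter_unit)
  if (any(diff(p) <= 0)) abort_domain("pressures must be strictly increasing")
  monotone <- all(diff(d) >= 0)
  if (!monotone)
    warn_model("diameters are not non-decreasing; curve flagged (monotone = FALSE)")
  structure(list(pressure = p, diameter = d, D_o = D_o,
                 axial_stretch = axial_stretch, segment = segment,
                 monotone = monotone),
            class = "pressure_diameter_curve")
}

#' @export
print.pressure_diameter_curve <- function(x, ...) {
  cat(sprintf("Pressure-diameter curve (%s, axial stretch %.2f): %d points, %.1f-%.1f mmHg\n",
              x$segment, x$axial_stretch, length(x$pressure),
              pressure_as(min(x$pressure), "mmHg"), pressure_as(max(x$pressure), "mmHg")))
  cat(sprintf("  D_o = %.3f mm, diameters %.3f-%.3f mm%s\n",
              1000 * x$D_o, 1000 * min(x$diameter), 1000 * max(x$diameter),
              if (x$monotone) "" else "  [non-monotone: flagged]"))
  invisible(x)
}

#' @export
plot.pressure_diameter_curve <- function(x, ...) {
  graphics::plot(pressure_as(x$pressure, "mmHg"), 1000 * x$diameter,
                 xlab = "pressure [mmHg]", ylab = "outer diameter [mm]",
                 type = "b", ...)
}

#' Circumferential stress-strain curve
#'
#' @param strain engineering strains, strictly increasing, >= 3 points.
#' @param stress circumferential stresses, non-decreasing.
#' @param quadrant `"ANT"`, `"LNT"`, `"POST"`, `"MED"` or `"mean"`.
#' @param stress_unit `"Pa"` (default) or `"kPa"`.
#' @return object of class `stress_strain_curve` (stress in Pa).
#' @export
stress_strain_curve <- function(strain, stress,
                                quadrant = c("mean", "ANT", "LNT", "POST", "MED"),
                                stress_unit = "Pa") {
  quadrant <- match.arg(quadrant)
  if (length(strain) != length(stress))
    abort_domain("strain and stress must have the same length")
  if (length(strain) < 3L) abort_domain("need at least 3 points")
  if (any(diff(strain) <= 0)) abort_domain("strains must be strictly increasing")
  if (!stress_unit %in% c("Pa", "kPa")) abort_config("stress_unit must be Pa or kPa")
  s <- if (stress_unit == "kPa") stress * 1000 else stress
  if (any(diff(s) < 0))
    warn_model("stresses are not non-decreasing; curve flagged")
  structure(list(strain = as.numeric(strain), stress = as.numeric(s),
                 quadrant = quadrant),
            class = "stress_strain_curve")
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("Stress-strain curve (%s): %d points, strain %.3g-%.3g, stress %.4g-%.4g kPa\n",
              x$quadrant, length(x$strain), min(x$strain), max(x$strain),
              min(x$stress) / 1000, max(x$stress) / 1000))
  invisible(x)
}

#' @export
plot.stress_strain_curve <- function(x, ...) {
  graphics::plot(x$strain, x$stress / 1000,
                 xlab = "engineering strain", ylab = "stress [kPa]",
                 type = "b", ...)
}

#' Relative circumferential strain between systole and diastole
#'
#' `eps_theta = (D_s - D_o)/D_o - (D_d - D_o)/D_o = (D_s - D_d)/D_o`: the
#' difference of the two engineering strains telescopes to a single ratio,
#' so only the diameter excursion and the unstressed diameter are needed.
#'
#' @param D_s,D_d systolic/diastolic outer diameters, m.
#' @param D_o unstressed outer diameter, m.
#' @return dimensionless strain.
#' @export
relative_strain <- function(D_s, D_d, D_o) {
  stopifnot_scalar(D_o, "D_o")
  if (D_s < D_d) abort_domain("D_s must not be below D_d")
  (D_s - D_d) / D_o
}

#' Diastolic/systolic strains read off a pressure-diameter curve
#'
#' Looks up the outer diameters at the diastolic and systolic pressures by
#' monotone piecewise-linear interpolation (never extrapolation) and returns
#' the engineering strains against the unstressed diameter.
#'
#' @param curve a [pressure_diameter_curve()].
#' @param p_d,p_s diastolic/systolic pressure.
#' @param unit pressure unit of `p_d`, `p_s` (default `"Pa"`).
#' @return list with `eps_d`, `eps_s`, `eps_theta`, `D_d`, `D_s`.
#' @export
strain_at_pressures <- function(curve, p_d, p_s, unit = "Pa") {
  if (!inherits(curve, "pressure_diameter_curve"))
    abort_domain("'curve' must be a pressure_diameter_curve")
  p_d <- convert_pressure(p_d, unit); p_s <- convert_pressure(p_s, unit)
  if (p_s < p_d) abort_domain("systolic pressure below diastolic")
  rng <- range(curve$pressure)
  if (p_d < rng[1] || p_s > rng[2])
    abort_domain(sprintf(
      "pressure outside curve range [%.5g, %.5g] Pa: no extrapolation",
      rng[1], rng[2]))
  D_d <- stats::approx(curve$pressure, curve$diameter, xout = p_d)$y
  D_s <- stats::approx(curve$pressure, curve$diameter, xout = p_s)$y
  list(eps_d = (D_d - curve$D_o) / curve$D_o,
       eps_s = (D_s - curve$D_o) / curve$D_o,
       eps_theta = (D_s - D_d) / curve$D_o,
       D_d = D_d, D_s = D_s)
}
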