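#' Mean blood flow sustained by aortic strain energy
#'
#' The central calculator: from a vessel geometry, wall material, pressure
#' state and blood properties it computes the characteristic per-pulse
#' velocity `V`, the base per-pulse flow `Q0 = A_f V`, the incremental flow
#' `dQ = eps_A(p_mean) A_f V` contributed by lumen distension, and the mean
#' flow `Qbar = n (Q0 + dQ)` per minute. All flows carry the frozen
#' calibration constant of [flow_calibration()] unless `calibrated = FALSE`.
#'
#' @param geometry a [vessel_geometry()].
#' @param material a [wall_material()].
#' @param pressure a [pressure_state()].
#' @param blood a [blood_properties()].
#' @param n pulse frequency, 1/min.
#' @param mode friction treatment, see [characteristic_velocity()].
#' @param beta,Re passed to [characteristic_velocity()].
#' @param calibrated apply the frozen calibration constant (default TRUE).
#' @return object of class `aortic_flow` with fields `alpha_s`, `alpha_d`,
#'   `beta`, `V` (m/pulse), `Q0`, `dQ`, `Q` (m^3/pulse), `Qbar` (m^3/min),
#'   `Qbar_L_min`, `Re`, `lam`, `n`, plus the inputs.
#' @examples
#' p <- example_parameters("normal")
#' aortic_flow(p$geometry, p$material, p$pressure, p$blood,
#'             n = p$n, beta = p$beta)
#' @export
aortic_flow <- function(geometry, material, pressure,
                        blood = blood_properties(), n = 60,
                        mode = c("fixed_beta", "fixed_Re", "self_consistent"),
                        beta = NULL, Re = NULL, calibrated = TRUE) {
  mode <- match.arg(mode)
  cv <- characteristic_velocity(geometry, material, pressure, blood,
                                n = n, mode = mode, beta = beta, Re = Re)
  c0 <- if (calibrated) flow_calibration()$c0 else 1
  eps_mean <- area_strain(material, pressure$p_mean, geometry$D_in, geometry$h)
  Q0 <- c0 * geometry$A_f * cv$V
  dQ <- eps_mean * Q0
  Q <- Q0 + dQ
  structure(list(
    alpha_s = cv$alpha_s, alpha_d = cv$alpha_d,
    beta = cv$beta, V = cv$V, lam = cv$lam, Re = cv$Re,
    Q0 = Q0, dQ = dQ, Q = Q, Qbar = n * Q, Qbar_L_min = 1000 * n * Q,
    n = n, mode = mode, eps_mean = eps_mean, calibrated = calibrated,
    geometry = geometry, material = material, pressure = pressure,
    blood = blood), class = "aortic_flow")
}

#' @export
print.aortic_flow <- function(x, ...) {
  cat(sprintf("Aortic mean flow: %.3f L/min  (n = %g /min, mode = %s)\n",
              x$Qbar_L_min, x$n, x$mode))
  cat(sprintf("  V = %.4g m/pulse, beta = %.4g, Re = %.4g, lambda = %.4g\n",
              x$V, x$beta, x$Re, x$lam))
  cat(sprintf("  Q0 = %.4g ml/pulse, dQ = %.4g ml/pulse (area strain at MBP %.3g)\n",
              1e6 * x$Q0, 1e6 * x$dQ, x$eps_mean))
  invisible(x)
}

#' @export
summary.aortic_flow <- function(object, ...) {
  structure(list(flow = object), class = "summary.aortic_flow")
}

#' @export
print.summary.aortic_flow <- function(x, ...) {
  f <- x$flow
  print(f$pressure); print(f$geometry); print(f$material); print(f$blood)
  print(f)
  invisible(x)
}

#' @export
as.data.frame.aortic_flow <- function(x, ...) {
  data.frame(alpha_s = x$alpha_s, alpha_d = x$alpha_d, beta = x$beta,
             V_m_per_pulse = x$V, Re = x$Re, lambda = x$lam,
             Q0_m3 = x$Q0, dQ_m3 = x$dQ, Q_m3 = x$Q,
             Qbar_m3_min = x$Qbar, Qbar_L_min = x$Qbar_L_min,
             n_per_min = x$n, mode = x$mode)
}

#' Relative change in mean flow between two states
#'
#' `100 (Qbar_a - Qbar_b) / Qbar_b`, in percent. Dimensionless by
#' construction: unit conventions, pulse-rate scaling (when shared) and the
#' calibration constant cancel.
#'
#' @param flow_a,flow_b two [aortic_flow()] objects (a compared against b).
#' @return percent change.
#' @export
relative_flow_change <- function(flow_a, flow_b) {
  if (!inherits(flow_a, "aortic_flow") || !inherits(flow_b, "aortic_flow"))
    abort_domain("both arguments must be aortic_flow objects")
  if (flow_b$Qbar == 0) abort_domain("reference flow is zero")
  100 * (flow_a$Qbar - flow_b$Qbar) / flow_b$Qbar
}

#' Solve for the diastolic pressure that matches a reference blood supply
#'
#' Given a reference cohort (pressures, pulse rate, compliance) and a subject
#' cohort with known systolic pressure, pulse rate and compliance but unknown
#' diastolic pressure, finds the subject diastolic pressure at which the
#' subject's mean flow equals the reference mean flow. The expansion
#' constraint coefficient of each cohort scales with its compliance:
#' `phi_i = phi_ref * C_i / C_ref`, where `phi_ref` (from `material`) is
#' anchored at the reference cohort. The root is found by bisection to
#' `tol_mmHg`.
#'
#' @param reference a [cohort_params()] with known `p_s`, `p_d`.
#' @param subject a [cohort_params()]; its `p_d` is ignored/unknown.
#' @param D_o,h reference vessel outer diameter and wall thickness, m.
#' @param material a [wall_material()]; `phi` is the reference-cohort anchor.
#' @param blood a [blood_properties()].
#' @param beta coupling coefficient, held equal across cohorts.
#' @param rule matching rule; only `"equal_mean_flow"` is implemented.
#' @param tol_mmHg bisection tolerance (default 1e-3 mmHg).
#' @param max_iter bisection iteration cap.
#' @param bracket_mmHg search interval; default `c(1, p_s - 1)`.
#' @return list with `p_d_mmHg` (the root), `Qbar_ref` (m^3/min), `iters`.
#' @export
solve_diastolic_pressure <- function(reference, subject,
                                     D_o = 0.032, h = 0.00146,
                                     material = wall_material(3.5e5, 0.0565),
                                     blood = blood_properties(),
                                     beta = 0.290,
                                     rule = c("equal_mean_flow",
                                              "equal_pulse_flow",
                                              "equal_flow_per_compliance"),
                                     tol_mmHg = 1e-3, max_iter = 200,
                                     bracket_mmHg = NULL) {
  rule <- match.arg(rule)
  if (rule != "equal_mean_flow")
    abort_config(sprintf("matching rule '%s' is reserved but not implemented", rule))
  if (!inherits(reference, "cohort_params") || !inherits(subject, "cohort_params"))
    abort_domain("'reference' and 'subject' must be cohort_params")
  if (is.na(reference$p_d))
    abort_domain("the reference cohort needs a known diastolic pressure")

  cohort_Qbar <- function(p_s, p_d, hr, C_ml) {
    phi_i <- material$phi * C_ml / reference$compliance_ml_mmHg
    mat <- wall_material(material$E, phi_i)
    prs <- pressure_state(p_s, p_d, "mmHg")
    geo <- distend_geometry(D_o, h, mat, prs, unit = "m")
    aortic_flow(geo, mat, prs, blood, n = hr,
                mode = "fixed_beta", beta = beta)$Qbar
  }
  Qbar_ref <- cohort_Qbar(reference$p_s, reference$p_d, reference$hr,
                          reference$compliance_ml_mmHg)
  f <- function(pd) cohort_Qbar(subject$p_s, pd, subject$hr,
                                subject$compliance_ml_mmHg) - Qbar_ref

  if (is.null(bracket_mmHg)) bracket_mmHg <- c(1, subject$p_s - 1)
  lo <- bracket_mmHg[1]; hi <- bracket_mmHg[2]
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    abort_regime(sprintf(
      "no sign change in [%g, %g] mmHg: Qbar(subject) - Qbar(reference) is %.4g and %.4g m^3/min",
      lo, hi, flo, fhi), data = list(f_lo = flo, f_hi = fhi))
  iters <- 0L
  while (hi - lo > tol_mmHg && iters < max_iter) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (flo * fm <= 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
    iters <- iters + 1L
  }
  list(p_d_mmHg = (lo + hi) / 2, Qbar_ref = Qbar_ref, iters = iters)
}
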