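# Seeded generators. RNG state is isolated: each generator saves and
# restores .Random.seed so that simulation helpers never disturb the
# caller's stream.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

# Draw one truncated-normal value consistent with a monotone sequence:
# resample until value >= floor (cap 100 attempts).
rtrunc_monotone <- function(mean, sd, floor_at, cap = 100) {
  for (i in seq_len(cap)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= floor_at) return(x)
  }
  abort_regime(sprintf(
    "noise too large to preserve monotonicity after %d resample attempts", cap))
}

#' Simulate a sigmoidal pressure-outer-diameter curve
#'
#' Generates the saturating dilation recorded in an expansion test:
#' `D(p) = D_o + (D_max - D_o) / (1 + exp(-(p - p_half)/slope))`, a bounded,
#' monotone sigmoid with half-dilation pressure `p_half` and pressure scale
#' `slope`. Optional truncated-normal noise is applied point by point and
#' kept monotone by rejection (at most 100 resamples per point).
#'
#' @param D_o unstressed outer diameter, m (lower sigmoid asymptote).
#' @param D_max saturated outer diameter, m.
#' @param p_half half-dilation pressure, Pa.
#' @param slope sigmoid pressure scale, Pa.
#' @param noise_sd diameter noise standard deviation, m.
#' @param n_points number of points (>= 3).
#' @param p_range pressure range, Pa.
#' @param seed integer seed (identical seeds give identical curves).
#' @param segment,axial_stretch stored on the returned curve.
#' @return a [pressure_diameter_curve()].
#' @examples
#' sim_pressure_diameter(seed = 1)
#' @export
sim_pressure_diameter <- function(D_o = 0.020, D_max = 0.026,
                                  p_half = convert_pressure(80, "mmHg"),
                                  slope = convert_pressure(25, "mmHg"),
                                  noise_sd = 0, n_points = 40,
                                  p_range = convert_pressure(c(10, 200), "mmHg"),
                                  seed = NULL,
                                  segment = "ascending",
                                  axial_stretch = 1.2) {
  if (n_points < 3L) abort_domain("n_points must be >= 3")
  if (D_max <= D_o) abort_domain("D_max must exceed D_o")
  stopifnot_scalar(slope, "slope")
  p <- seq(p_range[1], p_range[2], length.out = n_points)
  d <- D_o + (D_max - D_o) / (1 + exp(-(p - p_half) / slope))
  if (noise_sd > 0) {
    d <- with_seed(seed, {
      out <- numeric(n_points)
      prev <- -Inf
      for (i in seq_len(n_points)) {
        out[i] <- rtrunc_monotone(d[i], noise_sd, prev)
        prev <- out[i]
      }
      out
    })
  }
  pressure_diameter_curve(p, d, D_o = D_o, axial_stretch = axial_stretch,
                          segment = segment,
                          pressure_unit = "Pa", diameter_unit = "m")
}

#' Closed-form diameter of the simulated sigmoid
#'
#' The noiseless dilation model behind [sim_pressure_diameter()], exposed so
#' that interpolation-based readings can be checked against the exact curve.
#'
#' @param p pressure, Pa (vectorised).
#' @inheritParams sim_pressure_diameter
#' @return outer diameter, m.
#' @export
sigmoid_diameter <- function(p, D_o = 0.020, D_max = 0.026,
                             p_half = convert_pressure(80, "mmHg"),
                             slope = convert_pressure(25, "mmHg")) {
  D_o + (D_max - D_o) / (1 + exp(-(p - p_half) / slope))
}

#' Illustrative aortic-segment sigmoid parameters
#'
#' Parameter sets for the three thoracic segments (ascending, proximal
#' descending, distal descending) whose expansion curves differ in size and
#' compliance: more proximal segments are larger and dilate more. Values are
#' illustrative shapes for testing, not measurements.
#'
#' @param segment segment name.
#' @return list of arguments for [sim_pressure_diameter()].
#' @export
aorta_segment_params <- function(segment = c("ascending",
                                             "proximal_descending",
                                             "distal_descending")) {
  segment <- match.arg(segment)
  base <- switch(segment,
    ascending           = list(D_o = 0.0200, D_max = 0.0260, axial_stretch = 1.2,
                               p_half = convert_pressure(75, "mmHg"),
                               slope = convert_pressure(25, "mmHg")),
    proximal_descending = list(D_o = 0.0160, D_max = 0.0198, axial_stretch = 1.3,
                               p_half = convert_pressure(80, "mmHg"),
                               slope = convert_pressure(28, "mmHg")),
    distal_descending   = list(D_o = 0.0130, D_max = 0.0155, axial_stretch = 1.4,
                               p_half = convert_pressure(85, "mmHg"),
                               slope = convert_pressure(30, "mmHg")))
  c(base, list(segment = segment))
}

#' Simulate a convex exponential stress-strain curve
#'
#' `sigma = a (exp(b eps) - 1)` on an equally spaced strain grid (default
#' `[0, 0.4]`, the physiological strain range of the arterial wall), plus
#' optional truncated-normal noise kept monotone by rejection.
#'
#' @param a stress scale, Pa.
#' @param b strain exponent.
#' @param noise_sd stress noise standard deviation, Pa.
#' @param n_points number of grid points.
#' @param strain_max upper end of the strain grid.
#' @param seed integer seed.
#' @param quadrant stored on the returned curve.
#' @return a [stress_strain_curve()].
#' @export
sim_stress_strain <- function(a = 20e3, b = 6, noise_sd = 0, n_points = 50,
                              strain_max = 0.4, seed = NULL,
                              quadrant = "mean") {
  stopifnot_scalar(a, "a"); stopifnot_scalar(b, "b")
  eps <- seq(0, strain_max, length.out = n_points)
  sig <- a * (exp(b * eps) - 1)
  if (noise_sd > 0) {
    sig <- with_seed(seed, {
      out <- numeric(n_points)
      prev <- -Inf
      for (i in seq_len(n_points)) {
        out[i] <- rtrunc_monotone(sig[i], noise_sd, prev)
        prev <- out[i]
      }
      out
    })
  }
  stress_strain_curve(eps, sig, quadrant = quadrant, stress_unit = "Pa")
}

#' Default cohort distribution specification
#'
#' Per-parameter mean, standard deviation and truncation bounds for the
#' simulated clinical cohort: pressures in mmHg, diameters/thicknesses in
#' mm, modulus in Pa, viscosity in Pa s, heart rate in 1/min.
#'
#' @return named list of `c(mean, sd, lo, hi)` vectors.
#' @export
cohort_spec_default <- function() {
  list(
    p_s = c(mean = 120,    sd = 15,    lo = 90,   hi = 200),
    p_d = c(mean = 80,     sd = 10,    lo = 50,   hi = 120),
    E   = c(mean = 3.5e5,  sd = 7e4,   lo = 1e5,  hi = 1e6),
    D   = c(mean = 32,     sd = 2,     lo = 24,   hi = 40),
    h   = c(mean = 1.46,   sd = 0.15,  lo = 1.0,  hi = 2.0),
    phi = c(mean = 0.0565, sd = 0.01,  lo = 0.01, hi = 0.2),
    hr  = c(mean = 70,     sd = 10,    lo = 40,   hi = 120),
    mu  = c(mean = 3.5e-3, sd = 5e-4,  lo = 2e-3, hi = 6e-3))
}

#' Simulate a cohort of physiological parameter sets
#'
#' Draws `n_subjects` parameter sets from truncated normal distributions
#' (rejection sampling within bounds) and enforces a systolic-diastolic gap
#' of at least 5 mmHg by redrawing the diastolic pressure. Every subject
#' passes the pressure-state and vessel-geometry validity checks by
#' construction.
#'
#' @param n_subjects number of subjects (0 gives an empty frame).
#' @param spec distribution spec, see [cohort_spec_default()].
#' @param seed integer seed.
#' @param label cohort label.
#' @return data.frame with one row per subject.
#' @export
sim_cohort <- function(n_subjects, spec = cohort_spec_default(), seed = NULL,
                       label = "synthetic") {
  if (n_subjects < 0) abort_domain("n_subjects must be >= 0")
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (s[["lo"]] >= s[["hi"]])
      abort_regime(sprintf("infeasible bounds for '%s'", nm))
  }
  draw <- function(s, n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (k in seq_len(100)) {
        x <- stats::rnorm(1, s[["mean"]], s[["sd"]])
        if (x >= s[["lo"]] && x <= s[["hi"]]) { out[i] <- x; ok <- TRUE; break }
      }
      if (!ok) abort_regime("bounds too tight: 100 rejections in cohort draw")
    }
    out
  }
  with_seed(seed, {
    cols <- lapply(spec, draw, n = n_subjects)
    df <- as.data.frame(cols)
    if (n_subjects == 0) {
      df <- as.data.frame(lapply(spec, function(s) numeric(0)))
    } else {
      # enforce p_s - p_d >= 5 mmHg per subject
      for (i in seq_len(n_subjects)) {
        k <- 0
        while (df$p_s[i] - df$p_d[i] < 5 && k < 100) {
          df$p_d[i] <- draw(spec$p_d, 1); k <- k + 1
        }
        if (df$p_s[i] - df$p_d[i] < 5) df$p_d[i] <- df$p_s[i] - 5
      }
    }
    df$label <- rep(label, nrow(df))
    df
  })
}
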