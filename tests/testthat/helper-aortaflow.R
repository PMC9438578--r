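# Builders shared across test files.

# flow at clinical scalars with pressure-distended geometry; Reynolds
# diagnostics above the laminar threshold are expected at hypertensive
# states and silenced here.
flow_at <- function(p_s, p_d, phi = 0.0565, E = 3.5e5, D_o = 0.032,
                    h = 0.00146, n = 60, beta = 0.290,
                    mode = "fixed_beta", blood = blood_properties(), ...) {
  mat <- wall_material(E, phi)
  prs <- pressure_state(p_s, p_d, "mmHg")
  geo <- distend_geometry(D_o, h, mat, prs, unit = "m")
  suppressWarnings(
    aortic_flow(geo, mat, prs, blood, n = n, mode = mode, beta = beta, ...))
}

# dense noiseless sigmoid fixture for interpolation-based oracles
ascending_fixture <- function(n_points = 2001) {
  prm <- aorta_segment_params("ascending")
  sim_pressure_diameter(D_o = prm$D_o, D_max = prm$D_max,
                        p_half = prm$p_half, slope = prm$slope,
                        segment = prm$segment,
                        axial_stretch = prm$axial_stretch,
                        n_points = n_points)
}

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_true(abs(object - expected) <= rel_tol * abs(expected),
              label = sprintf("|%.10g - %.10g| <= %g relative", object, expected, rel_tol))
}
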