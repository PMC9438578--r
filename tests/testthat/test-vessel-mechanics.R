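test_that("relative strain telescopes to the diameter excursion", {
  expect_equal(relative_strain(0.026, 0.024, 0.020), 0.1)
  expect_equal(relative_strain(0.025, 0.025, 0.020), 0)
  set.seed(7)
  for (i in 1:20) {
    D_o <- runif(1, 0.01, 0.03)
    D_d <- D_o * runif(1, 1.0, 1.2)
    D_s <- D_d * runif(1, 1.0, 1.1)
    expect_rel_equal(relative_strain(D_s, D_d, D_o),
                     (D_s - D_o) / D_o - (D_d - D_o) / D_o, 1e-12)
  }
  expect_error(relative_strain(0.024, 0.026, 0.020), class = "aortaflow_domain_error")
})

test_that("strains read off a curve match the closed-form sigmoid", {
  cur <- ascending_fixture()
  prm <- aorta_segment_params("ascending")
  p_d <- convert_pressure(80, "mmHg"); p_s <- convert_pressure(120, "mmHg")
  st <- strain_at_pressures(cur, p_d, p_s)
  D_d_exact <- sigmoid_diameter(p_d, prm$D_o, prm$D_max, prm$p_half, prm$slope)
  D_s_exact <- sigmoid_diameter(p_s, prm$D_o, prm$D_max, prm$p_half, prm$slope)
  expect_equal(st$eps_d, (D_d_exact - prm$D_o) / prm$D_o, tolerance = 1e-6)
  expect_equal(st$eps_s, (D_s_exact - prm$D_o) / prm$D_o, tolerance = 1e-6)
  expect_equal(st$eps_theta, st$eps_s - st$eps_d)
  # equal pressures give zero relative strain; knots are returned exactly
  st0 <- strain_at_pressures(cur, p_d, p_d)
  expect_equal(st0$eps_theta, 0)
  k <- 500
  stk <- strain_at_pressures(cur, cur$pressure[k], cur$pressure[k])
  expect_equal(stk$D_d, cur$diameter[k])
  expect_error(strain_at_pressures(cur, convert_pressure(1, "mmHg"),
                                   convert_pressure(120, "mmHg")),
               class = "aortaflow_domain_error")
})

test_that("exponential fit recovers noiseless parameters exactly", {
  cur <- sim_stress_strain(a = 20e3, b = 6, n_points = 30)
  fit <- fit_exponential(cur)
  expect_rel_equal(fit$a, 20e3, 1e-6)
  expect_rel_equal(fit$b, 6, 1e-6)
  expect_lt(abs(fit$r2 - 1), 1e-9)
  # methods of the fit object
  expect_named(coef(fit), c("a", "b"))
  expect_equal(predict(fit, 0), 0)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("exponential fit recovers parameters under measurement noise", {
  bs <- vapply(1:100, function(s) {
    cur <- suppressWarnings(
      sim_stress_strain(a = 20e3, b = 6, noise_sd = 1e3, n_points = 50, seed = s))
    coef(fit_exponential(cur))[["b"]]
  }, 0)
  expect_lt(abs(mean(bs) - 6) / 6, 0.05)     # bias under 5 %
  expect_lt(max(abs(bs - 6) / 6), 0.10)      # every replicate within 10 %
})

test_that("near-linear curves are fitted with a*b recovering the slope", {
  E_true <- 2.5e5
  b_small <- 0.05
  eps <- seq(0, 0.4, length.out = 40)
  cur <- stress_strain_curve(eps, (E_true / b_small) * (exp(b_small * eps) - 1))
  fit <- fit_exponential(cur)
  # a and b are individually near-unidentifiable in the linear limit; their
  # product (the slope) is what the data determine
  expect_rel_equal(fit$a * fit$b, E_true, 1e-2)
})

test_that("linear window fits: chord construction and least squares", {
  E <- 3e5
  eps <- seq(0, 0.4, length.out = 41)
  lin <- stress_strain_curve(eps, E * eps)
  f1 <- fit_linear_window(lin, c(0.05, 0.35), method = "chord")
  f2 <- fit_linear_window(lin, c(0.05, 0.35), method = "least_squares")
  expect_rel_equal(f1$E_lin, E, 1e-12)
  expect_rel_equal(f2$E_lin, E, 1e-9)
  # convex curve: chord modulus exceeds the tangent slope at the window foot
  cur <- sim_stress_strain(a = 20e3, b = 6, n_points = 400)
  w <- c(0.1, 0.3)
  ch <- fit_linear_window(cur, w, method = "chord")
  tangent_lo <- 20e3 * 6 * exp(6 * w[1])
  expect_gt(ch$E_lin, tangent_lo)
  # window spanning the whole domain is the endpoint chord by definition
  full <- fit_linear_window(cur, range(cur$strain))
  expect_rel_equal(full$E_lin,
                   (max(cur$stress) - min(cur$stress)) / diff(range(cur$strain)),
                   1e-12)
  expect_error(fit_linear_window(cur, c(0.3, 0.3)), class = "aortaflow_domain_error")
})

test_that("strain-energy integration matches the analytic antiderivative", {
  a <- 20e3; b <- 6
  fit <- fit_exponential(sim_stress_strain(a = a, b = b, n_points = 30))
  closed <- strain_energy_integral(fit, 0, 0.3)
  exact <- a * (exp(b * 0.3) - 1) / b - a * 0.3
  expect_rel_equal(closed, exact, 1e-9)
  # trapezoid on a 200-panel tabulation agrees within 0.1 %
  eps <- seq(0, 0.3, length.out = 201)
  tab <- stress_strain_curve(eps, a * (exp(b * eps) - 1))
  expect_rel_equal(strain_energy_integral(tab, 0, 0.3), exact, 1e-3)
  # and converges to 1e-6 relative at 1e5 panels
  eps5 <- seq(0, 0.3, length.out = 1e5 + 1)
  tab5 <- stress_strain_curve(eps5, a * (exp(b * eps5) - 1))
  expect_rel_equal(strain_energy_integral(tab5, 0, 0.3), exact, 1e-6)
  # linear curve closed form and degenerate window
  E <- 3e5
  linc <- stress_strain_curve(seq(0, 0.4, length.out = 81), E * seq(0, 0.4, length.out = 81))
  expect_rel_equal(strain_energy_integral(linc, 0.1, 0.3), E * (0.3^2 - 0.1^2) / 2, 1e-12)
  expect_identical(strain_energy_integral(linc, 0.2, 0.2), 0)
  expect_error(strain_energy_integral(linc, -0.1, 0.2), class = "aortaflow_domain_error")
})

test_that("linear-vs-integral energy difference is positive, exact, and shrinks with the window", {
  E <- 3e5
  eps <- seq(0, 0.4, length.out = 81)
  linc <- stress_strain_curve(eps, E * eps)
  expect_equal(linear_vs_integral_ratio(linc, c(0.05, 0.35)), 0, tolerance = 1e-9)

  a <- 20e3; b <- 6
  dense <- seq(0, 0.4, length.out = 20001)
  cur <- stress_strain_curve(dense, a * (exp(b * dense) - 1))
  w <- c(0.15, 0.30)
  got <- linear_vs_integral_ratio(cur, w)
  # analytic oracle for the above-baseline areas
  s_ <- function(e) a * (exp(b * e) - 1)
  int_above <- (a * (exp(b * w[2]) - 1) / b - a * w[2]) -
    (a * (exp(b * w[1]) - 1) / b - a * w[1]) - s_(w[1]) * diff(w)
  lin_above <- (s_(w[2]) - s_(w[1])) * diff(w) / 2
  expect_rel_equal(got, 100 * (lin_above - int_above) / int_above, 1e-4)
  expect_gt(got, 0)
  # nested windows: the convexity error grows with window width
  widths <- c(0.05, 0.10, 0.15)
  vals <- vapply(widths, function(wd) linear_vs_integral_ratio(cur, c(0.15, 0.15 + wd)), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("phi from compliance inverts the area-strain compliance", {
  E <- 3.5e5; h <- 0.00146; D <- 0.02908; A <- pi / 4 * D^2; L <- 0.5
  phi <- 0.0565
  C <- compliance_from_phi(phi, E, h, A, D, L)
  expect_rel_equal(phi_from_compliance(C, E, h, A, D, L), phi, 1e-12)
  expect_rel_equal(phi_from_compliance(C, E, h, A, D, 2 * L), phi / 2, 1e-12)
  # the printed healthy compliance maps into (0, 1) for a half-metre segment
  C_SI <- 1.78 * 1e-6 / 133.322
  phi_h <- phi_from_compliance(C_SI, E, h, A, D, L)
  expect_gt(phi_h, 0); expect_lt(phi_h, 1)
})

test_that("curve constructors validate and flag their invariants", {
  expect_error(stress_strain_curve(c(0, 0.1), c(0, 1)), class = "aortaflow_domain_error")
  expect_error(stress_strain_curve(c(0, 0.1, 0.1), c(0, 1, 2)),
               class = "aortaflow_domain_error")
  expect_warning(stress_strain_curve(c(0, 0.1, 0.2), c(0, 2, 1)),
                 class = "aortaflow_warning")
  expect_error(pressure_diameter_curve(c(10, 20), c(20, 21), D_o = 20),
               class = "aortaflow_domain_error")
  expect_warning(
    cur <- pressure_diameter_curve(c(10, 20, 30), c(20, 22, 21), D_o = 20),
    class = "aortaflow_warning")
  expect_false(cur$monotone)
})
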