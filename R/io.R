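#' Read and write curve CSV files
#'
#' The CSV dialect is two-column, comma-separated, UTF-8, with `#` comment
#' lines ignored: `pressure_mmHg,outer_diameter_mm` for expansion-test
#' curves and `strain,stress_kPa` for stress-strain curves. Written
#' pressure-diameter files carry the unstressed diameter as a
#' `# D_o_mm=...` comment so that a round trip preserves the strain
#' reference.
#'
#' @param path file path.
#' @param D_o unstressed outer diameter in mm (pressure-diameter curves
#'   only); if `NULL`, taken from a `# D_o_mm=` comment, else from the first
#'   recorded diameter with a warning.
#' @return a [pressure_diameter_curve()] or [stress_strain_curve()],
#'   depending on the header.
#' @export
read_curve_csv <- function(path, D_o = NULL) {
  if (!file.exists(path)) abort_config(sprintf("file not found: %s", path))
  header <- NULL
  first_lines <- readLines(path, n = 20L, warn = FALSE)
  meta <- grep("^#\\s*D_o_mm\\s*=", first_lines, value = TRUE)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", strip.white = TRUE),
    error = function(e) abort_config(sprintf("malformed CSV '%s': %s",
                                             path, conditionMessage(e))))
  cols <- names(df)
  if (all(c("pressure_mmHg", "outer_diameter_mm") %in% cols)) {
    if (is.null(D_o) && length(meta))
      D_o <- as.numeric(sub(".*=\\s*", "", meta[1]))
    if (is.null(D_o) || is.na(D_o)) {
      warn_model(sprintf("'%s': no D_o given; using the first recorded diameter", path))
      D_o <- df$outer_diameter_mm[1]
    }
    pressure_diameter_curve(df$pressure_mmHg, df$outer_diameter_mm, D_o = D_o,
                            pressure_unit = "mmHg", diameter_unit = "mm")
  } else if (all(c("strain", "stress_kPa") %in% cols)) {
    stress_strain_curve(df$strain, df$stress_kPa, stress_unit = "kPa")
  } else {
    abort_config(sprintf(
      "'%s': unrecognised header '%s' (expected pressure_mmHg,outer_diameter_mm or strain,stress_kPa)",
      path, paste(cols, collapse = ",")))
  }
}

#' @rdname read_curve_csv
#' @param curve a curve object to write.
#' @export
write_curve_csv <- function(curve, path) {
  if (inherits(curve, "pressure_diameter_curve")) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("# D_o_mm=%.15g", 1000 * curve$D_o), con)
    utils::write.csv(
      data.frame(pressure_mmHg = pressure_as(curve$pressure, "mmHg"),
                 outer_diameter_mm = 1000 * curve$diameter),
      con, row.names = FALSE, quote = FALSE)
  } else if (inherits(curve, "stress_strain_curve")) {
    utils::write.csv(
      data.frame(strain = curve$strain, stress_kPa = curve$stress / 1000),
      path, row.names = FALSE, quote = FALSE)
  } else abort_domain("unsupported curve object")
  invisible(path)
}

# allowed run-config keys (unit-suffixed) and their defaults; NULL = required
run_config_schema <- function() {
  list(p_s_mmHg = NULL, p_d_mmHg = NULL,
       E_Pa = 3.5e5, phi = 0.0565, D_mm = 32, h_mm = 1.46,
       n_per_min = 60, mode = "fixed_beta", beta = 0.290, Re = NA,
       rho_kg_m3 = 1050, mu_Pa_s = 3.5e-3, K = 1, eta = 2,
       gamma_convention = "kgf",
       compliance_ml_per_mmHg = NA, seed = NA, label = "")
}

#' Load and validate a run configuration
#'
#' Reads a parameter set from JSON or YAML (by extension). Keys carry
#' explicit unit suffixes (`p_s_mmHg`, `D_mm`, `E_Pa`, ...). Unknown keys
#' are rejected; missing required keys are reported by name.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return named list with all schema keys filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) abort_config(sprintf(
               "malformed JSON in '%s': %s", path, conditionMessage(e))))
  } else if (ext %in% c("yaml", "yml")) {
    tryCatch(yaml::read_yaml(path),
             error = function(e) abort_config(sprintf(
               "malformed YAML in '%s': %s", path, conditionMessage(e))))
  } else abort_config(sprintf("config '%s' must be .json, .yaml or .yml", path))

  schema <- run_config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    abort_config(sprintf("unknown config key(s) in '%s': %s",
                         path, paste(unknown, collapse = ", ")))
  required <- names(schema)[vapply(schema, is.null, TRUE)]
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    abort_config(sprintf("missing required config key(s) in '%s': %s",
                         path, paste(missing, collapse = ", ")))
  out <- utils::modifyList(schema, cfg)
  out
}

#' Compute a flow solution from a run configuration
#'
#' @param cfg a list from [read_run_config()].
#' @return an [aortic_flow()] object.
#' @export
flow_from_config <- function(cfg) {
  mat <- wall_material(cfg$E_Pa, cfg$phi)
  prs <- pressure_state(cfg$p_s_mmHg, cfg$p_d_mmHg, "mmHg")
  blo <- blood_properties(rho = cfg$rho_kg_m3, mu = cfg$mu_Pa_s,
                          eta = cfg$eta, K = cfg$K,
                          convention = cfg$gamma_convention)
  geo <- distend_geometry(cfg$D_mm, cfg$h_mm, mat, prs, unit = "mm")
  aortic_flow(geo, mat, prs, blo, n = cfg$n_per_min, mode = cfg$mode,
              beta = if (is.na(cfg$beta)) NULL else cfg$beta,
              Re = if (is.na(cfg$Re)) NULL else cfg$Re)
}

#' Write a machine-readable flow report
#'
#' Serialises a flow solution and the effective configuration to JSON with
#' every intermediate quantity (wall ratios, beta, V, Re, lambda, per-pulse
#' and per-minute flows) for auditability.
#'
#' @param flow an [aortic_flow()].
#' @param path output path.
#' @param config optional effective configuration list to echo.
#' @return `path`, invisibly.
#' @export
write_flow_report <- function(flow, path, config = NULL) {
  report <- list(
    result = list(
      alpha_s = flow$alpha_s, alpha_d = flow$alpha_d, beta = flow$beta,
      V_m_per_pulse = flow$V, Re = flow$Re, lambda = flow$lam,
      Q0_m3 = flow$Q0, dQ_m3 = flow$dQ, Q_m3 = flow$Q,
      Qbar_m3_min = flow$Qbar, Qbar_L_min = flow$Qbar_L_min,
      n_per_min = flow$n, mode = flow$mode,
      area_strain_at_MBP = flow$eps_mean),
    calibration = flow_calibration()[c("c0", "gamma_convention")],
    config = config)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
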