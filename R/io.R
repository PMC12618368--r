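#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, fills every unset field from the
#' `paper_lcx_defaults` preset (Table-style material constants, 8 kPa outlet,
#' 3/0.8 kPa external wall tractions, 0.007 s / 3-cycle / 1.4 s schedule) and
#' validates physical ranges.  Unknown keys are rejected.
#'
#' Recognised top-level keys: `mode`, `seed`, `outlet_pressure_pa`,
#' `external_pressures_pa`, `output_dir`, `geometry` (either `file:` or a
#' synthetic spec with `kind`, `length_m`, `base_radius_m`, `dz_m`,
#' `severity`), `waveform` (either `file:` or `mean_velocity_m_s`,
#' `pulsatility_index`), `ktgf` (any [ktgf_params()] field), `rheology`
#' (any [single_phase_rheology()] field), `coupling` (any
#' [coupling_config()] field), `wall` (`preset`, `stiffness_scale`,
#' `viscoelastic`), `fsi`.
#'
#' @param path YAML file path; an empty file yields the full-default config.
#' @return A validated `run_config` list with all defaults resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_run_config()
  known <- names(defaults)
  bad <- setdiff(names(user), known)
  if (length(bad))
    stop("load_config: unknown keys: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, user)
  cfg$external_pressures_pa <- as.numeric(unlist(cfg$external_pressures_pa))
  if (length(cfg$external_pressures_pa) != 2)
    stop("load_config: external_pressures_pa must have two entries", call. = FALSE)
  for (sec in c("geometry", "waveform", "ktgf", "rheology", "coupling", "wall")) {
    extra <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    extra <- setdiff(extra, "file")
    if (length(extra))
      stop("load_config: unknown keys in `", sec, "`: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  # physical-range validation happens in the constructors
  k <- cfg$ktgf
  cfg$ktgf_params <- ktgf_params(d_rbc = k$d_rbc_m, rho_rbc = k$rho_rbc,
                                 rho_p = k$rho_p, mu_p = k$mu_p, e = k$e,
                                 eps_max = k$eps_max, e_wall = k$e_wall,
                                 phi_spec = k$phi_spec, eps_init = k$eps_init,
                                 theta_init = k$theta_init)
  r <- cfg$rheology
  cfg$rheology_obj <- single_phase_rheology(model = r$model, mu = r$mu,
                                            k = r$k, n = r$n, H = r$H,
                                            eta_p = r$eta_p, k0 = r$k0,
                                            k_inf = r$k_inf,
                                            gamma_c = r$gamma_c, rho = r$rho)
  cc <- cfg$coupling
  cfg$coupling_cfg <- coupling_config(dt = cc$dt_s, n_cycles = cc$n_cycles,
                                      T_cycle = cc$T_s,
                                      tol_radius = cc$tol_radius,
                                      max_subiters = cc$max_subiters,
                                      relaxation = cc$relaxation, nr = cc$nr)
  cfg$material <- wall_material(cfg$wall$preset,
                                stiffness_scale = cfg$wall$stiffness_scale,
                                viscoelastic = cfg$wall$viscoelastic)
  if (!cfg$mode %in% c("two_phase", "single_phase"))
    stop("load_config: mode must be two_phase or single_phase", call. = FALSE)
  structure(cfg, class = "run_config")
}

default_run_config <- function() {
  list(
    mode = "two_phase",
    seed = 1,
    outlet_pressure_pa = 8000,
    external_pressures_pa = c(3000, 800),
    output_dir = "hemofsi_out",
    fsi = TRUE,
    geometry = list(file = NULL, kind = "stenosis", length_m = 0.02,
                    base_radius_m = 1.5e-3, dz_m = 2e-3, severity = 0.5),
    waveform = list(file = NULL, mean_velocity_m_s = 0.15,
                    pulsatility_index = 1.2),
    ktgf = list(d_rbc_m = 8e-6, rho_rbc = 1096, rho_p = 1003, mu_p = 0.001,
                e = 0.99999, eps_max = 0.7, e_wall = 0.9999, phi_spec = 0.6,
                eps_init = 0.45, theta_init = 1e-4),
    rheology = list(model = "power_law", mu = 0.00345, k = 0.035, n = 0.6,
                    H = 0.45, eta_p = 0.001, k0 = 4.33, k_inf = 1.88,
                    gamma_c = 1.82, rho = 1050),
    coupling = list(dt_s = 0.007, n_cycles = 3, T_s = 1.4, tol_radius = 1e-4,
                    max_subiters = 50, relaxation = 0.7, nr = 24),
    wall = list(preset = "holzapfel_lcx", stiffness_scale = 1,
                viscoelastic = TRUE))
}

#' Resolve the geometry and waveform of a run configuration
#'
#' Builds the [vessel_geometry()] and [fourier_waveform()] a configuration
#' describes, reading CSV files when given, otherwise generating the
#' synthetic stand-ins (seeded by `cfg$seed`).
#'
#' @param cfg a `run_config` from [load_config()].
#' @return A list with `geometry` and `waveform`.
#' @export
resolve_inputs <- function(cfg) {
  geometry <- if (!is.null(cfg$geometry$file)) read_vessel_csv(cfg$geometry$file)
  else make_vessel(cfg$geometry$kind, length = cfg$geometry$length_m,
                   base_radius = cfg$geometry$base_radius_m,
                   dz = cfg$geometry$dz_m, severity = cfg$geometry$severity)
  waveform <- if (!is.null(cfg$waveform$file)) {
    df <- read_waveform_csv(cfg$waveform$file)
    fit_fourier(df, T_cycle = cfg$coupling$T_s)
  } else {
    synthesize_coronary_waveform(cfg$waveform$mean_velocity_m_s,
                                 T_cycle = cfg$coupling$T_s,
                                 pulsatility_index = cfg$waveform$pulsatility_index,
                                 seed = cfg$seed)
  }
  list(geometry = geometry, waveform = waveform)
}

#' Execute a configured run
#'
#' Convenience wrapper: resolve inputs, run the simulation, write outputs
#' (index CSV, manifest JSON, WSS/pressure CSV time series, VTK snapshots).
#'
#' @param cfg a `run_config` from [load_config()].
#' @param write logical; write output files to `cfg$output_dir`.
#' @return The `hemofsi_sim` result, invisibly when writing.
#' @export
execute_run <- function(cfg, write = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  inp <- resolve_inputs(cfg)
  sim <- run_simulation(inp$geometry, inp$waveform,
                        params = cfg$ktgf_params, mode = cfg$mode,
                        rheology = cfg$rheology_obj, cfg = cfg$coupling_cfg,
                        material = cfg$material,
                        external = cfg$external_pressures_pa,
                        outlet_pressure = cfg$outlet_pressure_pa,
                        fsi = cfg$fsi)
  if (write) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_indices_csv(sim, file.path(cfg$output_dir, "indices.csv"))
    write_timeseries_csv(sim, file.path(cfg$output_dir, "timeseries.csv"))
    write_vtk_snapshot(sim, file.path(cfg$output_dir, "fields_systole.vtk"),
                       time = sim$systole_time)
    write_manifest(cfg, sim, file.path(cfg$output_dir, "manifest.json"))
    invisible(sim)
  } else sim
}

#' Write the per-station index CSV
#'
#' Columns `z_m, tawss_pa, osi, vulnerable`; full double precision.
#'
#' @param sim a `hemofsi_sim`.
#' @param path output path.
#' @param threshold vulnerability threshold (Pa).
#' @export
write_indices_csv <- function(sim, path, threshold = 0.4) {
  df <- index_table(sim, threshold)
  df$tawss_pa <- format(df$tawss_pa, digits = 17, trim = TRUE)
  df$osi <- format(df$osi, digits = 17, trim = TRUE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the compact last-cycle time-series CSV
#'
#' Long format: `time_s, z_m, tau_w_pa, pressure_pa, eps_center` (the last
#' column only for two-phase runs).
#'
#' @param sim a `hemofsi_sim`.
#' @param path output path.
#' @export
write_timeseries_csv <- function(sim, path) {
  lc <- sim$last_cycle
  df <- expand.grid(z_m = sim$z, time_s = sim$times[lc])
  df <- df[c("time_s", "z_m")]
  df$tau_w_pa <- as.vector(sim$tau_w[, lc])
  df$pressure_pa <- as.vector(sim$pressure[, lc])
  if (!is.null(sim$eps_center)) df$eps_center <- as.vector(sim$eps_center[, lc])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write one saved instant as a legacy-ASCII VTK structured grid
#'
#' Axisymmetric r-z structured grid of the final states (the solver keeps
#' full radial profiles only for the current step), with plasma velocity,
#' RBC velocity, RBC fraction and granular temperature as point data for
#' two-phase runs, or the single-phase velocity otherwise.
#'
#' @param sim a `hemofsi_sim`.
#' @param path output `.vtk` path.
#' @param time snapshot label written into the header (s).
#' @export
write_vtk_snapshot <- function(sim, path, time = max(sim$times)) {
  states <- sim$states
  nr <- states[[1]]$nr
  S <- length(states)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("hemofsi axisymmetric fields t=%g", time),
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nr, S),
               sprintf("POINTS %d double", nr * S)), con)
  for (s in seq_len(S)) {
    g <- radial_grid(nr, states[[s]]$R)
    writeLines(sprintf("%.10e %.10e 0", g$r, rep(sim$z[s], nr)), con)
  }
  writeLines(sprintf("POINT_DATA %d", nr * S), con)
  wf <- function(name, get) {
    writeLines(c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"),
               con)
    for (s in seq_len(S)) writeLines(sprintf("%.10e", get(states[[s]])), con)
  }
  if (sim$mode == "two_phase") {
    wf("v_plasma", function(st) st$v_p)
    wf("v_rbc", function(st) st$v_rbc)
    wf("eps_rbc", function(st) st$eps_rbc)
    wf("granular_temperature", function(st) st$theta)
  } else {
    wf("v", function(st) st$v)
  }
  invisible(path)
}

#' Write the run manifest
#'
#' JSON record sufficient to reproduce the run: the resolved configuration,
#' seed, package version, periodicity metric and subiteration statistics.
#'
#' @param cfg a `run_config`.
#' @param sim the finished `hemofsi_sim`.
#' @param path output path.
#' @export
write_manifest <- function(cfg, sim, path) {
  man <- list(
    package = "hemofsi",
    version = as.character(utils::packageVersion("hemofsi")),
    seed = cfg$seed,
    mode = cfg$mode,
    config = cfg[c("mode", "seed", "outlet_pressure_pa",
                   "external_pressures_pa", "fsi", "geometry", "waveform",
                   "ktgf", "rheology", "coupling", "wall")],
    n_steps = length(sim$times),
    periodicity_rel_l2 = sim$periodicity,
    systole_time_s = sim$systole_time,
    diastole_time_s = sim$diastole_time,
    subiters = list(mean = mean(sim$subiters), max = max(sim$subiters)),
    conservation = sim$conservation)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a comparison report as JSON
#'
#' @param cmp a [compare_runs()] result.
#' @param path output path.
#' @export
write_comparison_json <- function(cmp, path) {
  stopifnot(inherits(cmp, "run_comparison"))
  jsonlite::write_json(unclass(cmp), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
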