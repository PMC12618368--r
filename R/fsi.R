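#' Signed wall-shear-stress record
#'
#' Wall shear stress per centerline station and saved time, signed by the
#' axial flow direction.
#'
#' @param tau_w matrix (stations x times) of wall shear stress (Pa).
#' @param times saved times (s), strictly increasing.
#' @param z station axial positions (m).
#' @return An object of class `wss_record`.
#' @export
wss_record <- function(tau_w, times, z) {
  tau_w <- as.matrix(tau_w)
  if (nrow(tau_w) != length(z) || ncol(tau_w) != length(times))
    stop("wss_record: tau_w must be stations x times", call. = FALSE)
  if (any(diff(times) <= 0)) stop("wss_record: times must be increasing", call. = FALSE)
  if (any(!is.finite(tau_w))) stop("wss_record: non-finite shear values", call. = FALSE)
  structure(list(tau_w = tau_w, times = times, z = z), class = "wss_record")
}

#' @export
print.wss_record <- function(x, ...) {
  cat(sprintf("WSS record: %d stations x %d times, t in [%g, %g] s\n",
              nrow(x$tau_w), ncol(x$tau_w), min(x$times), max(x$times)))
  cat(sprintf("  tau_w range [%.4g, %.4g] Pa\n", min(x$tau_w), max(x$tau_w)))
  invisible(x)
}

#' Coupling and schedule configuration
#'
#' Controls the cardiac-cycle schedule and the partitioned fluid-wall
#' coupling loop.  Defaults follow the standard protocol: time step 0.007 s,
#' cardiac period 1.4 s (43 bpm) and three cycles, i.e. 200 steps per cycle
#' and 600 in total, with only the final cycle reported.
#'
#' @param dt time step (s).
#' @param n_cycles number of cardiac cycles.
#' @param T_cycle cardiac period (s).
#' @param tol_radius relative radius convergence tolerance of the coupling
#'   subiteration.
#' @param max_subiters subiteration cap per time step.
#' @param relaxation under-relaxation factor in (0, 1].
#' @param nr radial cells per station.
#' @param theta_scheme implicitness of the fluid diffusion terms.
#' @return An object of class `coupling_config`.
#' @export
coupling_config <- function(dt = 0.007, n_cycles = 3, T_cycle = 1.4,
                            tol_radius = 1e-4, max_subiters = 50,
                            relaxation = 0.7, nr = 24, theta_scheme = 1) {
  if (dt <= 0 || n_cycles < 1 || T_cycle <= 0)
    stop("coupling_config: dt, n_cycles, T must be positive", call. = FALSE)
  if (relaxation <= 0 || relaxation > 1)
    stop("coupling_config: relaxation must be in (0, 1]", call. = FALSE)
  if (tol_radius <= 0) stop("coupling_config: tol_radius must be > 0", call. = FALSE)
  steps <- T_cycle / dt
  if (abs(steps - round(steps)) > 1e-9)
    stop("coupling_config: T must be an integer multiple of dt", call. = FALSE)
  structure(list(dt = dt, n_cycles = n_cycles, T_cycle = T_cycle,
                 tol_radius = tol_radius, max_subiters = max_subiters,
                 relaxation = relaxation, nr = nr,
                 theta_scheme = theta_scheme),
            class = "coupling_config")
}

# step every station's fluid state at fixed radii; returns states + station
# pressures (outlet anchored) + wall shear
fluid_sweep <- function(states, radii, Q, dt, z, mode, params, rheology,
                        outlet_pressure, theta_scheme) {
  S <- length(states)
  dpdz <- numeric(S)
  tau <- numeric(S)
  for (s in seq_len(S)) {
    if (mode == "two_phase") {
      states[[s]] <- step_station(states[[s]], radii[s],
                                  list(flow_rate = Q), dt, params,
                                  theta_scheme = theta_scheme)
      tau[s] <- wall_shear_stress(states[[s]], params = params)
    } else {
      states[[s]] <- step_station_single(states[[s]], radii[s],
                                         list(flow_rate = Q), dt, rheology,
                                         theta_scheme = theta_scheme)
      tau[s] <- wall_shear_stress(states[[s]], rheology = rheology)
    }
    dpdz[s] <- states[[s]]$dpdz
  }
  P <- numeric(S)
  P[S] <- outlet_pressure
  if (S > 1)
    for (s in (S - 1):1)
      P[s] <- P[s + 1] - 0.5 * (dpdz[s] + dpdz[s + 1]) * (z[s + 1] - z[s])
  for (s in seq_len(S)) states[[s]]$P <- P[s]
  list(states = states, P = P, tau = tau, dpdz = dpdz)
}

#' One two-way coupled time step
#'
#' Partitioned fixed-point loop over all stations: fluid sweep at the current
#' radii, station pressures, quasi-static wall response, under-relaxed radius
#' update, repeated until the maximum relative radius change falls below
#' `cfg$tol_radius`.  Fluid states are re-stepped from the same start-of-step
#' state in every subiteration; the wall's viscoelastic internal variables are
#' committed only once, at the converged pressures.
#'
#' @param states list of per-station fluid states at the start of the step.
#' @param radii current lumen radii (m).
#' @param wall_visco list of per-station viscoelastic wall states (or NULL).
#' @param Q target mixture flow rate for this step (m^3/s).
#' @param dt time step (s).
#' @param geometry a [vessel_geometry()].
#' @param material a [wall_material()].
#' @param external outer-surface radial pressures (Pa) for the two layers.
#' @param mode `"two_phase"` or `"single_phase"`.
#' @param params a [ktgf_params()] (two-phase mode).
#' @param rheology a [single_phase_rheology()] (single-phase mode).
#' @param outlet_pressure outlet pressure anchor (Pa).
#' @param cfg a [coupling_config()].
#' @return List: `states`, `radii`, `wall` (per-station [tube_response()]
#'   results), `wall_visco`, `P`, `tau`, `subiters`, `residuals`.
#' @export
couple_step <- function(states, radii, wall_visco, Q, dt, geometry, material,
                        external, mode, params, rheology, outlet_pressure,
                        cfg) {
  S <- nrow(geometry)
  states0 <- states
  residuals <- numeric(0)
  sweep <- NULL
  for (it in seq_len(cfg$max_subiters)) {
    sweep <- fluid_sweep(states0, radii, Q, dt, geometry$z_m, mode, params,
                         rheology, outlet_pressure, cfg$theta_scheme)
    r_wall <- vapply(seq_len(S), function(s) {
      st <- list(R0 = geometry$radius_m[s], t1 = geometry$t1_m[s],
                 t2 = geometry$t2_m[s])
      tube_response(max(sweep$P[s], 0), st, material, external,
                    visco_state = wall_visco[[s]], dt = dt)$radius
    }, numeric(1))
    res <- max(abs(r_wall - radii) / geometry$radius_m)
    residuals <- c(residuals, res)
    radii <- radii + cfg$relaxation * (r_wall - radii)
    if (res < cfg$tol_radius) break
  }
  if (residuals[length(residuals)] >= cfg$tol_radius)
    stop("couple_step: coupling did not converge in ", cfg$max_subiters,
         " subiterations; residual trace: ",
         paste(signif(residuals, 3), collapse = ", "), call. = FALSE)
  # commit the wall at the converged pressures
  wall <- vector("list", S)
  for (s in seq_len(S)) {
    st <- list(R0 = geometry$radius_m[s], t1 = geometry$t1_m[s],
               t2 = geometry$t2_m[s])
    wall[[s]] <- tube_response(max(sweep$P[s], 0), st, material, external,
                               visco_state = wall_visco[[s]], dt = dt)
    # single-bracket list assignment: the committed state may be NULL
    wall_visco[s] <- list(wall[[s]]$visco_state)
  }
  list(states = sweep$states, radii = radii, wall = wall,
       wall_visco = wall_visco, P = sweep$P, tau = sweep$tau,
       subiters = length(residuals), residuals = residuals)
}

# shared cycle driver behind solve_vessel() and run_simulation()
march_vessel <- function(geometry, waveform, params, mode, rheology,
                         cfg, outlet_pressure, fsi, material, external) {
  S <- nrow(geometry)
  A_in <- pi * geometry$radius_m[1]^2
  n_per <- round(cfg$T_cycle / cfg$dt)
  n_tot <- n_per * cfg$n_cycles
  states <- lapply(seq_len(S), function(s) {
    if (mode == "two_phase") two_phase_state(cfg$nr, geometry$radius_m[s], params)
    else single_phase_state(cfg$nr, geometry$radius_m[s])
  })
  radii <- geometry$radius_m
  wall_visco <- if (fsi) lapply(seq_len(S), function(s)
    new_wall_visco_state(material)) else NULL

  tau_w <- matrix(0, S, n_tot)
  pressure <- matrix(0, S, n_tot)
  radius_hist <- if (fsi) matrix(0, S, n_tot) else NULL
  vms1 <- if (fsi) matrix(0, S, n_tot) else NULL
  vms2 <- if (fsi) matrix(0, S, n_tot) else NULL
  eps_center <- if (mode == "two_phase") matrix(0, S, n_tot) else NULL
  subiters <- integer(n_tot)
  mass0 <- mass_prev <- NULL
  # area-mean RBC fraction per station (the measure the conservative
  # drift-transport preserves; profiles ride on the normalised radial grid
  # under wall motion, and the reduced model has no axial eps flux)
  rbc_mass <- function() vapply(states, function(st) {
    g <- radial_grid(st$nr, st$R)
    2 * sum(st$eps_rbc * g$r) * g$h / st$R^2
  }, numeric(1))
  mass_drift <- 0
  times <- seq_len(n_tot) * cfg$dt
  wall <- NULL

  for (k in seq_len(n_tot)) {
    Q <- evaluate_waveform(waveform, times[k]) * A_in
    if (fsi) {
      out <- couple_step(states, radii, wall_visco, Q, cfg$dt, geometry,
                         material, external, mode, params, rheology,
                         outlet_pressure, cfg)
      states <- out$states; radii <- out$radii
      wall_visco <- out$wall_visco; wall <- out$wall
      subiters[k] <- out$subiters
      radius_hist[, k] <- radii
      vms1[, k] <- vapply(wall, function(w) w$vms[1], numeric(1))
      vms2[, k] <- vapply(wall, function(w) w$vms[2], numeric(1))
    } else {
      out <- fluid_sweep(states, radii, Q, cfg$dt, geometry$z_m, mode,
                         params, rheology, outlet_pressure, cfg$theta_scheme)
      states <- out$states
      subiters[k] <- 1L
    }
    tau_w[, k] <- out$tau
    pressure[, k] <- out$P
    if (mode == "two_phase") {
      eps_center[, k] <- vapply(states, function(st) st$eps_rbc[1], numeric(1))
      if (k == 1) mass0 <- rbc_mass()
      if (k %% n_per == 0) {
        m <- rbc_mass()
        mass_drift <- max(mass_drift, max(abs(m - mass0) /
                                            pmax(mass0, 1e-300)))
      }
    }
  }
  last <- (n_tot - n_per + 1):n_tot
  prev <- if (cfg$n_cycles >= 2) (n_tot - 2 * n_per + 1):(n_tot - n_per) else NULL
  periodicity <- if (!is.null(prev)) {
    sqrt(sum((tau_w[, last] - tau_w[, prev])^2)) /
      max(sqrt(sum(tau_w[, last]^2)), 1e-300)
  } else NA_real_
  v_last <- evaluate_waveform(waveform, times[last])
  structure(list(
    mode = mode, times = times, z = geometry$z_m,
    tau_w = tau_w, pressure = pressure, radius = radius_hist,
    vms = if (fsi) list(layer1 = vms1, layer2 = vms2) else NULL,
    eps_center = eps_center, last_cycle = last,
    wss = wss_record(tau_w[, last, drop = FALSE], times[last], geometry$z_m),
    periodicity = periodicity,
    systole_time = times[last][which.max(v_last)],
    diastole_time = times[last][which.min(v_last)],
    subiters = subiters, states = states, wall = wall,
    conservation = list(
      eps_sum_drift = 0,   # eps_p is defined as 1 - eps_rbc identically
      rbc_mass_drift = if (mode == "two_phase") mass_drift else NA_real_,
      theta_min = if (mode == "two_phase")
        min(vapply(states, function(st) min(st$theta), numeric(1))) else NA_real_,
      theta_clips = if (mode == "two_phase")
        sum(vapply(states, function(st) st$theta_clips, integer(1))) else NA_integer_),
    cfg = cfg, geometry = geometry, waveform = waveform,
    params = if (mode == "two_phase") params else NULL,
    rheology = if (mode != "two_phase") rheology else NULL,
    outlet_pressure = outlet_pressure, fsi = fsi),
    class = "hemofsi_sim")
}

#' Rigid-wall transient solve over all stations
#'
#' Marches every centerline station through the cardiac-cycle schedule with
#' the instantaneous mixture flow rate (inlet waveform times inlet area)
#' conserved axially, assembling the axial pressure from the per-station
#' pressure gradients with the outlet anchored at `outlet_pressure`.
#'
#' @param geometry a [vessel_geometry()].
#' @param waveform a [fourier_waveform()].
#' @param params a [ktgf_params()] (two-phase mode).
#' @param mode `"two_phase"` or `"single_phase"`.
#' @param rheology a [single_phase_rheology()] (single-phase mode).
#' @param cfg a [coupling_config()] (its coupling fields are unused here).
#' @param outlet_pressure outlet pressure (Pa), default 8000.
#' @return A `hemofsi_sim` object; see [run_simulation()].
#' @export
solve_vessel <- function(geometry, waveform, params = ktgf_params(),
                         mode = c("two_phase", "single_phase"),
                         rheology = single_phase_rheology(),
                         cfg = coupling_config(), outlet_pressure = 8000) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(waveform, "fourier_waveform"))
  if (abs(waveform$T_cycle - cfg$T_cycle) > 1e-9)
    stop("solve_vessel: waveform period differs from cfg$T_cycle", call. = FALSE)
  march_vessel(geometry, waveform, params, mode, rheology, cfg,
               outlet_pressure, fsi = FALSE, material = NULL, external = NULL)
}

#' Two-way coupled cardiac-cycle simulation
#'
#' The full driver: `n_cycles` cardiac cycles at time step `dt`, each step
#' two-way coupled to the two-layer viscohyperelastic wall (unless
#' `fsi = FALSE`), with only the final cycle reported.  Periodicity of the
#' solution is logged as the relative L2 difference of the wall-shear field
#' between the last two cycles; systole/diastole snapshot instants are the
#' waveform argmax/argmin within the final cycle.
#'
#' @inheritParams solve_vessel
#' @param material a [wall_material()].
#' @param external outer-surface radial pressures (Pa) of wall layers 1 and 2.
#' @param fsi logical; `FALSE` gives a rigid-wall run.
#' @return An object of class `hemofsi_sim` with elements including
#'   `wss` (last-cycle [wss_record()]), `pressure`, `radius`, `vms`,
#'   `periodicity`, `systole_time`, `diastole_time`, `subiters`,
#'   `conservation`, and the final per-station fluid and wall states.
#' @export
run_simulation <- function(geometry, waveform, params = ktgf_params(),
                           mode = c("two_phase", "single_phase"),
                           rheology = single_phase_rheology(),
                           cfg = coupling_config(),
                           material = wall_material(),
                           external = c(3000, 800),
                           outlet_pressure = 8000, fsi = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(waveform, "fourier_waveform"))
  if (abs(waveform$T_cycle - cfg$T_cycle) > 1e-9)
    stop("run_simulation: waveform period differs from cfg$T_cycle", call. = FALSE)
  march_vessel(geometry, waveform, params, mode, rheology, cfg,
               outlet_pressure, fsi = fsi, material = material,
               external = external)
}

#' @export
print.hemofsi_sim <- function(x, ...) {
  cat(sprintf("hemofsi simulation (%s%s): %d stations x %d steps (%d cycles)\n",
              x$mode, if (x$fsi) ", two-way FSI" else ", rigid wall",
              length(x$z), length(x$times), x$cfg$n_cycles))
  lw <- x$tau_w[, x$last_cycle, drop = FALSE]
  i <- which(lw == max(lw), arr.ind = TRUE)[1, ]
  cat(sprintf("  last-cycle max WSS %.4g Pa at z = %g mm, t = %.3f s\n",
              max(lw), 1e3 * x$z[i[1]], x$times[x$last_cycle][i[2]]))
  if (!is.na(x$periodicity))
    cat(sprintf("  cycle-to-cycle periodicity (rel L2) %.3g\n", x$periodicity))
  invisible(x)
}
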