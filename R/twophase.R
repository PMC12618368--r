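#' Radial finite-volume grid for one axial station
#'
#' Cell-centered grid on \[0, R\] with `nr` cells: centers at
#' \eqn{r_j = (j - 1/2) h}, faces at \eqn{0, h, \dots, R}.  The axisymmetric
#' finite-volume scheme integrates over annular volumes \eqn{r_j h} (per unit
#' axial length and radian), so the axis face carries zero flux naturally.
#'
#' @param nr number of radial cells.
#' @param R lumen radius (m).
#' @return A list with `nr`, `R`, `h`, cell centers `r`, faces `r_face`.
#' @export
radial_grid <- function(nr, R) {
  if (nr < 4) stop("radial_grid: need at least 4 radial cells", call. = FALSE)
  if (R <= 0) stop("radial_grid: R must be > 0", call. = FALSE)
  h <- R / nr
  list(nr = nr, R = R, h = h, r = (seq_len(nr) - 0.5) * h,
       r_face = seq(0, R, length.out = nr + 1))
}

#' Radially resolved two-phase state at one station
#'
#' Holds the plasma and RBC axial velocity profiles, the RBC volume fraction,
#' the granular temperature, the axial pressure gradient and the station
#' pressure.  Initialisation mirrors the standard patch initialisation:
#' uniform RBC fraction `params$eps_init` and granular temperature
#' `params$theta_init`, fluid at rest.
#'
#' @param nr radial cells.
#' @param R lumen radius (m).
#' @param params a [ktgf_params()].
#' @return An object of class `two_phase_state`.
#' @export
two_phase_state <- function(nr, R, params = ktgf_params()) {
  structure(list(nr = nr, R = R,
                 v_p = rep(0, nr), v_rbc = rep(0, nr),
                 u_rbc = rep(0, nr + 1),
                 eps_rbc = rep(params$eps_init, nr),
                 theta = rep(params$theta_init, nr),
                 dpdz = 0, P = NA_real_, theta_clips = 0L),
            class = "two_phase_state")
}

#' @export
print.two_phase_state <- function(x, ...) {
  cat(sprintf("Two-phase station state: nr = %d, R = %g mm\n", x$nr, 1e3 * x$R))
  cat(sprintf("  v_p axis %.4g m/s | eps_rbc [%.4g, %.4g] | theta [%.3g, %.3g]\n",
              x$v_p[1], min(x$eps_rbc), max(x$eps_rbc),
              min(x$theta), max(x$theta)))
  cat(sprintf("  dpdz = %.5g Pa/m\n", x$dpdz))
  invisible(x)
}

#' Single-phase state at one station
#'
#' @param nr radial cells.
#' @param R lumen radius (m).
#' @return An object of class `single_phase_state`.
#' @export
single_phase_state <- function(nr, R) {
  structure(list(nr = nr, R = R, v = rep(0, nr), dpdz = 0, P = NA_real_),
            class = "single_phase_state")
}

# all KTGF closure fields evaluated on the cells of a state (lagged values)
closure_fields <- function(state, params) {
  eps <- state$eps_rbc
  eps_p <- 1 - eps
  g0 <- radial_distribution(eps, params$eps_max)
  th <- state$theta
  slip <- abs(state$v_rbc - state$v_p)
  list(
    eps = eps, eps_p = eps_p, g0 = g0,
    p_rbc = solids_pressure(eps, params$rho_rbc, th, params$e, g0),
    mu_rbc = shear_viscosity(eps, params$rho_rbc, params$d_rbc, g0,
                             params$e, th),
    lambda_rbc = bulk_viscosity(eps, params$rho_rbc, params$d_rbc, g0,
                                params$e, th),
    beta = drag_beta(eps, eps_p, params$rho_p, params$mu_p, slip,
                     params$d_rbc),
    diss = granular_dissipation_and_conductivity(eps, params$rho_rbc,
                                                 params$d_rbc, g0,
                                                 params$e, th))
}

# Johnson-Jackson specularity coefficient C such that the wall shear on the
# RBC phase is C * u_slip (evaluated with wall-adjacent cell values)
jj_wall_coefficient <- function(eps_n, g0_n, theta_n, params,
                                phi_spec = params$phi_spec) {
  pi * sqrt(3) / 6 * phi_spec * (eps_n / params$eps_max) *
    params$rho_rbc * g0_n * sqrt(theta_n)
}

# second-order one-sided wall gradient: v'(R) from wall value and the two
# wall-adjacent cell values (spacings h/2 and 3h/2); exact for quadratics
wall_gradient <- function(v_w, v_n, v_nm1, h) (8 * v_w - 9 * v_n + v_nm1) / (3 * h)

# RBC wall slip velocity implied by the Johnson-Jackson stress balance
# eps*mu*v'(R) = -C*v_w, with v'(R) the one-sided quadratic form
jj_slip_velocity <- function(C, eps_mu, v_n, v_nm1, h) {
  if (eps_mu <= 0) return(v_n)           # inviscid RBC phase: free slip
  eps_mu * (9 * v_n - v_nm1) / (3 * h) / (C + 8 * eps_mu / (3 * h))
}

# Advance the coupled plasma/RBC axial momentum equations one step.
# Implicit radial diffusion and drag exchange (theta-scheme on diffusion, drag
# fully implicit); pressure gradient either prescribed or determined so the
# mixture flow rate matches `flow_rate` (the system is affine in dpdz, so two
# right-hand sides give the exact match).
advance_momentum <- function(state, R, forcing, dt, params, cf,
                             theta_scheme = 1) {
  nr <- state$nr
  g <- radial_grid(nr, R)
  h <- g$h; r <- g$r; rf <- g$r_face
  eps <- cf$eps; eps_p <- cf$eps_p
  eps_floor <- pmax(eps, 1e-10)

  # diffusion operators L (such that momentum source = L %*% v)
  mu_face_p <- 0.5 * (eps_p[-nr] + eps_p[-1]) * params$mu_p
  emu_rbc <- eps * cf$mu_rbc
  mu_face_r <- 0.5 * (emu_rbc[-nr] + emu_rbc[-1])
  Dp <- rf[2:nr] * mu_face_p / h
  Dr <- rf[2:nr] * mu_face_r / h

  band_L <- function(D) {
    L <- matrix(0, nr, nr)
    for (j in seq_len(nr - 1)) {
      L[j, j] <- L[j, j] - D[j];     L[j, j + 1] <- L[j, j + 1] + D[j]
      L[j + 1, j + 1] <- L[j + 1, j + 1] - D[j]; L[j + 1, j] <- L[j + 1, j] + D[j]
    }
    L
  }
  Lp <- band_L(Dp)
  Lr <- band_L(Dr)
  # plasma wall face: no slip (Dirichlet 0), quadratic one-sided flux
  cw <- eps_p[nr] * params$mu_p * R / (3 * h)
  Lp[nr, nr] <- Lp[nr, nr] - 9 * cw
  Lp[nr, nr - 1] <- Lp[nr, nr - 1] + cw
  # RBC wall face: Johnson-Jackson partial slip
  C_jj <- jj_wall_coefficient(eps[nr], cf$g0[nr], state$theta[nr], params)
  em <- emu_rbc[nr]
  k_c <- if (em > 0) C_jj * (em / (3 * h)) / (C_jj + 8 * em / (3 * h)) else 0
  Lr[nr, nr] <- Lr[nr, nr] - 9 * R * k_c
  Lr[nr, nr - 1] <- Lr[nr, nr - 1] + R * k_c

  vol <- r * h
  Mp <- params$rho_p * eps_p * vol / dt
  Mr <- params$rho_rbc * eps_floor * vol / dt
  Bd <- cf$beta * vol

  n2 <- 2 * nr
  A <- matrix(0, n2, n2)
  ip <- seq_len(nr); ir <- nr + ip
  A[ip, ip] <- -theta_scheme * Lp
  A[ir, ir] <- -theta_scheme * Lr
  diag(A)[ip] <- diag(A)[ip] + Mp + Bd
  diag(A)[ir] <- diag(A)[ir] + Mr + Bd
  A[cbind(ip, ir)] <- A[cbind(ip, ir)] - Bd
  A[cbind(ir, ip)] <- A[cbind(ir, ip)] - Bd

  b0 <- c(Mp * state$v_p + (1 - theta_scheme) * as.vector(Lp %*% state$v_p),
          Mr * state$v_rbc + (1 - theta_scheme) * as.vector(Lr %*% state$v_rbc))
  bG <- c(-eps_p * vol, -eps * vol)   # sensitivity to unit dpdz

  if (!is.null(forcing$dpdz)) {
    v <- solve(A, b0 + forcing$dpdz * bG)
    dpdz <- forcing$dpdz
  } else if (!is.null(forcing$flow_rate)) {
    X <- solve(A, cbind(b0, bG))
    qmix <- function(v) 2 * pi * sum((eps_p * v[ip] + eps * v[ir]) * vol)
    q0 <- qmix(X[, 1]); q1 <- qmix(X[, 2])
    if (abs(q1) < .Machine$double.eps)
      stop("advance_momentum: degenerate pressure-gradient sensitivity", call. = FALSE)
    dpdz <- (forcing$flow_rate - q0) / q1
    v <- X[, 1] + dpdz * X[, 2]
  } else {
    stop("advance_momentum: forcing must provide `dpdz` or `flow_rate`", call. = FALSE)
  }
  state$v_p <- v[ip]
  state$v_rbc <- v[ir]
  state$dpdz <- dpdz
  state
}

# cell-centered radial gradient of an axial velocity profile (symmetry at the
# axis; one-sided quadratic with the wall value at the last cell)
cell_gradient <- function(v, h, v_wall) {
  nr <- length(v)
  dv <- numeric(nr)
  dv[1] <- (v[2] - v[1]) / (2 * h)          # ghost mirror across the axis
  if (nr > 2) dv[2:(nr - 1)] <- (v[3:nr] - v[1:(nr - 2)]) / (2 * h)
  dv[nr] <- (v_wall - v[nr - 1]) / (2 * h)  # centered using the wall value
  dv
}

#' Advance the granular-temperature balance one step
#'
#' Semi-implicit, positivity-preserving update of the RBC fluctuation energy:
#' shear production (explicit, nonnegative), radial conduction (implicit),
#' collisional dissipation and interphase exchange \eqn{\Phi = -3\beta\theta}
#' (implicit, linearised in \eqn{\theta}), plus the Johnson-Jackson wall flux
#' (slip production minus inelastic wall dissipation).
#'
#' @param state a [two_phase_state()] with current velocities.
#' @param dt time step (s).
#' @param params a [ktgf_params()].
#' @param include_exchange include the interphase exchange sink
#'   \eqn{\Phi = -3\beta\theta} (default); `FALSE` isolates the
#'   production/dissipation/conduction balance (diagnostics and limit tests).
#' @return The state with updated `theta` (>= 0 everywhere).
#' @export
step_granular_temperature <- function(state, dt, params,
                                      include_exchange = TRUE) {
  nr <- state$nr
  g <- radial_grid(nr, state$R)
  h <- g$h; r <- g$r; rf <- g$r_face
  cf <- closure_fields(state, params)
  eps <- cf$eps
  vol <- r * h

  C_jj <- jj_wall_coefficient(eps[nr], cf$g0[nr], state$theta[nr], params)
  em <- eps[nr] * cf$mu_rbc[nr]
  v_w <- jj_slip_velocity(C_jj, em, state$v_rbc[nr], state$v_rbc[nr - 1], h)

  dvr <- cell_gradient(state$v_rbc, h, v_w)
  prod <- eps * cf$mu_rbc * dvr^2                     # tau_rz * dv/dr, >= 0

  cap <- 1.5 * params$rho_rbc * pmax(eps, 1e-10) * vol
  # linearised sinks: gamma = G1 * theta^(3/2) -> (G1 sqrt(theta_old)) * theta
  G1 <- 12 * (1 - params$e^2) * cf$g0 * params$rho_rbc * eps^2 /
    (params$d_rbc * sqrt(pi))
  sink <- (G1 * sqrt(state$theta) +
             if (include_exchange) 3 * cf$beta else 0) * vol

  kf <- 0.5 * (cf$diss$k_s[-nr] + cf$diss$k_s[-1])
  Dk <- rf[2:nr] * kf / h

  A <- matrix(0, nr, nr)
  for (j in seq_len(nr - 1)) {
    A[j, j] <- A[j, j] + Dk[j];     A[j, j + 1] <- A[j, j + 1] - Dk[j]
    A[j + 1, j + 1] <- A[j + 1, j + 1] + Dk[j]; A[j + 1, j] <- A[j + 1, j] - Dk[j]
  }
  diag(A) <- diag(A) + cap / dt + sink

  b <- cap / dt * state$theta + prod * vol
  # Johnson-Jackson wall energy flux: slip production (explicit) minus
  # inelastic wall dissipation (implicit, linearised)
  q_prod <- C_jj * v_w^2
  D_wall <- pi * sqrt(3) / 4 * (1 - params$e_wall^2) *
    (eps[nr] / params$eps_max) * params$rho_rbc * cf$g0[nr] *
    sqrt(state$theta[nr])
  b[nr] <- b[nr] + state$R * q_prod
  A[nr, nr] <- A[nr, nr] + state$R * D_wall

  th <- solve(A, b)
  neg <- th < 0
  if (any(neg)) {
    state$theta_clips <- state$theta_clips + sum(neg)
    th[neg] <- 0
  }
  state$theta <- th
  state
}

# terminal radial drift of the RBC phase (solids-pressure gradient balanced
# against drag) and conservative upwind transport of the volume fraction
advance_eps <- function(state, dt, params, cf) {
  nr <- state$nr
  g <- radial_grid(nr, state$R)
  h <- g$h; r <- g$r; rf <- g$r_face
  eps <- state$eps_rbc
  p_rbc <- solids_pressure(eps, params$rho_rbc, state$theta, params$e,
                           radial_distribution(eps, params$eps_max))
  dP <- (p_rbc[-1] - p_rbc[-nr]) / h
  beta_f <- 0.5 * (cf$beta[-nr] + cf$beta[-1])
  u <- ifelse(beta_f > 0, -dP / beta_f, 0)

  cfl <- max(abs(u)) * dt / h
  if (cfl > 0.9)
    stop(sprintf(paste0("advance_eps: RBC drift CFL %.3g > 0.9; ",
                        "reduce dt to <= %.3g s"), cfl, 0.45 * h / max(abs(u))),
         call. = FALSE)
  u <- pmax(pmin(u, 0.45 * h / dt), -0.45 * h / dt)

  eps_up <- ifelse(u > 0, eps[-nr], eps[-1])
  flux <- c(0, rf[2:nr] * u * eps_up, 0)   # zero flux at axis and wall
  eps_new <- eps - dt / (r * h) * (flux[-1] - flux[-(nr + 1)])
  if (any(eps_new >= params$eps_max - 1e-9))
    stop("advance_eps: RBC volume fraction reached the packing limit", call. = FALSE)
  state$eps_rbc <- pmax(eps_new, 0)
  state$u_rbc <- c(0, u, 0)
  state
}

#' Advance a two-phase station state by one time step
#'
#' One semi-implicit step of the reduced (locally fully developed,
#' radially resolved) two-phase equations: coupled plasma/RBC axial momentum
#' with implicit radial diffusion and drag exchange, granular-temperature
#' balance, then RBC radial drift and volume-fraction transport.  Nonlinear
#' closures are lagged one step.  The plasma volume fraction is `1 - eps_rbc`
#' by construction, so the phase fractions sum to one to machine precision.
#'
#' @param state a [two_phase_state()].
#' @param R lumen radius for this step (m); may differ from the previous step
#'   under wall motion (velocity profiles are carried on the normalised grid).
#' @param forcing a list with either `flow_rate` (m^3/s, mixture) or `dpdz`
#'   (Pa/m); `dpdz` may also be a function of time if used via [solve_vessel()].
#' @param dt time step (s), > 0.
#' @param params a [ktgf_params()].
#' @param theta_scheme implicitness of the diffusion terms: 1 = backward
#'   Euler (default, robust), 0.5 = Crank-Nicolson (second order in time).
#' @return The advanced `two_phase_state`.
#' @export
step_station <- function(state, R, forcing, dt, params,
                         theta_scheme = 1) {
  stopifnot(inherits(state, "two_phase_state"))
  if (dt <= 0) stop("step_station: dt must be > 0", call. = FALSE)
  state$R <- R
  cf <- closure_fields(state, params)
  state <- advance_momentum(state, R, forcing, dt, params, cf, theta_scheme)
  state <- step_granular_temperature(state, dt, params)
  state <- advance_eps(state, dt, params, cf)
  state
}

#' Advance a single-phase station state by one time step
#'
#' Same radial finite-volume scheme as the two-phase solver, with a single
#' momentum equation and the configured viscosity law.  Shear-thinning laws
#' (power-law, Quemada) are handled by Picard iteration on the lagged
#' strain-rate field.
#'
#' @param state a [single_phase_state()].
#' @param R lumen radius (m).
#' @param forcing list with `flow_rate` (m^3/s) or `dpdz` (Pa/m).
#' @param dt time step (s).
#' @param rheology a [single_phase_rheology()].
#' @param theta_scheme implicitness (1 = backward Euler, 0.5 = CN).
#' @param picard_tol,picard_max Picard stopping tolerance (relative velocity
#'   change) and iteration cap.
#' @return The advanced `single_phase_state`.
#' @export
step_station_single <- function(state, R, forcing, dt, rheology,
                                theta_scheme = 1,
                                picard_tol = 1e-10, picard_max = 40) {
  stopifnot(inherits(state, "single_phase_state"))
  if (dt <= 0) stop("step_station_single: dt must be > 0", call. = FALSE)
  state$R <- R
  nr <- state$nr
  g <- radial_grid(nr, R)
  h <- g$h; r <- g$r; rf <- g$r_face
  vol <- r * h
  v_iter <- state$v
  newtonian <- rheology$model == "newtonian"
  for (it in seq_len(if (newtonian) 1 else picard_max)) {
    gam <- abs(cell_gradient(v_iter, h, 0))
    mu <- single_phase_viscosity(gam, rheology)
    mu_face <- 0.5 * (mu[-nr] + mu[-1])
    D <- rf[2:nr] * mu_face / h
    L <- matrix(0, nr, nr)
    for (j in seq_len(nr - 1)) {
      L[j, j] <- L[j, j] - D[j];     L[j, j + 1] <- L[j, j + 1] + D[j]
      L[j + 1, j + 1] <- L[j + 1, j + 1] - D[j]; L[j + 1, j] <- L[j + 1, j] + D[j]
    }
    gw <- abs(wall_gradient(0, v_iter[nr], v_iter[nr - 1], h))
    cw <- single_phase_viscosity(gw, rheology) * R / (3 * h)
    L[nr, nr] <- L[nr, nr] - 9 * cw
    L[nr, nr - 1] <- L[nr, nr - 1] + cw

    M <- rheology$rho * vol / dt
    A <- -theta_scheme * L
    diag(A) <- diag(A) + M
    b0 <- M * state$v + (1 - theta_scheme) * as.vector(L %*% state$v)
    bG <- -vol
    if (!is.null(forcing$dpdz)) {
      v_new <- solve(A, b0 + forcing$dpdz * bG)
      dpdz <- forcing$dpdz
    } else {
      X <- solve(A, cbind(b0, bG))
      q0 <- 2 * pi * sum(X[, 1] * vol); q1 <- 2 * pi * sum(X[, 2] * vol)
      dpdz <- (forcing$flow_rate - q0) / q1
      v_new <- X[, 1] + dpdz * X[, 2]
    }
    dv <- max(abs(v_new - v_iter)) / max(max(abs(v_new)), 1e-12)
    v_iter <- v_new
    if (newtonian || dv < picard_tol) break
  }
  state$v <- v_iter
  state$dpdz <- dpdz
  state
}

#' Wall shear stress of a station state
#'
#' \eqn{\tau_w = -\mu_{eff} \, \partial v/\partial r |_{r=R}} with a
#' second-order one-sided difference; the sign follows the axial flow
#' direction (positive for forward flow).  In two-phase mode the wall traction
#' sums the phase-weighted plasma and granular contributions, with the RBC
#' wall value taken from the Johnson-Jackson slip balance.
#'
#' @param state a [two_phase_state()] or [single_phase_state()].
#' @param params a [ktgf_params()] (two-phase states).
#' @param rheology a [single_phase_rheology()] (single-phase states).
#' @return Signed wall shear stress (Pa).
#' @export
wall_shear_stress <- function(state, params = NULL, rheology = NULL) {
  nr <- state$nr
  h <- state$R / nr
  if (inherits(state, "two_phase_state")) {
    stopifnot(!is.null(params))
    cf <- closure_fields(state, params)
    dvp <- wall_gradient(0, state$v_p[nr], state$v_p[nr - 1], h)
    C_jj <- jj_wall_coefficient(cf$eps[nr], cf$g0[nr], state$theta[nr], params)
    em <- cf$eps[nr] * cf$mu_rbc[nr]
    v_w <- jj_slip_velocity(C_jj, em, state$v_rbc[nr], state$v_rbc[nr - 1], h)
    dvr <- wall_gradient(v_w, state$v_rbc[nr], state$v_rbc[nr - 1], h)
    -(cf$eps_p[nr] * params$mu_p * dvp + em * dvr)
  } else {
    stopifnot(!is.null(rheology))
    dv <- wall_gradient(0, state$v[nr], state$v[nr - 1], h)
    -single_phase_viscosity(abs(dv), rheology) * dv
  }
}

#' RBC wall slip velocity of a two-phase state
#'
#' Diagnostic: the Johnson-Jackson partial-slip wall velocity of the RBC
#' phase implied by the current profile.
#'
#' @param state a [two_phase_state()].
#' @param params a [ktgf_params()].
#' @param phi_spec optionally override the specularity coefficient.
#' @return Wall slip velocity (m/s).
#' @export
rbc_wall_slip <- function(state, params, phi_spec = params$phi_spec) {
  nr <- state$nr
  h <- state$R / nr
  cf <- closure_fields(state, params)
  C_jj <- jj_wall_coefficient(cf$eps[nr], cf$g0[nr], state$theta[nr], params,
                              phi_spec = phi_spec)
  jj_slip_velocity(C_jj, cf$eps[nr] * cf$mu_rbc[nr],
                   state$v_rbc[nr], state$v_rbc[nr - 1], h)
}

#' Viscosity diagnostics of a two-phase state
#'
#' Two complementary radial viscosity profiles:
#' * `momentum`: the momentum-equation coefficient sum
#'   \eqn{\epsilon_p \mu_p + \epsilon_{RBC} \mu_{RBC}(r)} — what the two-phase
#'   equations actually diffuse momentum with;
#' * `apparent`: the apparent suspension viscosity of the local composition,
#'   i.e. the Quemada law evaluated at the local haematocrit
#'   \eqn{H(r) = \epsilon_{RBC}(r)} and local shear rate — the quantity the
#'   Fåhræus–Lindqvist effect is phrased in (cell depletion near the wall
#'   lowers the apparent viscosity there).
#'
#' @param state a [two_phase_state()].
#' @param params a [ktgf_params()].
#' @param gamma_ref reference shear rate (1/s) at which the apparent
#'   (composition) viscosity is evaluated, so that radial variation of the
#'   `apparent` column reflects haematocrit alone and not shear thinning;
#'   `NULL` uses the local shear rate instead.
#' @return A data.frame with columns `r_m, eps_rbc, momentum, apparent` (Pa s).
#' @export
mixture_viscosity <- function(state, params, gamma_ref = 100) {
  stopifnot(inherits(state, "two_phase_state"))
  g <- radial_grid(state$nr, state$R)
  cf <- closure_fields(state, params)
  gam <- if (is.null(gamma_ref)) abs(cell_gradient(state$v_p, g$h, 0))
  else rep(gamma_ref, state$nr)
  app <- vapply(seq_len(state$nr), function(j) {
    rh <- single_phase_rheology("quemada", H = state$eps_rbc[j],
                                eta_p = params$mu_p)
    single_phase_viscosity(gam[j], rh)
  }, numeric(1))
  data.frame(r_m = g$r, eps_rbc = state$eps_rbc,
             momentum = cf$eps_p * params$mu_p + cf$eps * cf$mu_rbc,
             apparent = app)
}
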