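#' Kinetic-theory parameter set for the red-blood-cell phase
#'
#' Bundles the granular-phase constants and the phase material properties used
#' by every kinetic-theory-of-granular-flow (KTGF) closure.  Defaults are the
#' standard simulation conditions for whole blood at 45% haematocrit: plasma is
#' the continuous Newtonian phase, RBCs are rigid 8 micron spheres with a
#' near-elastic restitution coefficient.
#'
#' @param d_rbc RBC particle diameter (m).
#' @param rho_rbc RBC density (kg/m^3).
#' @param rho_p plasma density (kg/m^3).
#' @param mu_p plasma dynamic viscosity (Pa s).
#' @param e particle-particle restitution coefficient, in (0, 1].
#' @param eps_max RBC volume fraction at maximum packing.
#' @param e_wall particle-wall restitution coefficient, in (0, 1].
#' @param phi_spec specularity coefficient of the Johnson-Jackson wall
#'   condition, in [0, 1] (0 = free slip, 1 = fully diffuse collisions).
#' @param eps_init initial (patch) RBC volume fraction.
#' @param theta_init initial granular temperature (m^2/s^2).
#' @return An object of class `ktgf_params` (a validated named list).
#' @examples
#' p <- ktgf_params()
#' p$d_rbc
#' @export
ktgf_params <- function(d_rbc = 8e-6, rho_rbc = 1096, rho_p = 1003,
                        mu_p = 0.001, e = 0.99999, eps_max = 0.7,
                        e_wall = 0.9999, phi_spec = 0.6,
                        eps_init = 0.45, theta_init = 1e-4) {
  p <- list(d_rbc = d_rbc, rho_rbc = rho_rbc, rho_p = rho_p, mu_p = mu_p,
            e = e, eps_max = eps_max, e_wall = e_wall, phi_spec = phi_spec,
            eps_init = eps_init, theta_init = theta_init)
  for (nm in c("d_rbc", "rho_rbc", "rho_p", "mu_p", "eps_max"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("ktgf_params: `", nm, "` must be strictly positive", call. = FALSE)
  if (e <= 0 || e > 1) stop("ktgf_params: restitution `e` must be in (0, 1]", call. = FALSE)
  if (e_wall <= 0 || e_wall > 1) stop("ktgf_params: `e_wall` must be in (0, 1]", call. = FALSE)
  if (eps_max >= 1) stop("ktgf_params: packing limit `eps_max` must be < 1", call. = FALSE)
  if (phi_spec < 0 || phi_spec > 1)
    stop("ktgf_params: specularity `phi_spec` must be in [0, 1]", call. = FALSE)
  if (eps_init < 0 || eps_init >= eps_max)
    stop("ktgf_params: `eps_init` must satisfy 0 <= eps_init < eps_max", call. = FALSE)
  if (theta_init < 0) stop("ktgf_params: `theta_init` must be >= 0", call. = FALSE)
  structure(p, class = "ktgf_params")
}

#' @export
print.ktgf_params <- function(x, ...) {
  cat("KTGF parameter set (plasma + RBC granular phase)\n")
  cat(sprintf("  RBC: d = %g m, rho = %g kg/m^3, e = %g, eps_max = %g\n",
              x$d_rbc, x$rho_rbc, x$e, x$eps_max))
  cat(sprintf("  plasma: rho = %g kg/m^3, mu = %g Pa s\n", x$rho_p, x$mu_p))
  cat(sprintf("  wall: e_wall = %g, specularity = %g\n", x$e_wall, x$phi_spec))
  cat(sprintf("  init: eps = %g, theta = %g m^2/s^2\n", x$eps_init, x$theta_init))
  invisible(x)
}

#' Radial distribution function at contact
#'
#' Collision-probability correction for the granular phase,
#' \eqn{g_0 = [1 - (\epsilon/\epsilon_{max})^{1/3}]^{-1}}.  Equals 1 in the
#' dilute limit and diverges at the packing limit.
#'
#' @param eps_rbc RBC volume fraction (vectorised).
#' @param eps_max packing limit.
#' @return g0 (dimensionless), >= 1.
#' @export
radial_distribution <- function(eps_rbc, eps_max = 0.7) {
  if (any(eps_rbc < 0)) stop("radial_distribution: eps_rbc must be >= 0", call. = FALSE)
  if (any(eps_rbc >= eps_max))
    stop("radial_distribution: eps_rbc at or above the packing limit; ",
         "closure diverges", call. = FALSE)
  1 / (1 - (eps_rbc / eps_max)^(1 / 3))
}

#' Granular (solids) pressure of the RBC phase
#'
#' \eqn{P_{RBC} = \epsilon \rho \theta + 2 \rho (1+e) \epsilon^2 g_0 \theta};
#' kinetic plus collisional contribution, linear in the granular temperature.
#'
#' @param eps_rbc RBC volume fraction.
#' @param rho_rbc RBC density (kg/m^3).
#' @param theta granular temperature (m^2/s^2).
#' @param e restitution coefficient.
#' @param g0 radial distribution value (from [radial_distribution()]).
#' @return Solids pressure (Pa).
#' @export
solids_pressure <- function(eps_rbc, rho_rbc, theta, e, g0) {
  stopifnot(all(eps_rbc >= 0), all(theta >= 0), all(e > 0), all(e <= 1))
  eps_rbc * rho_rbc * theta + 2 * rho_rbc * (1 + e) * eps_rbc^2 * g0 * theta
}

#' Granular bulk viscosity of the RBC phase
#'
#' \eqn{\lambda_{RBC} = (4/3) \epsilon \rho d g_0 (1+e) \sqrt{\theta/\pi}}.
#'
#' @inheritParams solids_pressure
#' @param d_rbc RBC diameter (m).
#' @return Bulk viscosity (Pa s).
#' @export
bulk_viscosity <- function(eps_rbc, rho_rbc, d_rbc, g0, e, theta) {
  stopifnot(all(eps_rbc >= 0), all(theta >= 0))
  (4 / 3) * eps_rbc * rho_rbc * d_rbc * g0 * (1 + e) * sqrt(theta / pi)
}

#' Granular shear viscosity of the RBC phase
#'
#' Sum of a collisional part proportional to \eqn{\epsilon^2} and a kinetic
#' part proportional to \eqn{1/g_0} with the dense-correction bracket:
#' \deqn{\mu_{RBC} = \frac{4}{5}\epsilon^2 \rho d g_0 (1+e)\sqrt{\theta/\pi}
#'   + \frac{10 \rho d \sqrt{\theta \pi}}{96 (1+e) g_0}
#'     \left[1 + \frac{4}{5} g_0 \epsilon (1+e)\right]^2.}
#' Both parts scale as \eqn{\sqrt\theta}.
#'
#' @inheritParams bulk_viscosity
#' @param parts if `TRUE`, return a list with `collisional`, `kinetic`, `total`.
#' @return Shear viscosity (Pa s), or a list when `parts = TRUE`.
#' @export
shear_viscosity <- function(eps_rbc, rho_rbc, d_rbc, g0, e, theta, parts = FALSE) {
  stopifnot(all(eps_rbc >= 0), all(theta >= 0))
  if (any(g0 <= 0)) stop("shear_viscosity: g0 must be > 0", call. = FALSE)
  coll <- (4 / 5) * eps_rbc^2 * rho_rbc * d_rbc * g0 * (1 + e) * sqrt(theta / pi)
  kin <- 10 * rho_rbc * d_rbc * sqrt(theta * pi) / (96 * (1 + e) * g0) *
    (1 + (4 / 5) * g0 * eps_rbc * (1 + e))^2
  if (parts) list(collisional = coll, kinetic = kin, total = coll + kin)
  else coll + kin
}

#' Particle Reynolds number of the slip flow around an RBC
#'
#' \eqn{Re_p = \rho_p d |v_{RBC} - v_p| / \mu_p}.
#'
#' @param rho_p plasma density (kg/m^3).
#' @param d_rbc RBC diameter (m).
#' @param slip_speed magnitude of the interphase slip velocity (m/s).
#' @param mu_p plasma viscosity (Pa s).
#' @return Re_p (dimensionless).
#' @export
particle_reynolds <- function(rho_p, d_rbc, slip_speed, mu_p) {
  if (any(mu_p <= 0)) stop("particle_reynolds: mu_p must be > 0", call. = FALSE)
  rho_p * d_rbc * abs(slip_speed) / mu_p
}

#' Drag coefficient of the dilute (Wen-Yu) branch
#'
#' \eqn{C_D = \frac{24}{\epsilon_p Re_p}[1 + 0.15 (\epsilon_p Re_p)^{0.687}]}.
#'
#' @param re_p particle Reynolds number, > 0.
#' @param eps_p plasma volume fraction, in (0, 1].
#' @return C_D (dimensionless).
#' @export
drag_cd <- function(re_p, eps_p) {
  if (any(re_p <= 0))
    stop("drag_cd: Re_p must be > 0 (the zero-slip limit is handled ",
         "analytically inside drag_beta)", call. = FALSE)
  stopifnot(all(eps_p > 0), all(eps_p <= 1))
  24 / (eps_p * re_p) * (1 + 0.15 * (eps_p * re_p)^0.687)
}

#' Gidaspow interphase momentum-exchange coefficient
#'
#' Piecewise drag law: the dense Ergun form for plasma fraction
#' \eqn{\epsilon_p \le 0.8},
#' \deqn{\beta = 150 \frac{\epsilon_{RBC}(1-\epsilon_p)\mu_p}{\epsilon_p d^2}
#'   + 1.75 \frac{\rho_p \epsilon_{RBC} |\Delta v|}{d},}
#' and the Wen-Yu form for \eqn{\epsilon_p > 0.8},
#' \deqn{\beta = \frac{3}{4} C_D
#'   \frac{\epsilon_{RBC}\epsilon_p \rho_p |\Delta v|}{d} \epsilon_p^{-2.65}.}
#' The switch at 0.8 is a hard switch by default, matching the piecewise law;
#' `blend_width > 0` enables tanh blending across the branch boundary.
#' In the Wen-Yu branch zero slip returns beta = 0 directly: the slip factor
#' cancels the 1/Re_p singularity of C_D analytically.
#'
#' @param eps_rbc RBC volume fraction.
#' @param eps_p plasma volume fraction (must satisfy eps_p + eps_rbc = 1).
#' @param rho_p plasma density (kg/m^3).
#' @param mu_p plasma viscosity (Pa s).
#' @param slip_speed |v_RBC - v_p| (m/s).
#' @param d_rbc RBC diameter (m).
#' @param blend_width half-width of optional tanh blending of the branch
#'   switch in eps_p units; 0 (default) keeps the hard switch.
#' @return beta (kg m^-3 s^-1), >= 0.
#' @export
drag_beta <- function(eps_rbc, eps_p, rho_p, mu_p, slip_speed, d_rbc,
                      blend_width = 0) {
  if (any(abs(eps_p + eps_rbc - 1) > 1e-9))
    stop("drag_beta: volume fractions must sum to 1", call. = FALSE)
  if (any(d_rbc <= 0)) stop("drag_beta: d_rbc must be > 0", call. = FALSE)
  slip <- abs(slip_speed)
  ergun <- 150 * eps_rbc * (1 - eps_p) * mu_p / (eps_p * d_rbc^2) +
    1.75 * rho_p * eps_rbc * slip / d_rbc
  # Wen-Yu: (3/4) C_D eps eps_p rho |dv| / d * eps_p^-2.65 with C_D's 1/Re_p
  # singularity cancelled against the slip factor:
  re <- particle_reynolds(rho_p, d_rbc, slip, mu_p)
  epre <- eps_p * re
  wenyu <- 18 * eps_rbc * mu_p / d_rbc^2 * (1 + 0.15 * epre^0.687) *
    eps_p^(-2.65)
  if (blend_width > 0) {
    w <- 0.5 * (1 + tanh((eps_p - 0.8) / blend_width))
    out <- (1 - w) * ergun + w * wenyu
  } else {
    out <- ifelse(eps_p <= 0.8, ergun, wenyu)
  }
  out
}

#' Collisional dissipation and granular conductivity
#'
#' The granular-energy sink and diffusivity closing the granular-temperature
#' balance.  Dissipation uses the Lun form
#' \eqn{\gamma = 12 (1 - e^2) g_0 \rho \epsilon^2 \theta^{3/2} / (d \sqrt\pi)};
#' conductivity uses the Gidaspow form
#' \deqn{k_s = \frac{150 \rho d \sqrt{\theta\pi}}{384 (1+e) g_0}
#'  \left[1 + \frac{6}{5}\epsilon g_0 (1+e)\right]^2
#'  + 2 \rho \epsilon^2 d g_0 (1+e) \sqrt{\theta/\pi}.}
#' Both vanish as \eqn{\theta \to 0}; dissipation vanishes for elastic
#' collisions (e = 1).
#'
#' @inheritParams bulk_viscosity
#' @return A list with `gamma` (W/m^3) and `k_s` (kg m^-1 s^-1).
#' @export
granular_dissipation_and_conductivity <- function(eps_rbc, rho_rbc, d_rbc,
                                                  g0, e, theta) {
  stopifnot(all(eps_rbc >= 0), all(theta >= 0))
  gamma <- 12 * (1 - e^2) * g0 * rho_rbc * eps_rbc^2 * theta^(3 / 2) /
    (d_rbc * sqrt(pi))
  k_s <- 150 * rho_rbc * d_rbc * sqrt(theta * pi) / (384 * (1 + e) * g0) *
    (1 + (6 / 5) * eps_rbc * g0 * (1 + e))^2 +
    2 * rho_rbc * eps_rbc^2 * d_rbc * g0 * (1 + e) * sqrt(theta / pi)
  list(gamma = gamma, k_s = k_s)
}

#' Single-phase blood rheology description
#'
#' Container for the viscosity law used in single-phase comparator runs:
#' Newtonian (constant), power-law \eqn{\eta = k \dot\gamma^{n-1}}, or the
#' haematocrit-dependent Quemada model.  Power-law defaults are the standard
#' whole-blood fit (k = 0.035 Pa s^n, n = 0.6); Quemada defaults are the
#' literature-standard intrinsic-viscosity parameters.
#'
#' @param model one of `"newtonian"`, `"power_law"`, `"quemada"`.
#' @param mu Newtonian viscosity (Pa s), `model = "newtonian"` only.
#' @param k consistency index (Pa s^n).
#' @param n power-law index.
#' @param H haematocrit (RBC volume fraction) for the Quemada model.
#' @param eta_p plasma viscosity (Pa s) for the Quemada model.
#' @param k0,k_inf,gamma_c Quemada intrinsic viscosities at zero/infinite
#'   shear and the critical shear rate (1/s).
#' @param rho fluid density (kg/m^3); whole-blood default 1050.
#' @param gamma_floor strain-rate floor (1/s) guarding the shear-thinning
#'   laws against the singular zero-shear limit.
#' @return An object of class `single_phase_rheology`.
#' @export
single_phase_rheology <- function(model = c("power_law", "newtonian", "quemada"),
                                  mu = 0.00345, k = 0.035, n = 0.6,
                                  H = 0.45, eta_p = 0.001,
                                  k0 = 4.33, k_inf = 1.88, gamma_c = 1.82,
                                  rho = 1050, gamma_floor = 1e-6) {
  model <- match.arg(model)
  if (n <= 0) stop("single_phase_rheology: power-law index n must be > 0", call. = FALSE)
  if (H < 0 || H >= 1) stop("single_phase_rheology: haematocrit H must be in [0, 1)", call. = FALSE)
  if (gamma_floor <= 0) stop("single_phase_rheology: gamma_floor must be > 0", call. = FALSE)
  structure(list(model = model, mu = mu, k = k, n = n, H = H, eta_p = eta_p,
                 k0 = k0, k_inf = k_inf, gamma_c = gamma_c, rho = rho,
                 gamma_floor = gamma_floor),
            class = "single_phase_rheology")
}

#' @export
print.single_phase_rheology <- function(x, ...) {
  cat("Single-phase blood rheology:", x$model, "\n")
  if (x$model == "newtonian") cat(sprintf("  mu = %g Pa s\n", x$mu))
  if (x$model == "power_law") cat(sprintf("  k = %g Pa s^n, n = %g\n", x$k, x$n))
  if (x$model == "quemada")
    cat(sprintf("  H = %g, eta_p = %g, k0 = %g, k_inf = %g, gamma_c = %g 1/s\n",
                x$H, x$eta_p, x$k0, x$k_inf, x$gamma_c))
  invisible(x)
}

#' Apparent viscosity of a single-phase blood model
#'
#' Evaluates the configured viscosity law at the given strain rate.  The
#' power-law returns \eqn{k\dot\gamma^{n-1}}; Quemada returns
#' \eqn{\eta_p (1 - \tfrac12 k(\dot\gamma) H)^{-2}} with
#' \eqn{k(\dot\gamma) = (k_0 + k_\infty\sqrt{\dot\gamma/\gamma_c}) /
#' (1 + \sqrt{\dot\gamma/\gamma_c})}.  Strain rates below the configured floor
#' are clamped to it, so the shear-thinning laws stay finite at zero shear.
#'
#' @param strain_rate shear rate \eqn{\dot\gamma} (1/s), vectorised.
#' @param rheology a [single_phase_rheology()] object.
#' @return Viscosity (Pa s), finite and positive.
#' @export
single_phase_viscosity <- function(strain_rate, rheology) {
  stopifnot(inherits(rheology, "single_phase_rheology"))
  g <- pmax(abs(strain_rate), rheology$gamma_floor)
  switch(rheology$model,
    newtonian = rep(rheology$mu, length(g)),
    power_law = rheology$k * g^(rheology$n - 1),
    quemada = {
      s <- sqrt(g / rheology$gamma_c)
      kq <- (rheology$k0 + rheology$k_inf * s) / (1 + s)
      denom <- 1 - 0.5 * kq * rheology$H
      if (any(denom <= 0))
        stop("single_phase_viscosity: Quemada model diverges ",
             "(k * H / 2 >= 1); reduce haematocrit or k0", call. = FALSE)
      rheology$eta_p / denom^2
    })
}
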