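#' Five-parameter Mooney-Rivlin material constants
#'
#' Polynomial hyperelastic strain-energy model in the isochoric invariants,
#' \deqn{W = C_{10}(\bar I_1 - 3) + C_{01}(\bar I_2 - 3) + C_{20}(\bar I_1-3)^2
#'  + C_{11}(\bar I_1-3)(\bar I_2-3) + C_{02}(\bar I_2-3)^2
#'  + \tfrac{1}{d}(J-1)^2.}
#' Constants are in MPa; signs are unrestricted (fitted arterial constants are
#' frequently negative term-by-term), but the tangent shear modulus
#' \eqn{2(C_{10}+C_{01})} at the reference state must be positive.
#'
#' @param c10,c01,c20,c11,c02 material constants (MPa).
#' @param d incompressibility parameter (1/Pa); 0 selects exact
#'   incompressibility (volumetric term undefined away from J = 1).
#' @return An object of class `mooney_rivlin`.
#' @export
mooney_rivlin <- function(c10, c01, c20, c11, c02, d = 0) {
  vals <- c(c10, c01, c20, c11, c02, d)
  if (any(!is.finite(vals))) stop("mooney_rivlin: constants must be finite", call. = FALSE)
  if (d < 0) stop("mooney_rivlin: d must be >= 0", call. = FALSE)
  if (c10 + c01 <= 0)
    stop("mooney_rivlin: tangent shear modulus 2(C10 + C01) must be positive",
         call. = FALSE)
  structure(list(c10 = c10, c01 = c01, c20 = c20, c11 = c11, c02 = c02, d = d),
            class = "mooney_rivlin")
}

#' Principal-stretch state
#'
#' Kinematic container: volume ratio \eqn{J = \lambda_1\lambda_2\lambda_3},
#' invariants \eqn{I_1 = \sum \lambda_i^2},
#' \eqn{I_2 = \sum_{i<j} \lambda_i^2\lambda_j^2}, and their isochoric
#' counterparts \eqn{\bar I_1 = J^{-2/3} I_1}, \eqn{\bar I_2 = J^{-4/3} I_2}.
#'
#' @param lambda1,lambda2,lambda3 principal stretches, > 0.
#' @return An object of class `stretch_state`.
#' @export
stretch_state <- function(lambda1, lambda2, lambda3) {
  l <- c(lambda1, lambda2, lambda3)
  if (any(l <= 0)) stop("stretch_state: stretches must be > 0", call. = FALSE)
  J <- prod(l)
  I1 <- sum(l^2)
  I2 <- l[1]^2 * l[2]^2 + l[2]^2 * l[3]^2 + l[3]^2 * l[1]^2
  structure(list(lambda1 = l[1], lambda2 = l[2], lambda3 = l[3], J = J,
                 I1 = I1, I2 = I2,
                 I1bar = J^(-2 / 3) * I1, I2bar = J^(-4 / 3) * I2),
            class = "stretch_state")
}

#' Mooney-Rivlin strain-energy density
#'
#' @param s a [stretch_state()].
#' @param p a [mooney_rivlin()] parameter set.
#' @return Energy density (MPa); zero at the reference state.
#' @export
strain_energy <- function(s, p) {
  stopifnot(inherits(s, "stretch_state"), inherits(p, "mooney_rivlin"))
  a <- s$I1bar - 3
  b <- s$I2bar - 3
  W <- p$c10 * a + p$c01 * b + p$c20 * a^2 + p$c11 * a * b + p$c02 * b^2
  if (abs(s$J - 1) > 1e-12) {
    if (p$d == 0)
      stop("strain_energy: d = 0 (incompressible) requires J = 1", call. = FALSE)
    # d is in 1/Pa; convert the volumetric contribution to MPa
    W <- W + (1 / p$d) * (s$J - 1)^2 * 1e-6
  }
  W
}

# dW/dI1bar and dW/dI2bar at given isochoric invariants
mr_derivs <- function(I1b, I2b, p) {
  a <- I1b - 3
  b <- I2b - 3
  list(W1 = p$c10 + 2 * p$c20 * a + p$c11 * b,
       W2 = p$c01 + p$c11 * a + 2 * p$c02 * b)
}

#' Uniaxial Cauchy stress of an incompressible Mooney-Rivlin solid
#'
#' For a uniaxial stretch \eqn{\lambda} with lateral stretches
#' \eqn{\lambda^{-1/2}} (J = 1):
#' \eqn{\sigma = 2(\lambda^2 - 1/\lambda)(W_1 + W_2/\lambda)}, with
#' \eqn{W_1, W_2} the analytic invariant derivatives.
#'
#' @param lambda axial stretch, > 0 (vectorised).
#' @param p a [mooney_rivlin()].
#' @return Cauchy stress (MPa); zero at lambda = 1.
#' @export
uniaxial_cauchy_stress <- function(lambda, p) {
  stopifnot(inherits(p, "mooney_rivlin"))
  if (any(lambda <= 0)) stop("uniaxial_cauchy_stress: lambda must be > 0", call. = FALSE)
  I1 <- lambda^2 + 2 / lambda
  I2 <- 2 * lambda + 1 / lambda^2
  d <- mr_derivs(I1, I2, p)
  2 * (lambda^2 - 1 / lambda) * (d$W1 + d$W2 / lambda)
}

# hoop-minus-radial Cauchy stress difference for a tube wall element with
# stretches (1/lambda, lambda, 1) (incompressible, axial stretch fixed at 1)
hoop_stress_difference <- function(lambda, p) {
  I <- lambda^2 + 1 + 1 / lambda^2   # I1 = I2 for this stretch state
  d <- mr_derivs(I, I, p)
  2 * (lambda^2 - 1 / lambda^2) * (d$W1 + d$W2)
}

# axial-minus-radial Cauchy stress difference for the same stretch state
axial_stress_difference <- function(lambda, p) {
  I <- lambda^2 + 1 + 1 / lambda^2
  d <- mr_derivs(I, I, p)
  2 * d$W1 * (1 - 1 / lambda^2) - 2 * d$W2 * (1 - lambda^2)
}

#' Five-term Prony shear-relaxation parameters
#'
#' Normalised relaxation modulus
#' \eqn{G(t) = G_0[\alpha_\infty + \sum_i \alpha_i e^{-t/\tau_i}]} with
#' \eqn{\alpha_\infty = 1 - \sum_i \alpha_i} computed exactly from the loaded
#' moduli (and reported, since fitted arterial tables often sum to ~1,
#' implying a nearly fully relaxing long-term response).
#'
#' @param G0 instantaneous shear modulus (Pa).
#' @param alpha relative moduli (dimensionless, >= 0).
#' @param tau relaxation times (s), > 0.
#' @param quiet suppress the long-term-modulus message.
#' @return An object of class `prony_params` with `alpha_inf` filled in.
#' @export
prony_params <- function(G0, alpha, tau, quiet = FALSE) {
  if (length(alpha) != length(tau))
    stop("prony_params: alpha and tau must have equal length", call. = FALSE)
  if (any(tau <= 0)) stop("prony_params: relaxation times must be > 0", call. = FALSE)
  if (any(alpha < 0)) stop("prony_params: relative moduli must be >= 0", call. = FALSE)
  alpha_inf <- 1 - sum(alpha)
  if (!quiet)
    message(sprintf("prony_params: alpha_inf = 1 - sum(alpha) = %.6g; ",
                    alpha_inf),
            sprintf("long-term modulus G0*alpha_inf = %.6g Pa", G0 * alpha_inf))
  structure(list(G0 = G0, alpha = alpha, tau = tau, alpha_inf = alpha_inf),
            class = "prony_params")
}

#' Prony relaxation modulus
#'
#' @param t time(s) >= 0 (vectorised).
#' @param p a [prony_params()].
#' @return G(t) (Pa), monotone non-increasing.
#' @export
prony_relaxation_modulus <- function(t, p) {
  stopifnot(inherits(p, "prony_params"))
  if (any(t < 0)) stop("prony_relaxation_modulus: t must be >= 0", call. = FALSE)
  vapply(t, function(ti)
    p$G0 * (p$alpha_inf + sum(p$alpha * exp(-ti / p$tau))), numeric(1))
}

#' Incremental viscoelastic stress update
#'
#' Advances the hereditary deviatoric stress
#' \eqn{\sigma(t) = \int_0^t 2 G(t-s)\,\dot e\,ds} by the exact exponential
#' recursion per Prony term (exact for strain piecewise linear in time; a
#' strain jump is applied with `dt = 0`).  The bulk (volumetric) relaxation
#' term is omitted throughout the package.
#'
#' @param de deviatoric strain increment over the step (scalar component).
#' @param dt step duration (s), >= 0; `dt = 0` applies `de` as a jump.
#' @param vars internal-variable list from a previous call, or `NULL` to
#'   start from virgin state (zero strain, zero stress).
#' @param p a [prony_params()].
#' @return A list with `stress` (Pa) and the updated `vars`
#'   (`e`: accumulated strain; `s`: per-term stresses).
#' @export
viscoelastic_stress_update <- function(de, dt, vars, p) {
  stopifnot(inherits(p, "prony_params"))
  if (dt < 0) stop("viscoelastic_stress_update: dt must be >= 0", call. = FALSE)
  if (is.null(vars)) vars <- list(e = 0, s = rep(0, length(p$alpha)))
  if (dt == 0) {
    decay <- rep(1, length(p$tau))
    load <- rep(1, length(p$tau))
  } else {
    x <- dt / p$tau
    decay <- exp(-x)
    load <- (1 - decay) / x      # exact for linear strain over the step
  }
  vars$s <- decay * vars$s + 2 * p$G0 * p$alpha * load * de
  vars$e <- vars$e + de
  list(stress = 2 * p$G0 * p$alpha_inf * vars$e + sum(vars$s), vars = vars)
}

#' Von Mises stress
#'
#' \deqn{VMS = \sqrt{\tfrac12[(\sigma_1-\sigma_2)^2 + (\sigma_2-\sigma_3)^2 +
#'  (\sigma_3-\sigma_1)^2 + 6(\tau_{12}^2+\tau_{23}^2+\tau_{31}^2)]}.}
#' Invariant under addition of a hydrostatic stress to all normal components.
#'
#' @param sigma1,sigma2,sigma3 normal stresses (Pa).
#' @param tau12,tau23,tau31 shear stresses (Pa).
#' @return Von Mises equivalent stress (Pa).
#' @export
von_mises <- function(sigma1, sigma2, sigma3, tau12 = 0, tau23 = 0, tau31 = 0) {
  sqrt(((sigma1 - sigma2)^2 + (sigma2 - sigma3)^2 + (sigma3 - sigma1)^2 +
          6 * (tau12^2 + tau23^2 + tau31^2)) / 2)
}

#' Built-in wall material presets
#'
#' `"holzapfel_lcx"`: the two-layer coronary wall description used throughout
#' the package — five-parameter Mooney-Rivlin constants per layer (layer 1:
#' intima + transition zone; layer 2: media + adventitia) and the five-term
#' Prony shear-relaxation table for healthy coronary arterial tissue.  The
#' per-layer instantaneous shear modulus is taken as the Mooney-Rivlin tangent
#' \eqn{G_0 = 2(C_{10} + C_{01})} since no separate value is tabulated.
#'
#' @param name preset name.
#' @param stiffness_scale multiplier on all Mooney-Rivlin constants (e.g. 1e6
#'   approximates a rigid wall).
#' @param viscoelastic include the Prony description (`TRUE`) or elastic-only.
#' @return A list with `layer1`, `layer2` ([mooney_rivlin()]), `prony1`,
#'   `prony2` ([prony_params()] or `NULL`).
#' @export
wall_material <- function(name = "holzapfel_lcx", stiffness_scale = 1,
                          viscoelastic = TRUE) {
  if (name != "holzapfel_lcx")
    stop("wall_material: unknown preset `", name, "`", call. = FALSE)
  s <- stiffness_scale
  layer1 <- mooney_rivlin(-0.19 * s, 2.03 * s, 11.30 * s, -0.19 * s,
                          20.10 * s, d = 1e-5 / s)
  layer2 <- mooney_rivlin(-0.17 * s, 0.21 * s, 5.02 * s, -1.88 * s,
                          13.5 * s, d = 1e-5 / s)
  pr <- NULL
  if (viscoelastic) {
    alpha <- c(6.28e-13, 0.53, 7.15e-15, 0.47, 3.67e-16)
    tau <- c(10.906, 0.8558, 5.556, 27.358, 86.51)
    pr <- list(
      prony1 = prony_params(2 * (layer1$c10 + layer1$c01) * 1e6, alpha, tau,
                            quiet = TRUE),
      prony2 = prony_params(2 * (layer2$c10 + layer2$c01) * 1e6, alpha, tau,
                            quiet = TRUE))
  }
  list(layer1 = layer1, layer2 = layer2,
       prony1 = pr$prony1, prony2 = pr$prony2,
       name = name, stiffness_scale = stiffness_scale)
}

# fresh viscoelastic internal state for one station (2 layers x 2 deviatoric
# stress components: hoop-radial and axial-radial differences)
new_wall_visco_state <- function(material) {
  if (is.null(material$prony1)) return(NULL)
  empty <- list(e = 0, s = rep(0, length(material$prony1$alpha)))
  list(theta_r = list(empty, empty), z_r = list(empty, empty),
       S_prev = matrix(0, 2, 2))   # rows: layer; cols: (theta_r, z_r)
}

#' Quasi-static two-layer tube response
#'
#' Thin-wall (Laplace-law) inflation of the two concentric wall layers under
#' lumen pressure, with the stated constant radial tractions on each layer's
#' outer surface and the interlayer pressure as an internal unknown.  Both
#' layers share the circumferential stretch \eqn{\lambda} (thin-wall bonded
#' approximation, axial stretch 1, incompressible), found by root-solving the
#' summed equilibrium
#' \deqn{p_{lumen} - p_{ext,1} - p_{ext,2} = \sum_k S_k(\lambda)
#'   \frac{t_k/\lambda}{\lambda\, r_{k,0}},}
#' where \eqn{S_k} is layer k's hoop-radial Cauchy stress difference
#' (relaxed by the Prony description when viscoelastic state is supplied).
#'
#' @param p_lumen lumen pressure (Pa), the load on layer 1's inner surface.
#' @param station list with `R0` (reference lumen radius, m), `t1`, `t2`
#'   (layer thicknesses, m).
#' @param material a [wall_material()] list.
#' @param external outer-surface radial pressures (Pa) of layers 1 and 2;
#'   defaults c(3000, 800).
#' @param visco_state internal-variable state from a previous call (or `NULL`
#'   for elastic response / virgin viscoelastic state with `dt`).
#' @param dt time-step (s) for the viscoelastic update; `NULL` for purely
#'   elastic (rate-independent) response.
#' @return A `wall_state` list: `lambda`, `radius` (deformed inner radius, m),
#'   `p_interface` (Pa), per-layer principal Cauchy stresses
#'   (`sigma` matrix, rows = layer, cols = r/theta/z), `vms` per layer (Pa),
#'   and the updated `visco_state`.
#' @export
tube_response <- function(p_lumen, station, material,
                          external = c(3000, 800),
                          visco_state = NULL, dt = NULL) {
  if (p_lumen < 0) stop("tube_response: p_lumen must be >= 0", call. = FALSE)
  R0 <- station$R0
  t0 <- c(station$t1, station$t2)
  r0 <- c(R0 + t0[1] / 2, R0 + t0[1] + t0[2] / 2)  # reference mid-wall radii
  layers <- list(material$layer1, material$layer2)
  pronys <- list(material$prony1, material$prony2)
  visco <- !is.null(dt) && !is.null(material$prony1)
  if (visco && is.null(visco_state)) visco_state <- new_wall_visco_state(material)

  # relaxed stress difference for layer k at trial stretch lambda
  S_of <- function(lambda, k, comp) {
    S_el <- if (comp == 1) hoop_stress_difference(lambda, layers[[k]]) * 1e6
    else axial_stress_difference(lambda, layers[[k]]) * 1e6
    if (!visco) return(S_el)
    p <- pronys[[k]]
    # normalised quasi-linear relaxation on the elastic stress measure:
    # treat S_el as 2*G0*e and advance the normalised hereditary integral
    de <- (S_el - visco_state$S_prev[k, comp]) / (2 * p$G0)
    st <- visco_state[[comp]][[k]]
    up <- viscoelastic_stress_update(de, dt, st, p)
    up$stress
  }
  net_load <- p_lumen - external[1] - external[2]
  balance <- function(lambda)
    sum(vapply(1:2, function(k)
      S_of(lambda, k, 1) * (t0[k] / lambda) / (lambda * r0[k]), numeric(1))) -
      net_load
  lo <- 0.5; hi <- 2
  flo <- balance(lo); fhi <- balance(hi)
  tries <- 0
  while (flo * fhi > 0 && tries < 6) {
    lo <- lo * 0.7; hi <- hi * 1.4
    flo <- balance(lo); fhi <- balance(hi)
    tries <- tries + 1
  }
  if (flo * fhi > 0)
    stop(sprintf(paste0("tube_response: no equilibrium stretch in [%.3g, %.3g] ",
                        "for p_lumen = %.4g Pa (f(lo) = %.3g, f(hi) = %.3g)"),
                 lo, hi, p_lumen, flo, fhi), call. = FALSE)
  lambda <- stats::uniroot(balance, c(lo, hi), tol = 1e-12)$root

  # commit stresses (and the viscoelastic state) at the converged stretch
  S <- matrix(0, 2, 2)
  for (k in 1:2) for (comp in 1:2) {
    S_el <- if (comp == 1) hoop_stress_difference(lambda, layers[[k]]) * 1e6
    else axial_stress_difference(lambda, layers[[k]]) * 1e6
    if (visco) {
      p <- pronys[[k]]
      de <- (S_el - visco_state$S_prev[k, comp]) / (2 * p$G0)
      up <- viscoelastic_stress_update(de, dt, visco_state[[comp]][[k]], p)
      S[k, comp] <- up$stress
      visco_state[[comp]][[k]] <- up$vars
      visco_state$S_prev[k, comp] <- S_el
    } else {
      S[k, comp] <- S_el
    }
  }
  dp2 <- S[2, 1] * (t0[2] / lambda) / (lambda * r0[2])
  p_if <- external[2] + dp2
  p_in <- c(p_lumen, p_if)
  p_out <- c(p_if + external[1], external[2])
  sigma <- matrix(0, 2, 3, dimnames = list(paste0("layer", 1:2),
                                           c("r", "theta", "z")))
  vms <- numeric(2)
  for (k in 1:2) {
    sr <- -(p_in[k] + p_out[k]) / 2
    sigma[k, ] <- c(sr, sr + S[k, 1], sr + S[k, 2])
    vms[k] <- von_mises(sigma[k, 1], sigma[k, 2], sigma[k, 3])
  }
  structure(list(lambda = lambda, radius = lambda * R0, R0 = R0,
                 p_interface = p_if, sigma = sigma, vms = vms,
                 visco_state = visco_state),
            class = "wall_state")
}

#' @export
print.wall_state <- function(x, ...) {
  cat(sprintf("Wall state: lambda = %.6f, inner radius %.4f mm\n",
              x$lambda, 1e3 * x$radius))
  cat(sprintf("  interface pressure %.1f Pa; VMS layer1 %.3g Pa, layer2 %.3g Pa\n",
              x$p_interface, x$vms[1], x$vms[2]))
  invisible(x)
}
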