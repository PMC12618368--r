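# Independent oracles for the constitutive closures and analytic flows.
# Everything here is written from the governing formulas directly, in a
# different arrangement from the package code, and is used only to check it.

# --- KTGF closures, brute-force second implementations -----------------------

oracle_g0 <- function(eps, eps_max) {
  x <- (eps / eps_max)^(1 / 3)
  (1 - x)^(-1)
}

oracle_solids_pressure <- function(eps, rho, theta, e, g0) {
  term1 <- eps * rho * theta
  term2 <- 2 * rho * (1 + e) * eps * eps * g0 * theta
  term1 + term2
}

oracle_bulk_viscosity <- function(eps, rho, d, g0, e, theta) {
  4 / 3 * eps * rho * d * g0 * (1 + e) * sqrt(theta) / sqrt(pi)
}

oracle_shear_viscosity <- function(eps, rho, d, g0, e, theta) {
  coll <- 4 / 5 * eps * eps * rho * d * g0 * (1 + e) * sqrt(theta) / sqrt(pi)
  brack <- 1 + 4 / 5 * g0 * eps * (1 + e)
  kin <- (10 * rho * d * sqrt(pi * theta)) / (96 * (1 + e) * g0) * brack * brack
  coll + kin
}

oracle_re_p <- function(rho_p, d, slip, mu_p) rho_p * d * abs(slip) / mu_p

oracle_cd <- function(re, eps_p) {
  x <- eps_p * re
  (24 / x) * (1 + 0.15 * x^0.687)
}

oracle_beta <- function(eps, eps_p, rho_p, mu_p, slip, d) {
  if (eps_p <= 0.8) {
    150 * eps * (1 - eps_p) * mu_p / (eps_p * d * d) +
      1.75 * rho_p * eps * abs(slip) / d
  } else {
    re <- oracle_re_p(rho_p, d, slip, mu_p)
    if (re == 0) return(18 * eps * mu_p / d^2 * eps_p^(-2.65))
    0.75 * oracle_cd(re, eps_p) * eps * eps_p * rho_p * abs(slip) / d *
      eps_p^(-2.65)
  }
}

oracle_gamma_diss <- function(eps, rho, d, g0, e, theta) {
  12 * (1 - e * e) * g0 * rho * eps * eps * theta * sqrt(theta) / (d * sqrt(pi))
}

oracle_ks <- function(eps, rho, d, g0, e, theta) {
  (150 * rho * d * sqrt(pi * theta)) / (384 * (1 + e) * g0) *
    (1 + 1.2 * eps * g0 * (1 + e))^2 +
    2 * rho * eps * eps * d * g0 * (1 + e) * sqrt(theta) / sqrt(pi)
}

oracle_power_law <- function(gdot, k, n) k * gdot^(n - 1)

oracle_quemada <- function(gdot, H, eta_p, k0, k_inf, gc) {
  s <- sqrt(gdot / gc)
  kq <- (k0 + k_inf * s) / (1 + s)
  eta_p * (1 - 0.5 * kq * H)^(-2)
}

# Mooney-Rivlin strain energy (independent arrangement, isochoric invariants)
oracle_mr_energy <- function(l1, l2, l3, c) {
  J <- l1 * l2 * l3
  I1 <- l1^2 + l2^2 + l3^2
  I2 <- (l1 * l2)^2 + (l2 * l3)^2 + (l3 * l1)^2
  a <- J^(-2 / 3) * I1 - 3
  b <- J^(-4 / 3) * I2 - 3
  c$c10 * a + c$c01 * b + c$c20 * a * a + c$c11 * a * b + c$c02 * b * b
}

oracle_prony_G <- function(t, G0, alpha, tau) {
  a_inf <- 1 - sum(alpha)
  G0 * (a_inf + sum(alpha * exp(-t / tau)))
}

# direct trapezoid quadrature of the hereditary integral
# sigma(t) = int_0^t 2 G(t - s) de/ds ds for a given strain path e(s)
oracle_hereditary <- function(t_end, e_fun, G0, alpha, tau, n_fine = 20000) {
  s <- seq(0, t_end, length.out = n_fine + 1)
  de <- diff(e_fun(s))
  smid <- 0.5 * (s[-1] + s[-length(s)])
  Gv <- vapply(t_end - smid, oracle_prony_G, numeric(1),
               G0 = G0, alpha = alpha, tau = tau)
  sum(2 * Gv * de)
}

# --- Womersley analytic solution (complex Bessel series) ---------------------

cbessel_j0 <- function(z) {
  s <- 1 + 0i
  term <- 1 + 0i
  for (k in 1:80) {
    term <- term * (-z * z / 4) / (k * k)
    s <- s + term
  }
  s
}

cbessel_j1 <- function(z) {
  s <- 1 + 0i
  term <- 1 + 0i
  for (k in 1:80) {
    term <- term * (-z * z / 4) / (k * (k + 1))
    s <- s + term
  }
  (z / 2) * s
}

# oscillatory pressure-gradient flow dpdz = -G cos(om t) in a rigid tube:
# complex profile amplitude and wall-gradient amplitude
womersley_profile <- function(r, R, G, om, rho, mu) {
  alpha <- R * sqrt(om * rho / mu)
  bet <- complex(modulus = alpha, argument = 3 * pi / 4)  # i^(3/2) * alpha
  (G / (1i * rho * om)) * (1 - cbessel_j0(bet * r / R) / cbessel_j0(bet))
}

womersley_wall_dvdr <- function(R, G, om, rho, mu) {
  alpha <- R * sqrt(om * rho / mu)
  bet <- complex(modulus = alpha, argument = 3 * pi / 4)
  (G / (1i * rho * om)) * (bet / R) * cbessel_j1(bet) / cbessel_j0(bet)
}

# trapezoid rule (quadrature oracle for waveform means and indices)
oracle_trapz <- function(t, v) sum(0.5 * (v[-1] + v[-length(v)]) * diff(t))

# --- small shared fixtures ---------------------------------------------------

demo_geometry <- function() make_vessel("stenosis", length = 0.02,
                                        base_radius = 1.5e-3, severity = 0.5)

demo_waveform <- function(T_cycle = 1.4)
  synthesize_coronary_waveform(0.15, T_cycle, 1.2, seed = 7)

# short schedule for fast transient tests (50 steps/cycle at dt = 0.007)
fast_cfg <- function(nr = 16, ...) coupling_config(dt = 0.007, T_cycle = 0.35,
                                                   nr = nr, ...)
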