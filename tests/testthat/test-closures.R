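test_that("radial distribution function: limits, example value, monotonicity", {
  expect_identical(radial_distribution(0, 0.7), 1)
  expect_equal(radial_distribution(0.45, 0.7), oracle_g0(0.45, 0.7),
               tolerance = 1e-14)
  expect_equal(radial_distribution(0.45, 0.7), 7.302, tolerance = 1e-3)
  expect_error(radial_distribution(0.7, 0.7), "packing")
  expect_error(radial_distribution(0.75, 0.7), "packing")
  eps <- seq(0, 0.69, by = 0.01)
  expect_true(all(diff(radial_distribution(eps, 0.7)) > 0))
  expect_true(all(radial_distribution(eps, 0.7) >= 1))
})

test_that("solids pressure: zero limits and direct evaluation", {
  expect_identical(solids_pressure(0.45, 1096, 0, 0.99999, 7.302), 0)
  expect_identical(solids_pressure(0, 1096, 1e-4, 0.99999, 1), 0)
  p <- solids_pressure(0.45, 1096, 1e-4, 0.99999, 7.302)
  expect_equal(p, oracle_solids_pressure(0.45, 1096, 1e-4, 0.99999, 7.302),
               tolerance = 1e-14)
  expect_equal(p, 0.698, tolerance = 1e-3)
  # linear in theta
  expect_equal(solids_pressure(0.45, 1096, 2e-4, 0.99999, 7.302), 2 * p,
               tolerance = 1e-14)
})

test_that("granular viscosities: zero limits, dilute limit, sqrt(theta) scaling", {
  p <- ktgf_params()
  g0 <- radial_distribution(0.45, p$eps_max)
  expect_identical(bulk_viscosity(0.45, p$rho_rbc, p$d_rbc, g0, p$e, 0), 0)
  expect_identical(bulk_viscosity(0, p$rho_rbc, p$d_rbc, 1, p$e, 1e-4), 0)
  expect_identical(shear_viscosity(0.45, p$rho_rbc, p$d_rbc, g0, p$e, 0), 0)
  th <- 1e-4
  lam <- bulk_viscosity(0.45, p$rho_rbc, p$d_rbc, g0, p$e, th)
  expect_equal(lam, oracle_bulk_viscosity(0.45, p$rho_rbc, p$d_rbc, g0, p$e, th),
               tolerance = 1e-14)
  expect_equal(bulk_viscosity(0.45, p$rho_rbc, p$d_rbc, g0, p$e, 2 * th),
               sqrt(2) * lam, tolerance = 1e-12)
  mu <- shear_viscosity(0.45, p$rho_rbc, p$d_rbc, g0, p$e, th, parts = TRUE)
  expect_equal(mu$total,
               oracle_shear_viscosity(0.45, p$rho_rbc, p$d_rbc, g0, p$e, th),
               tolerance = 1e-12)
  expect_equal(mu$collisional + mu$kinetic, mu$total)
  # dilute limit: collisional part vanishes, kinetic tends to the free-flight
  # value 10 rho d sqrt(theta pi) / (96 (1 + e))
  mu0 <- shear_viscosity(0, p$rho_rbc, p$d_rbc, 1, p$e, th, parts = TRUE)
  expect_identical(mu0$collisional, 0)
  expect_equal(mu0$kinetic,
               10 * p$rho_rbc * p$d_rbc * sqrt(th * pi) / (96 * (1 + p$e)),
               tolerance = 1e-14)
  expect_error(shear_viscosity(0.1, p$rho_rbc, p$d_rbc, 0, p$e, th), "g0")
})

test_that("particle Reynolds number and drag coefficient", {
  expect_identical(particle_reynolds(1003, 8e-6, 0, 0.001), 0)
  expect_equal(particle_reynolds(1003, 8e-6, 0.01, 0.001), 0.08024,
               tolerance = 1e-10)
  expect_equal(particle_reynolds(1003, 8e-6, 0.02, 0.001),
               2 * particle_reynolds(1003, 8e-6, 0.01, 0.001))
  expect_equal(drag_cd(1, 1), 27.6, tolerance = 1e-14)
  # Stokes limit: C_D * eps_p * Re -> 24
  expect_equal(drag_cd(1e-8, 1) * 1e-8, 24, tolerance = 1e-5)
  re <- 10^seq(-3, 2, by = 0.25)
  expect_true(all(diff(drag_cd(re, 0.9)) < 0))
  expect_error(drag_cd(0, 1), "Re_p")
})

test_that("Gidaspow drag: branches, limits, and branch jump is reported honestly", {
  p <- ktgf_params()
  expect_identical(drag_beta(0, 1, p$rho_p, p$mu_p, 0.5, p$d_rbc), 0)
  # Ergun-branch value against the brute-force oracle
  b <- drag_beta(0.45, 0.55, p$rho_p, p$mu_p, 0.01, p$d_rbc)
  expect_equal(b, oracle_beta(0.45, 0.55, p$rho_p, p$mu_p, 0.01, p$d_rbc),
               tolerance = 1e-14)
  # zero slip in the Ergun branch: viscous term only
  expect_equal(drag_beta(0.45, 0.55, p$rho_p, p$mu_p, 0, p$d_rbc),
               150 * 0.45 * 0.45 * p$mu_p / (0.55 * p$d_rbc^2),
               tolerance = 1e-14)
  # hard switch: measure the jump at eps_p = 0.8, nonzero and finite
  lo <- drag_beta(0.2 + 1e-9, 0.8 - 1e-9, p$rho_p, p$mu_p, 0.01, p$d_rbc)
  hi <- drag_beta(0.2 - 1e-9, 0.8 + 1e-9, p$rho_p, p$mu_p, 0.01, p$d_rbc)
  expect_true(is.finite(lo) && is.finite(hi) && lo != hi)
  # optional blending removes the discontinuity
  bl <- vapply(c(0.799, 0.8, 0.801), function(ep)
    drag_beta(1 - ep, ep, p$rho_p, p$mu_p, 0.01, p$d_rbc, blend_width = 0.01),
    numeric(1))
  expect_true(max(abs(diff(bl))) < abs(lo - hi))
  expect_error(drag_beta(0.3, 0.75, p$rho_p, p$mu_p, 0, p$d_rbc), "sum to 1")
})

test_that("single-phase viscosity laws match their defining formulas", {
  pl <- single_phase_rheology("power_law", k = 0.035, n = 0.6)
  expect_equal(single_phase_viscosity(1, pl), 0.035, tolerance = 1e-14)
  expect_equal(single_phase_viscosity(100, pl), 0.035 * 100^(-0.4),
               tolerance = 1e-14)
  expect_equal(single_phase_viscosity(100, pl), 5.547e-3, tolerance = 1e-3)
  g <- 10^seq(-2, 3, by = 0.2)
  expect_true(all(diff(single_phase_viscosity(g, pl)) < 0))
  # Quemada: haematocrit-free limit is plasma viscosity
  q0 <- single_phase_rheology("quemada", H = 0, eta_p = 0.001)
  expect_equal(single_phase_viscosity(c(0.1, 1, 100), q0), rep(0.001, 3))
  q <- single_phase_rheology("quemada", H = 0.45)
  expect_equal(single_phase_viscosity(10, q),
               oracle_quemada(10, 0.45, 0.001, 4.33, 1.88, 1.82),
               tolerance = 1e-14)
  # divergence guard
  qb <- single_phase_rheology("quemada", H = 0.6, k0 = 8)
  expect_error(single_phase_viscosity(1e-6, qb), "diverges")
  # strain-rate floor keeps the laws finite at zero shear
  expect_true(is.finite(single_phase_viscosity(0, pl)))
})

test_that("dissipation and conductivity vanish at theta = 0 and for elastic collisions", {
  p <- ktgf_params()
  g0 <- radial_distribution(0.45, p$eps_max)
  d0 <- granular_dissipation_and_conductivity(0.45, p$rho_rbc, p$d_rbc, g0,
                                              p$e, 0)
  expect_identical(d0$gamma, 0)
  expect_identical(d0$k_s, 0)
  de <- granular_dissipation_and_conductivity(0.45, p$rho_rbc, p$d_rbc, g0,
                                              1, 1e-4)
  expect_identical(de$gamma, 0)
  dd <- granular_dissipation_and_conductivity(0.45, p$rho_rbc, p$d_rbc, g0,
                                              0.9, 1e-4)
  expect_equal(dd$gamma, oracle_gamma_diss(0.45, p$rho_rbc, p$d_rbc, g0, 0.9,
                                           1e-4), tolerance = 1e-14)
  expect_equal(dd$k_s, oracle_ks(0.45, p$rho_rbc, p$d_rbc, g0, 0.9, 1e-4),
               tolerance = 1e-14)
})

test_that("closures are homogeneous in theta of the stated degrees", {
  p <- ktgf_params()
  set.seed(42)
  for (i in 1:20) {
    eps <- runif(1, 0.05, 0.65)
    th <- runif(1, 1e-6, 1e-2)
    c_th <- runif(1, 1.5, 4)
    g0 <- radial_distribution(eps, p$eps_max)
    expect_equal(solids_pressure(eps, p$rho_rbc, c_th * th, p$e, g0),
                 c_th * solids_pressure(eps, p$rho_rbc, th, p$e, g0),
                 tolerance = 1e-12)
    expect_equal(bulk_viscosity(eps, p$rho_rbc, p$d_rbc, g0, p$e, c_th * th),
                 sqrt(c_th) * bulk_viscosity(eps, p$rho_rbc, p$d_rbc, g0,
                                             p$e, th), tolerance = 1e-12)
    expect_equal(shear_viscosity(eps, p$rho_rbc, p$d_rbc, g0, p$e, c_th * th),
                 sqrt(c_th) * shear_viscosity(eps, p$rho_rbc, p$d_rbc, g0,
                                              p$e, th), tolerance = 1e-12)
    gam <- granular_dissipation_and_conductivity(eps, p$rho_rbc, p$d_rbc, g0,
                                                 p$e, th)$gamma
    gam_c <- granular_dissipation_and_conductivity(eps, p$rho_rbc, p$d_rbc,
                                                   g0, p$e, c_th * th)$gamma
    expect_equal(gam_c, c_th^1.5 * gam, tolerance = 1e-12)
  }
})

test_that("parameter validation rejects non-physical inputs", {
  expect_error(ktgf_params(e = 1.2), "restitution")
  expect_error(ktgf_params(eps_init = 0.8), "eps_init")
  expect_error(ktgf_params(phi_spec = 1.5), "specularity")
  expect_error(ktgf_params(d_rbc = -1), "positive")
  expect_error(single_phase_rheology(n = -1), "index")
  expect_error(single_phase_rheology(H = 1), "haematocrit")
})
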