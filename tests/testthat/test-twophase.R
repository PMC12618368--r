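# Newtonian limits, Womersley accuracy, migration, conservation.

test_that("dilute two-phase run reduces exactly to single-phase Newtonian plasma", {
  nr <- 16; R <- 1.5e-3
  p0 <- ktgf_params(eps_init = 0, theta_init = 0)
  rh <- single_phase_rheology("newtonian", mu = p0$mu_p, rho = p0$rho_p)
  st2 <- two_phase_state(nr, R, p0)
  st1 <- single_phase_state(nr, R)
  for (i in 1:100) {
    st2 <- step_station(st2, R, list(dpdz = -3000), 0.007, p0)
    st1 <- step_station_single(st1, R, list(dpdz = -3000), 0.007, rh)
  }
  expect_lt(max(abs(st2$v_p - st1$v)) / max(abs(st1$v)), 1e-8)
  expect_equal(st2$eps_rbc, rep(0, nr))
})

test_that("steady Poiseuille profile, WSS = 4 mu vbar / R, and pressure-gradient recovery", {
  nr <- 32; R <- 1.5e-3; mu <- 0.001; G <- -4000
  rh <- single_phase_rheology("newtonian", mu = mu, rho = 1050)
  g <- radial_grid(nr, R)
  v_exact <- -G * (R^2 - g$r^2) / (4 * mu)
  st <- single_phase_state(nr, R)
  for (i in 1:3000) st <- step_station_single(st, R, list(dpdz = G), 0.01, rh)
  expect_lt(max(abs(st$v - v_exact)) / max(v_exact), 1e-10)
  vbar <- -G * R^2 / (8 * mu)
  expect_equal(wall_shear_stress(st, rheology = rh), 4 * mu * vbar / R,
               tolerance = 1e-10)
  # flow-rate forcing recovers the same pressure gradient when targeting the
  # discrete flux of the exact profile (the continuous-flux mismatch is the
  # O(h^2) quadrature bias checked in the vessel-level convergence test)
  Q <- 2 * pi * sum(v_exact * g$r) * g$h
  st2 <- single_phase_state(nr, R)
  for (i in 1:3000) st2 <- step_station_single(st2, R, list(flow_rate = Q),
                                               0.01, rh)
  expect_equal(st2$dpdz, G, tolerance = 1e-9)
  # zero flow: zero WSS
  st0 <- single_phase_state(nr, R)
  expect_equal(wall_shear_stress(st0, rheology = rh), 0)
})

test_that("oscillatory flow matches the Womersley series in velocity and WSS", {
  nr <- 64; R <- 1.5e-3; mu <- 0.001; rho <- 1003
  Tp <- 1.4; om <- 2 * pi / Tp; G <- 2000
  g <- radial_grid(nr, R)
  vhat <- womersley_profile(g$r, R, G, om, rho, mu)
  rh <- single_phase_rheology("newtonian", mu = mu, rho = rho)
  st <- single_phase_state(nr, R)
  st$v <- Re(vhat)
  dt <- Tp / 1000
  err2 <- ref2 <- 0
  tau_err <- tau_ref <- 0
  dv_w <- womersley_wall_dvdr(R, G, om, rho, mu)
  for (k in 1:1000) {
    st <- step_station_single(st, R, list(dpdz = -G * cos(om * (k - 0.5) * dt)),
                              dt, rh, theta_scheme = 0.5)
    ph <- exp(1i * om * k * dt)
    vex <- Re(vhat * ph)
    err2 <- err2 + sum((st$v - vex)^2 * g$r)
    ref2 <- ref2 + sum(vex^2 * g$r)
    tau_ex <- Re(-mu * dv_w * ph)
    tau_err <- max(tau_err, abs(wall_shear_stress(st, rheology = rh) - tau_ex))
    tau_ref <- max(tau_ref, abs(tau_ex))
  }
  expect_lt(sqrt(err2 / ref2), 0.01)       # <= 1% L2 velocity error
  expect_lt(tau_err / tau_ref, 0.02)       # <= 2% peak WSS error
})

test_that("Womersley spatial error converges at second order under grid doubling", {
  R <- 1.5e-3; mu <- 0.001; rho <- 1003
  Tp <- 1.4; om <- 2 * pi / Tp; G <- 2000
  rh <- single_phase_rheology("newtonian", mu = mu, rho = rho)
  l2err <- function(nr) {
    g <- radial_grid(nr, R)
    vhat <- womersley_profile(g$r, R, G, om, rho, mu)
    st <- single_phase_state(nr, R)
    st$v <- Re(vhat)
    dt <- Tp / 4000
    err2 <- ref2 <- 0
    for (k in 1:4000) {
      st <- step_station_single(st, R,
                                list(dpdz = -G * cos(om * (k - 0.5) * dt)),
                                dt, rh, theta_scheme = 0.5)
      vex <- Re(vhat * exp(1i * om * k * dt))
      err2 <- err2 + sum((st$v - vex)^2 * g$r)
      ref2 <- ref2 + sum(vex^2 * g$r)
    }
    sqrt(err2 / ref2)
  }
  e16 <- l2err(16)
  e32 <- l2err(32)
  order <- log2(e16 / e32)
  expect_gt(order, 1.9)
})

test_that("granular temperature: conserved for elastic collisions, decays for inelastic", {
  nr <- 16; R <- 1.5e-3
  p_el <- ktgf_params(e = 1, e_wall = 1)
  st <- two_phase_state(nr, R, p_el)   # zero velocities: no shear production
  th0 <- st$theta
  for (i in 1:50)
    st <- step_granular_temperature(st, 0.007, p_el, include_exchange = FALSE)
  expect_equal(st$theta, th0, tolerance = 1e-12)

  p_in <- ktgf_params(e = 0.9, e_wall = 1)
  st <- two_phase_state(nr, R, p_in)
  prev <- st$theta[1]
  mono <- TRUE
  for (i in 1:200) {
    st <- step_granular_temperature(st, 0.007, p_in, include_exchange = FALSE)
    mono <- mono && all(st$theta <= prev + 1e-18)
    prev <- st$theta[1]
  }
  expect_true(mono)
  expect_lt(max(st$theta), 1e-6)   # decayed by orders of magnitude from 1e-4
  expect_true(all(st$theta >= 0))
})

test_that("homogeneous granular-temperature step matches the algebraic closure balance", {
  nr <- 16; R <- 1.5e-3
  p <- ktgf_params(e = 0.95, e_wall = 1)
  st <- two_phase_state(nr, R, p)
  g <- radial_grid(nr, R)
  a <- 200                     # uniform shear dv/dr = a
  st$v_rbc <- a * g$r
  st$v_p <- a * g$r
  dt <- 0.007
  st1 <- step_granular_temperature(st, dt, p, include_exchange = FALSE)
  # interior cells: theta uniform -> no conduction; implicit balance is
  # 1.5 rho eps (th1 - th0)/dt = prod - G1 sqrt(th0) th1
  g0 <- oracle_g0(p$eps_init, p$eps_max)
  mu_r <- oracle_shear_viscosity(p$eps_init, p$rho_rbc, p$d_rbc, g0, p$e,
                                 p$theta_init)
  prod <- p$eps_init * mu_r * a^2
  G1 <- 12 * (1 - p$e^2) * g0 * p$rho_rbc * p$eps_init^2 /
    (p$d_rbc * sqrt(pi))
  cap <- 1.5 * p$rho_rbc * p$eps_init
  th_expect <- (cap / dt * p$theta_init + prod) /
    (cap / dt + G1 * sqrt(p$theta_init))
  # mid-radius cells, away from the axis (mirror-gradient cell) and from the
  # wall (Johnson-Jackson flux perturbs nearby cells through conduction)
  expect_equal(st1$theta[7:8], rep(th_expect, 2), tolerance = 1e-8)
})

test_that("Johnson-Jackson wall condition: specularity limits and default slip", {
  nr <- 24; R <- 1.5e-3
  p <- ktgf_params()
  st <- two_phase_state(nr, R, p)
  for (i in 1:150) st <- step_station(st, R, list(flow_rate = 1e-6), 0.007, p)
  slip_default <- rbc_wall_slip(st, p)
  expect_gt(slip_default, 0)
  expect_lt(slip_default, max(st$v_rbc))
  # phi -> 0 is free slip (zero tangential wall stress: wall value equals the
  # zero-gradient extrapolation); phi -> 1 approaches no slip
  slips <- vapply(c(0, 0.1, 0.6, 1), function(phi)
    rbc_wall_slip(st, p, phi_spec = phi), numeric(1))
  expect_true(all(diff(slips) < 0))
  h <- R / nr
  extrap <- (9 * st$v_rbc[nr] - st$v_rbc[nr - 1]) / 8
  expect_equal(slips[1], extrap, tolerance = 1e-12)
})

test_that("RBCs migrate away from the wall and deplete the near-wall layer", {
  nr <- 24; R <- 1.5e-3
  p <- ktgf_params()
  st <- two_phase_state(nr, R, p)
  for (i in 1:200) st <- step_station(st, R, list(flow_rate = 1e-6), 0.007, p)
  expect_lt(st$eps_rbc[nr], st$eps_rbc[1])           # strict near-wall deficit
  # depletion is localised at the wall, where the granular-pressure gradient
  # acts; the displaced cells accumulate just inside
  expect_equal(which.min(st$eps_rbc), nr)
  mv <- mixture_viscosity(st, p)
  expect_lt(mv$apparent[nr], mv$apparent[1])         # depleted wall layer is thinner
  # area-mean RBC fraction conserved by the drift transport
  g <- radial_grid(nr, R)
  expect_equal(2 * sum(st$eps_rbc * g$r) * g$h / R^2, p$eps_init,
               tolerance = 1e-12)
  expect_true(all(st$theta >= 0))
})

test_that("packing-limit and drift-CFL guards raise errors", {
  nr <- 16; R <- 1.5e-3
  p <- ktgf_params()
  st <- two_phase_state(nr, R, p)
  st$eps_rbc <- rep(0.71, nr)
  expect_error(step_station(st, R, list(dpdz = -100), 0.007, p), "packing")
  st2 <- two_phase_state(nr, R, p)
  st2$eps_rbc <- seq(0.65, 0.05, length.out = nr)
  st2$theta <- rep(10, nr)   # enormous granular pressure gradient
  cf <- hemofsi:::closure_fields(st2, p)
  expect_error(hemofsi:::advance_eps(st2, 50, p, cf), "CFL")
})

test_that("two-phase WSS reduces to the plasma Poiseuille value in the dilute limit", {
  nr <- 32; R <- 1.5e-3
  p0 <- ktgf_params(eps_init = 0, theta_init = 0)
  st <- two_phase_state(nr, R, p0)
  for (i in 1:2000) st <- step_station(st, R, list(dpdz = -4000), 0.01, p0)
  expect_equal(wall_shear_stress(st, params = p0), -(-4000) * R / 2,
               tolerance = 1e-8)
})
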