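test_that("rhs vanishes at equilibria and at cubic roots", {
  p <- table2_params()
  # equilibrium constructed from the nullclines
  for (nu in c(0, 0.05, 0.15)) {
    vs <- uteromag:::fhn_equilibrium(nu, p)
    ws <- (p$beta * vs + p$delta) / p$gamma
    expect_equal(fhn_rhs(c(vs, ws), 0, p, stimulus("constant", nu)),
                 c(0, 0), tolerance = 1e-9)
  }
  # cubic vanishes at a root potential
  d <- fhn_rhs(c(p$v1, 0), 0, p)
  expect_equal(d[1], 0)
  # hand-evaluated cubic at v = -0.03, w = 0, nu = 0:
  # 7000*(-0.01)*(-0.01)*(0.035) / (10*0.01) = 0.245
  d2 <- fhn_rhs(c(-0.03, 0), 0, p)
  expect_equal(d2[1], 7000 * (-0.03 + 0.02) * (-0.04 + 0.03) *
                 (-0.03 + 0.065) / (10 * 0.01))
  expect_error(fhn_rhs(c(NaN, 0), 0, p), "non-finite")
})

test_that("equilibrium stimulus map matches nullcline algebra", {
  p <- table2_params()
  p0 <- fhn_params(beta = 1e-12, delta = 0)
  p0$beta <- 0 # zero linear term
  expect_equal(equilibrium_stimulus(p0$v2, p0), 0)
  expect_equal(equilibrium_stimulus(resting_potential(p), p), 0,
               tolerance = 1e-9)
})

test_that("discriminants take the published signs and magnitudes", {
  p <- table2_params()
  d <- discriminants(p)
  expect_lt(d[["Delta1"]], 0)
  expect_gt(d[["Delta2"]], 0)
  # hand arithmetic: S^2 - 3P = 0.001525; 3*beta/(k*gamma) = 3/700;
  # 3*eps1*eps2*cm*gamma/k = 0.3/7000
  expect_equal(d[["Delta1"]], 0.001525 - 3 / 700, tolerance = 1e-12)
  expect_equal(d[["Delta2"]], 0.001525 - 0.3 / 7000, tolerance = 1e-12)
  # equality boundary beta = eps1*eps2*cm*gamma^2
  pb <- fhn_params(beta = 10 * 10 * 0.01 * 0.1^2)
  db <- discriminants(pb)
  expect_equal(db[["Delta1"]], db[["Delta2"]], tolerance = 1e-14)
})

test_that("limit-cycle window endpoints and degenerate cases", {
  p <- table2_params()
  rng <- limit_cycle_range(p)
  # frozen from direct hand evaluation of the window formulas
  expect_equal(rng, c(0.01177297, 0.20669), tolerance = 1e-5)
  # inflated time scales close the window
  pinf <- fhn_params(eps1 = 100, eps2 = 100)
  expect_length(limit_cycle_range(pinf), 0)
  # window midpoint (in vm) is classified as a limit cycle
  d <- discriminants(p)
  vm_mid <- (p$v1 + p$v2 + p$v3) / 3
  nu_mid <- equilibrium_stimulus(vm_mid, p)
  expect_identical(classify_stimulus(nu_mid, p), "limit_cycle")
})

test_that("stimulus classification matches the published examples and the
           window boundary", {
  p <- table2_params()
  expect_identical(classify_stimulus(0.15, p), "limit_cycle")
  expect_identical(classify_stimulus(0, p), "stable_equilibrium")
  rng <- limit_cycle_range(p)
  eps <- 5e-4
  expect_identical(classify_stimulus(rng[1] - eps, p), "stable_equilibrium")
  expect_identical(classify_stimulus(rng[2] + eps, p), "stable_equilibrium")
  expect_identical(classify_stimulus(rng[1] + eps, p), "limit_cycle")
})

test_that("classification agrees with long-time integration on a nu grid", {
  p <- table2_params()
  nus <- seq(0.002, 0.25, length.out = 21)
  for (nu in nus) {
    cls <- classify_stimulus(nu, p)
    tr <- simulate_cell(p, stimulus("constant", nu), duration = 120,
                        dt = 0.01)
    # attractor diagnosis: variance of v over the last 30 s
    sel <- tr$time > 90
    spread <- diff(range(tr$vm[sel]))
    if (cls == "limit_cycle") {
      expect_gt(spread, 1e-3)
    } else {
      expect_lt(spread, 1e-3)
    }
  }
})

test_that("resting potential value, translation covariance, and root
           residual", {
  p <- table2_params()
  v0 <- resting_potential(p)
  expect_equal(v0, -0.0556, tolerance = 2e-3)
  # shifting all root potentials by c and delta by -beta*c shifts rest by c
  cc <- 0.013
  ps <- fhn_params(v1 = p$v1 + cc, v2 = p$v2 + cc, v3 = p$v3 + cc,
                   delta = p$delta - p$beta * cc)
  expect_equal(resting_potential(ps), v0 + cc, tolerance = 1e-10)
  # residual of the root, cross-checked by bisection on the same cubic
  f <- function(v) equilibrium_stimulus(v, p)
  bis <- uniroot(f, c(-0.08, -0.03), tol = 1e-13)$root
  expect_equal(v0, bis, tolerance = 1e-8)
})

test_that("linearized frequency obeys the sqrt(eps2/eps1) scaling and the
           quadratic-formula oracle", {
  # the linearization is oscillatory near the Hopf boundary, where the
  # frequency relation applies; evaluate each parameter set just inside its
  # own stimulus window
  om_at_onset <- function(p) hopf_frequency(p, limit_cycle_range(p)[1] + 1e-6)
  p <- table2_params()
  nu <- limit_cycle_range(p)[1] + 1e-6
  om <- om_at_onset(p)
  expect_equal(om_at_onset(fhn_params(eps1 = 4 * p$eps1)), om / 2,
               tolerance = 0.02)
  expect_equal(om_at_onset(fhn_params(eps2 = 4 * p$eps2)), 2 * om,
               tolerance = 0.02)
  # independent quadratic-formula eigenvalues of the 2x2 Jacobian
  vs <- uteromag:::fhn_equilibrium(nu, p)
  J <- uteromag:::fhn_jacobian(vs, p)
  tr <- J[1, 1] + J[2, 2]; det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- tr^2 - 4 * det
  expect_lt(disc, 0)
  expect_equal(om, sqrt(-disc) / 2, tolerance = 1e-10)
  # deep in the relaxation regime the eigenvalues are real
  expect_error(hopf_frequency(p, 0.15), "oscillatory")
  expect_error(hopf_frequency(fhn_params(eps2 = 1e-4), 0), "oscillatory")
})

test_that("plateau response returns to rest and constant stimulus sustains
           spiking", {
  p <- table2_params()
  v0 <- resting_potential(p)
  w0 <- (p$beta * v0 + p$delta) / p$gamma
  tr <- simulate_cell(p, stimulus("none"), duration = 60,
                      initial = c(-0.035, w0), dt = 0.01)
  expect_gt(max(tr$vm), -0.02)          # excursion happened
  expect_equal(tr$vm[length(tr$vm)], v0, tolerance = 1e-4)
  tr2 <- simulate_cell(p, stimulus("constant", 0.15), duration = 60,
                       dt = 0.005)
  # spikes persist into the last tenth of the trace
  sel <- tr2$time > 54
  expect_gt(diff(range(tr2$vm[sel])), 0.02)
  # quiescent trace has zero spike rate
  expect_equal(spike_frequency(tr), 0)
})

test_that("periodic heaviside stimulus produces bursts at the drive period", {
  p <- table2_params()
  stim <- stimulus("periodic_heaviside", amplitude = 0.11, period = 420,
                   duration = 60)
  tr <- simulate_cell(p, stim, duration = 900, dt = 0.01)
  bi <- burst_intervals(tr)
  expect_gte(length(bi$onsets), 2)
  expect_equal(mean(bi$intervals), 420, tolerance = 0.01)
})

test_that("bifurcation diagram localizes the instability window and cycle
           extrema bracket the equilibrium", {
  p <- table2_params()
  grid <- seq(0, 0.25, length.out = 26)
  bd <- bifurcation_diagram(p, grid)
  rng <- limit_cycle_range(p)
  expect_identical(!bd$stable, grid > rng[1] & grid < rng[2])
  bd15 <- bifurcation_diagram(p, 0.15, cycles = TRUE,
                              t_settle = 30, t_measure = 30)
  expect_false(bd15$stable)
  expect_lt(bd15$cycle_min, bd15$vm_eq)
  expect_gt(bd15$cycle_max, bd15$vm_eq)
})

test_that("linearized frequency is order-one consistent with measured spike
           rate near the bifurcation boundary", {
  p <- table2_params()
  nu <- limit_cycle_range(p)[1] + 1e-3
  f_lin <- hopf_frequency(p, nu) / (2 * pi)
  tr <- simulate_cell(p, stimulus("constant", nu), duration = 120,
                      dt = 0.005)
  f_meas <- spike_frequency(tr)
  expect_gt(f_meas, 0)
  expect_gt(f_meas / f_lin, 0.2)
  expect_lt(f_meas / f_lin, 5)
})

test_that("stimulus waveforms evaluate their gates and carriers", {
  s <- stimulus("periodic_heaviside", amplitude = 0.11, period = 420,
                duration = 60)
  expect_equal(stim_value(s, c(0, 59.9, 60.1, 420.5, -1)),
               c(0.11, 0.11, 0, 0.11, 0))
  ssin <- stimulus("sinusoid", amplitude = 0.11, period = 20)
  expect_equal(stim_value(ssin, 5), 0.11)
  expect_equal(stim_value(ssin, 10), 0, tolerance = 1e-12)
  expect_error(stimulus("periodic_heaviside", period = 10, duration = 20))
})
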