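# Shared small fixtures, built in code at test time.

table2_params <- function() fhn_params()

small_sphere <- function(subdiv = 3) {
  make_spherical_uterus(geometry_spec(subdiv = subdiv))
}

# Independent 1-D monodomain cable (finite differences, explicit), used as
# the oracle for the analytic front speed. Not derived from the package's
# surface solver.
cable_front_speed <- function(params, tissue, length = 0.08, dx = 2e-4,
                              dt = 2.5e-4, duration = 1.6,
                              x_probe = c(0.03, 0.06),
                              threshold = -0.035) {
  D <- tissue$zeta * tissue$sigma_el /
    ((tissue$zeta + 1) * tissue$a_m * params$c_m)
  stopifnot(D * dt / dx^2 < 0.5)
  x <- seq(0, length, by = dx)
  n <- length(x)
  v0 <- resting_potential(params)
  v <- rep(v0, n); w <- rep((params$beta * v0 + params$delta) / params$gamma, n)
  v[x < 0.005] <- -0.01
  arr <- rep(NA_real_, n)
  nstep <- ceiling(duration / dt)
  for (s in seq_len(nstep)) {
    lap <- c(v[2] - v[1], diff(v, differences = 2) + 0,
             v[n - 1] - v[n])
    lap <- lap / dx^2
    cub <- params$k * (v - params$v1) * (params$v2 - v) * (v - params$v3)
    dv <- D * lap + (cub - w) / (params$eps1 * params$c_m)
    dw <- params$eps2 * (params$beta * v - params$gamma * w + params$delta)
    v <- v + dt * dv; w <- w + dt * dw
    newly <- is.na(arr) & v >= threshold
    arr[newly] <- s * dt
  }
  i1 <- which.min(abs(x - x_probe[1])); i2 <- which.min(abs(x - x_probe[2]))
  (x[i2] - x[i1]) / (arr[i2] - arr[i1])
}

# Closed-form current-dipole field in an infinite homogeneous medium,
# written independently of the compiled kernel.
dipole_field_oracle <- function(q, r0, pts) {
  mu0_4pi <- 1e-7
  t(vapply(seq_len(nrow(pts)), function(i) {
    d <- pts[i, ] - r0
    r3 <- sum(d^2)^1.5
    mu0_4pi * c(q[2] * d[3] - q[3] * d[2],
                q[3] * d[1] - q[1] * d[3],
                q[1] * d[2] - q[2] * d[1]) / r3
  }, numeric(3)))
}
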