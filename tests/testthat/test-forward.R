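test_that("source current density is zero for uniform fields, linear, and
           matches a hand-computed single-triangle gradient", {
  m <- small_sphere(2)
  ff <- fiber_field(m, 0)
  s0 <- source_current_density(rep(0.3, nrow(m$vertices)), m, ff)
  expect_lt(max(abs(s0$J)), 1e-12)
  set.seed(2)
  vm <- rnorm(nrow(m$vertices))
  s1 <- source_current_density(vm, m, ff)
  s2 <- source_current_density(2 * vm, m, ff)
  expect_equal(s2$J, 2 * s1$J, tolerance = 1e-12)
  # one right triangle in the z = 0 plane, isotropic tensor, linear vm
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(1:3, 1, 3), check = FALSE)
  fft <- fiber_field(tri, 0)
  tis <- tissue_params(t_ratio = 1)
  a <- 0.7; b <- -0.3
  vm_lin <- a * tri$vertices[, 1] + b * tri$vertices[, 2]
  st <- source_current_density(vm_lin, tri, fft, tis, thickness = 0.01)
  expect_equal(as.numeric(st$J),
               -tis$zeta * tis$sigma_el * c(a, b, 0), tolerance = 1e-12)
})

test_that("magnetic field matches the closed-form dipole oracle and its
           far-field decay", {
  q <- c(2e-8, -1e-8, 3e-8); r0 <- c(0.01, -0.02, 0.03)
  src <- list(positions = matrix(r0, 1, 3), Q = matrix(q, 1, 3))
  set.seed(7)
  pts <- matrix(rnorm(30, sd = 0.3), 10, 3)
  pts <- pts[sqrt(rowSums(sweep(pts, 2, r0)^2)) > 0.05, , drop = FALSE]
  B <- magnetic_field(src, pts)
  expect_equal(B, dipole_field_oracle(q, r0, pts), tolerance = 1e-12)
  # colocated opposite dipoles cancel
  src2 <- list(positions = rbind(r0, r0), Q = rbind(q, -q))
  expect_lt(max(abs(magnetic_field(src2, pts))), 1e-25)
  # far-field 1/r^2 decay along a ray
  r <- 2^(3:8) * 0.1
  ray <- outer(r, c(1, 0.2, -0.4) / sqrt(1.2))
  mag <- sqrt(rowSums(magnetic_field(src, ray)^2))
  slope <- coef(lm(log(mag) ~ log(r)))[2]
  expect_equal(as.numeric(slope), -2, tolerance = 0.05 / 2)
  # superposition
  srcA <- list(positions = matrix(r0, 1, 3), Q = matrix(q, 1, 3))
  srcB <- list(positions = matrix(-r0, 1, 3), Q = matrix(rev(q), 1, 3))
  srcAB <- list(positions = rbind(r0, -r0), Q = rbind(q, rev(q)))
  expect_equal(magnetic_field(srcAB, pts),
               magnetic_field(srcA, pts) + magnetic_field(srcB, pts),
               tolerance = 1e-14)
  # singular evaluation guard
  expect_error(magnetic_field(src, matrix(r0 + 1e-6, 1, 3)), "singular")
})

test_that("the SARA preset places 151 unit-norm channels with an 8 cm
           baseline", {
  ab <- make_abdomen_surface(geometry_spec(subdiv = 2))
  arr <- sara_array(ab)
  expect_identical(arr$count, 151L)
  expect_equal(rowSums(arr$orientations^2), rep(1, 151), tolerance = 1e-12)
  outer_pos <- arr$positions + arr$baseline * arr$orientations
  expect_equal(sqrt(rowSums((outer_pos - arr$positions)^2)),
               rep(0.08, 151), tolerance = 1e-12)
  # inner coils sit on the abdomen sphere
  ctr <- attr(ab, "center")
  expect_equal(sqrt(rowSums(sweep(arr$positions, 2, ctr)^2)),
               rep(attr(ab, "radius"), 151), tolerance = 1e-12)
  # array file round-trip
  path <- tempfile(fileext = ".csv")
  save_sensor_array(arr, path)
  arr2 <- load_sensor_array(path)
  expect_equal(arr2$positions, arr$positions, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(arr2$baseline, 0.08)
})

test_that("gradiometers reject uniform fields, scale linearly, and match the
           Taylor oracle for a distant source", {
  ab <- make_abdomen_surface(geometry_spec(subdiv = 2))
  arr <- sara_array(ab)
  # distant dipole: field nearly uniform across the 8 cm baseline
  q <- c(0, 1e-2, 0); r0 <- c(60, 5, -40)
  src <- list(positions = matrix(r0, 1, 3), Q = matrix(q, 1, 3))
  g <- gradiometer_readings(src, arr)
  inner <- rowSums(magnetic_field(src, arr$positions) * arr$orientations)
  expect_lt(max(abs(g)), 1e-2 * max(abs(inner)))
  # Taylor expansion: reading ~ -baseline * d(n.B)/ds along the orientation
  h <- 1e-4
  num_deriv <- vapply(seq_len(arr$count), function(i) {
    p <- arr$positions[i, ]; n <- arr$orientations[i, ]
    f <- function(s) sum(magnetic_field(src, matrix(p + s * n, 1, 3)) * n)
    (f(h) - f(-h)) / (2 * h)
  }, numeric(1))
  expect_equal(g, -arr$baseline * num_deriv, tolerance = 0.02)
  # linearity in source strength
  src2 <- list(positions = src$positions, Q = 2 * src$Q)
  expect_equal(gradiometer_readings(src2, arr), 2 * g, tolerance = 1e-12)
})

test_that("coarse volume-potential solver reproduces the interior dipole
           potential and the insulating-boundary contract", {
  # zero sources: constant potential, zero secondary currents
  src0 <- list(positions = matrix(0, 1, 3), Q = matrix(0, 1, 3))
  vp0 <- solve_volume_potential(src0, function(p) rep(1, nrow(p)),
                                box = 0.1, n = 10)
  expect_equal(diff(range(vp0$phi)), 0)
  expect_equal(max(abs(vp0$J2)), 0)
  # dipole in a homogeneous medium: interior potential matches the
  # infinite-medium closed form away from the boundary
  src <- list(positions = matrix(0, 1, 3), Q = matrix(c(0, 0, 1e-8), 1, 3))
  vp <- solve_volume_potential(src, function(p) rep(1, nrow(p)),
                               box = 0.15, n = 24)
  r <- sqrt(rowSums(vp$grid^2))
  sel <- r > 0.05 & r < 0.09
  phi_inf <- (vp$grid[, 3] * 1e-8) / (4 * pi * r^3)
  expect_gt(cor(vp$phi[sel], phi_inf[sel]), 0.97)
  fit <- coef(lm(vp$phi[sel] ~ phi_inf[sel] - 1))
  expect_equal(as.numeric(fit), 1, tolerance = 0.2)
  # net current through any closed voxel shell is ~0 (insulated domain)
  shell <- r > 0.12 & r < 0.14
  flux <- sum(rowSums(vp$J2[shell, ] * vp$grid[shell, ]) / r[shell])
  expect_lt(abs(flux) * vp$h^2, 1e-10 * max(abs(vp$phi)) / vp$h)
})

test_that("volume currents leave the radial field of a spherical conductor
           unchanged", {
  # tangential dipole inside a homogeneous sphere: secondary currents add
  # no radial magnetic field outside
  src <- list(positions = matrix(c(0, 0.05, 0), 1, 3),
              Q = matrix(c(1e-8, 0, 0), 1, 3))
  sigma_f <- function(p) ifelse(sqrt(rowSums(p^2)) < 0.12, 1, 1e-8)
  vp <- solve_volume_potential(src, sigma_f, box = 0.15, n = 24)
  keep <- sqrt(rowSums(vp$Q2^2)) > 0
  sec <- list(positions = vp$grid[keep, , drop = FALSE],
              Q = vp$Q2[keep, , drop = FALSE])
  pts <- rbind(c(0, 0.2, 0.15), c(0.1, 0.15, 0.18), c(0, 0, 0.25),
               c(-0.12, 0.1, 0.2))
  rhat <- pts / sqrt(rowSums(pts^2))
  br_p <- rowSums(magnetic_field(src, pts) * rhat)
  br_s <- rowSums(magnetic_field(sec, pts) * rhat)
  expect_lt(max(abs(br_s)), 0.1 * max(abs(br_p)))
})
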