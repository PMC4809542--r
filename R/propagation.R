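#' Assemble the anisotropic surface diffusion operator
#'
#' Linear (P1) finite-element discretization of
#' \eqn{\nabla\cdot \frac{\zeta}{\zeta+1} G_e' \nabla v_m} on the triangulated
#' myometrial surface, with the extracellular tensor
#' \eqn{G_e' = (\sigma_{el}-\sigma_{et}) a_3 a_3^T + \sigma_{et} I} evaluated
#' per element from the fiber field. The surface is closed, so the zero-flux
#' condition is built in (no boundary terms). The semi-discrete system is
#' `M dv/dt = -coef * K v + M * reaction`, with `K` the stiffness matrix,
#' `M` the lumped mass (vertex areas) and
#' `coef = zeta / ((zeta+1) * a_m * c_m)`.
#'
#' @param mesh a [surface_mesh()]
#' @param fibers a [fiber_field()] on the same mesh
#' @param tissue a [tissue_params()] object
#' @param c_m membrane capacitance (F/m^2) used in the time-scaling
#' @return list with sparse symmetric `K` (S), numeric `M` (m^2, lumped),
#'   scalar `coef` (m^2 s / S ... such that `coef*K/M` has units 1/s), and
#'   `D` the bulk diffusion coefficient (m^2/s) along the fiber.
#' @export
assemble_diffusion_operator <- function(mesh, fibers, tissue = tissue_params(),
                                        c_m = 0.01) {
  v <- mesh$vertices; f <- mesh$faces
  nf <- nrow(f); nv <- nrow(v)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  n <- mesh$face_normals; A <- mesh$face_areas
  cross3 <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  # P1 basis gradients (tangential): grad(lambda_i) = n x e_i / (2A),
  # e_i the edge opposite vertex i, oriented consistently.
  g1 <- cross3(n, p3 - p2) / (2 * A)
  g2 <- cross3(n, p1 - p3) / (2 * A)
  g3 <- cross3(n, p2 - p1) / (2 * A)
  sl <- tissue$sigma_el; st <- tissue$sigma_et
  a3 <- fibers$a3
  d1 <- rowSums(g1 * a3); d2 <- rowSums(g2 * a3); d3 <- rowSums(g3 * a3)
  kij <- function(ga, gb, da, db) A * ((sl - st) * da * db +
                                         st * rowSums(ga * gb))
  ii <- c(f[, 1], f[, 1], f[, 1], f[, 2], f[, 2], f[, 2],
          f[, 3], f[, 3], f[, 3])
  jj <- c(f[, 1], f[, 2], f[, 3], f[, 1], f[, 2], f[, 3],
          f[, 1], f[, 2], f[, 3])
  xx <- c(kij(g1, g1, d1, d1), kij(g1, g2, d1, d2), kij(g1, g3, d1, d3),
          kij(g2, g1, d2, d1), kij(g2, g2, d2, d2), kij(g2, g3, d2, d3),
          kij(g3, g1, d3, d1), kij(g3, g2, d3, d2), kij(g3, g3, d3, d3))
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nv, nv),
                            symmetric = FALSE)
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  M <- as.numeric(Matrix::sparseMatrix(
    i = as.vector(f), j = rep(1L, 3 * nf), x = rep(A / 3, 3),
    dims = c(nv, 1)))
  coef <- tissue$zeta / ((tissue$zeta + 1) * tissue$a_m * c_m)
  list(K = K, M = M, coef = coef,
       D = coef * sl)
}

#' Pacemaker specification
#'
#' A localized stimulus current applied within `radius` of `center` for
#' `0 <= t <= duration`, entering the voltage equation as
#' `amplitude * gate(t) * gate(r) * carrier(t) / (eps1 c_m)`. The carrier is
#' either a 0.05 Hz cosine `cos(2 pi 0.05 (t - duration))` (as used for the
#' validation runs) or a plain gate.
#'
#' @param center 3-vector (m)
#' @param radius stimulus radius (m)
#' @param amplitude stimulus amplitude V_stim (V)
#' @param duration stimulus duration T_stim (s)
#' @param carrier `"cosine"` (0.05 Hz) or `"gate"`
#' @param carrier_freq carrier frequency (Hz)
#' @return object of class `pacemaker_spec`.
#' @export
pacemaker_spec <- function(center, radius = 0.05, amplitude = 0.11,
                           duration = 5, carrier = c("cosine", "gate"),
                           carrier_freq = 0.05) {
  carrier <- match.arg(carrier)
  stopifnot(radius > 0, duration > 0, length(center) == 3)
  structure(list(center = as.numeric(center), radius = radius,
                 amplitude = amplitude, duration = duration,
                 carrier = carrier, carrier_freq = carrier_freq),
            class = "pacemaker_spec")
}

#' Evaluate the pacemaker drive
#'
#' Returns the stimulus value `nu*h` (the quantity added to the cubic in the
#' voltage equation before the `1/(eps1 c_m)` scaling) at the given positions
#' and time.
#'
#' @param positions n x 3 matrix (m)
#' @param t time (s)
#' @param spec a [pacemaker_spec()]
#' @return numeric vector of length n.
#' @export
pacemaker_current <- function(positions, t, spec) {
  if (t < 0 || t > spec$duration) return(rep(0, nrow(positions)))
  d <- sqrt(rowSums((positions - matrix(spec$center, nrow(positions), 3,
                                        byrow = TRUE))^2))
  carrier <- if (spec$carrier == "cosine")
    cos(2 * pi * spec$carrier_freq * (t - spec$duration)) else 1
  spec$amplitude * carrier * as.numeric(d <= spec$radius)
}

#' Region-specific ionic configuration
#'
#' Vertices within `radius` of `center` (Euclidean) get the `inside`
#' parameters (limit-cycle capable); all others get `outside` parameters in
#' the stable-equilibrium regime, which confines propagation to the inside
#' region. The published outside set raises `eps1` to 200, lowers `eps2` to
#' 0.09 and raises `k` to 10000.
#'
#' @param inside,outside [fhn_params()] objects
#' @param center 3-vector (m); usually the pacemaker center
#' @param radius inside-region radius (m)
#' @return object of class `region_ionic`.
#' @export
region_ionic <- function(inside = fhn_params(),
                         outside = fhn_params(eps1 = 200, eps2 = 0.09,
                                              k = 10000),
                         center = c(0, 0, 0), radius = 0.10) {
  structure(list(inside = inside, outside = outside,
                 center = as.numeric(center), radius = radius),
            class = "region_ionic")
}

# Expand ionic parameters to per-vertex vectors.
vertex_params <- function(mesh, ionic) {
  nv <- nrow(mesh$vertices)
  fields <- c("c_m", "eps1", "eps2", "v1", "v2", "v3", "k",
              "beta", "gamma", "delta")
  if (inherits(ionic, "fhn_params")) {
    pv <- lapply(ionic[fields], rep, nv)
    pv$inside <- rep(TRUE, nv)
    return(pv)
  }
  stopifnot(inherits(ionic, "region_ionic"))
  d <- sqrt(rowSums((mesh$vertices -
                       matrix(ionic$center, nv, 3, byrow = TRUE))^2))
  ins <- d <= ionic$radius
  pv <- lapply(fields, function(nm)
    ifelse(ins, ionic$inside[[nm]], ionic$outside[[nm]]))
  names(pv) <- fields
  pv$inside <- ins
  pv
}

#' Monodomain simulation on the fibered uterine surface
#'
#' Integrates the surface monodomain equation with FHN reaction kinetics by
#' operator splitting: explicit sub-stepped reaction (compiled kernel)
#' followed by an implicit (backward Euler) diffusion solve with a cached
#' sparse Cholesky factor. The initial state is the local resting equilibrium
#' of each vertex's parameter set; with no pacemaker the state therefore
#' stays uniform (in each region) for all time.
#'
#' @param mesh a [surface_mesh()]
#' @param fibers a [fiber_field()]
#' @param ionic an [fhn_params()] (uniform) or [region_ionic()] object
#' @param pacemaker a [pacemaker_spec()] or `NULL`
#' @param duration simulated time (s)
#' @param dt diffusion time step (s)
#' @param tissue a [tissue_params()] object
#' @param snapshot_times times (s) at which full `v_m`/`w` fields are stored
#' @param threshold arrival-detection threshold (V)
#' @param n_react_sub explicit reaction sub-steps per diffusion step
#' @return object of class `tm_solution`: list with `times` (snapshot times),
#'   `vm`, `w` (vertex x snapshot matrices), `arrival` (per-vertex first
#'   threshold-crossing time, NA if never), `mesh`, `dt`, `threshold`.
#' @export
simulate_propagation <- function(mesh, fibers, ionic = fhn_params(),
                                 pacemaker = NULL, duration, dt = 1e-3,
                                 tissue = tissue_params(),
                                 snapshot_times = NULL,
                                 threshold = -0.035, n_react_sub = 4) {
  stopifnot(duration > 0, dt > 0)
  nv <- nrow(mesh$vertices)
  pv <- vertex_params(mesh, ionic)
  op <- assemble_diffusion_operator(mesh, fibers, tissue,
                                    c_m = pv$c_m[1])
  A <- Matrix::Diagonal(x = op$M) + (dt * op$coef) * op$K
  Ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  # per-region resting equilibria as initial state
  v <- numeric(nv); w <- numeric(nv)
  for (grp in unique(pv$inside)) {
    sel <- pv$inside == grp
    i1 <- which(sel)[1]
    prm <- fhn_params(pv$c_m[i1], pv$eps1[i1], pv$eps2[i1], pv$v1[i1],
                      pv$v2[i1], pv$v3[i1], pv$k[i1], pv$beta[i1],
                      pv$gamma[i1], pv$delta[i1])
    v0 <- resting_potential(prm)
    v[sel] <- v0
    w[sel] <- (prm$beta * v0 + prm$delta) / prm$gamma
  }
  inv_e1cm <- 1 / (pv$eps1 * pv$c_m)
  nstep <- ceiling(duration / dt)
  if (is.null(snapshot_times))
    snapshot_times <- c(0, duration)
  snap_steps <- unique(pmin(pmax(round(snapshot_times / dt), 0), nstep))
  vm_out <- matrix(NA_real_, nv, length(snap_steps))
  w_out <- matrix(NA_real_, nv, length(snap_steps))
  arrival <- rep(NA_real_, nv)
  zero_stim <- numeric(nv)
  record <- function(step, v, w) {
    k <- match(step, snap_steps)
    if (!is.na(k)) { vm_out[, k] <<- v; w_out[, k] <<- w }
  }
  record(0L, v, w)
  below <- v < threshold
  for (step in seq_len(nstep)) {
    t_mid <- (step - 0.5) * dt
    stim <- if (is.null(pacemaker)) zero_stim else
      pacemaker_current(mesh$vertices, t_mid, pacemaker)
    .react_step(v, w, stim, pv$k, pv$v1, pv$v2, pv$v3, inv_e1cm,
                pv$eps2, pv$beta, pv$gamma, pv$delta, dt, n_react_sub)
    v <- as.numeric(Matrix::solve(Ch, op$M * v, system = "A"))
    if (step %% 200L == 0L && !all(is.finite(v)))
      stop("non-finite state at step ", step,
           " (t=", step * dt, " s): reduce dt")
    crossed <- below & v >= threshold & is.na(arrival)
    if (any(crossed)) arrival[crossed] <- step * dt
    below <- v < threshold
    record(step, v, w)
  }
  if (!all(is.finite(v)))
    stop("non-finite final state: reduce dt")
  structure(list(times = snap_steps * dt, vm = vm_out, w = w_out,
                 arrival = arrival, mesh = mesh, dt = dt,
                 threshold = threshold),
            class = "tm_solution")
}

#' @exportS3Method base::print
print.tm_solution <- function(x, ...) {
  cat(sprintf(
    "tm_solution: %d vertices, %d snapshots to %.3g s, %d/%d activated\n",
    nrow(x$vm), length(x$times), max(x$times),
    sum(!is.na(x$arrival)), length(x$arrival)))
  invisible(x)
}

#' Front speed between two points from arrival times
#'
#' Surface distance between two mesh vertices divided by the difference of
#' their first threshold-crossing times. On (near-)spherical surfaces the
#' great-circle arc is the appropriate surface distance; for flat or
#' irregular meshes the Euclidean chord can be selected.
#'
#' @param solution a `tm_solution`
#' @param point_a,point_b vertex indices
#' @param metric `"arc"` (sphere fit through the vertex centroid) or
#'   `"euclidean"`
#' @return speed (m/s).
#' @export
measure_front_speed <- function(solution, point_a, point_b,
                                metric = c("arc", "euclidean")) {
  metric <- match.arg(metric)
  if (point_a == point_b) stop("degenerate input: identical points")
  ta <- solution$arrival[point_a]; tb <- solution$arrival[point_b]
  if (is.na(ta) || is.na(tb))
    stop("no arrival: a point never crossed the threshold")
  if (tb == ta) stop("zero arrival-time difference between points")
  d <- if (metric == "arc") {
    arc_distance(solution$mesh, point_a, point_b)
  } else {
    sqrt(sum((solution$mesh$vertices[point_a, ] -
                solution$mesh$vertices[point_b, ])^2))
  }
  d / abs(tb - ta)
}
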