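#' Myometrial source current density and dipole moments
#'
#' From a transmembrane potential snapshot, computes the per-element source
#' current density \eqn{J_s = -\zeta G_e' \nabla v_m} (A/m^2) using the
#' linear-shape-function tangential gradient on each triangle, and the
#' element current-dipole moment `Q = J_s * area * thickness` (A m) used by
#' the magnetic forward computation.
#'
#' @param vm per-vertex transmembrane potential (V)
#' @param mesh a [surface_mesh()]
#' @param fibers a [fiber_field()]
#' @param tissue a [tissue_params()]
#' @param thickness myometrial wall thickness (m); defaults to the mesh
#'   attribute, else 0.01
#' @return object of class `source_field`: list with `J` (elements x 3,
#'   A/m^2), `Q` (elements x 3, A m), `positions` (element centers).
#' @export
source_current_density <- function(vm, mesh, fibers,
                                   tissue = tissue_params(),
                                   thickness = NULL) {
  if (is.null(thickness))
    thickness <- attr(mesh, "thickness")
  if (is.null(thickness)) thickness <- 0.01
  v <- mesh$vertices; f <- mesh$faces
  n <- mesh$face_normals; A <- mesh$face_areas
  cross3 <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  g1 <- cross3(n, p3 - p2) / (2 * A)
  g2 <- cross3(n, p1 - p3) / (2 * A)
  g3 <- cross3(n, p2 - p1) / (2 * A)
  grad <- g1 * vm[f[, 1]] + g2 * vm[f[, 2]] + g3 * vm[f[, 3]]
  # Ge' grad = (sl - st)(a3 . grad) a3 + st grad
  a3 <- fibers$a3
  proj <- rowSums(a3 * grad)
  Ge_grad <- (tissue$sigma_el - tissue$sigma_et) * a3 * proj +
    tissue$sigma_et * grad
  J <- -tissue$zeta * Ge_grad
  structure(list(J = J, Q = J * (A * thickness),
                 positions = mesh$face_centers),
            class = "source_field")
}

#' Quasi-static magnetic field of the source dipoles
#'
#' Primary-current (infinite homogeneous medium) Biot-Savart superposition
#' \deqn{B(r) = \frac{\mu_0}{4\pi}\sum_e Q_e \times
#'   \frac{r - r_e}{\|r - r_e\|^3}.}
#' Volume (return) currents are omitted on this default path; they can be
#' added from [solve_volume_potential()].
#'
#' @param sources a `source_field` from [source_current_density()], or a
#'   list with `positions` and `Q` matrices
#' @param points n x 3 matrix of field points (m)
#' @param exclusion evaluation-exclusion radius (m); points closer than this
#'   to any dipole raise an error
#' @return n x 3 matrix of B vectors (T).
#' @export
magnetic_field <- function(sources, points, exclusion = 1e-4) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  .bs_field(points, sources$positions, sources$Q, exclusion)
}

#' SARA-style gradiometer array on the abdominal surface
#'
#' Places `count` inner coils on the (anterior cap of the) abdominal surface
#' in a deterministic lattice of concentric rings centered on the array axis,
#' oriented along the local outward surface normal; the outer coil of each
#' hardware gradiometer sits `baseline` further out along that normal.
#' The coil coordinates of the physical device are not public; this lattice
#' is a documented stand-in with the correct channel count and baseline.
#'
#' @param abdomen a [surface_mesh()] from [make_abdomen_surface()] (sphere or
#'   cap mode); its `center`/`radius` attributes define the sphere
#' @param count number of sensors (151 for the SARA preset)
#' @param baseline inner-to-outer coil separation (m)
#' @param cap_half_angle angular radius of the sensor lattice (rad)
#' @param n_rings number of concentric rings (plus the central sensor)
#' @return object of class `sensor_array`: list with `positions` (count x 3),
#'   `orientations` (count x 3 unit outward normals), `baseline`, `count`.
#' @export
sara_array <- function(abdomen, count = 151, baseline = 0.08,
                       cap_half_angle = pi / 4, n_rings = 7) {
  ctr <- attr(abdomen, "center"); R <- attr(abdomen, "radius")
  if (is.null(ctr) || is.null(R))
    stop("abdomen mesh lacks sphere center/radius attributes")
  # ring angular radii and per-ring counts proportional to circumference
  th <- cap_half_angle * seq_len(n_rings) / n_rings
  wt <- sin(th)
  counts <- round((count - 1) * wt / sum(wt))
  counts[n_rings] <- count - 1 - sum(counts[-n_rings])
  if (counts[n_rings] < 1)
    stop("cap too small to host the requested rings")
  dirs <- c(0, 0, 1)
  pos <- matrix(c(0, 0, 1), 1, 3)
  for (i in seq_len(n_rings)) {
    phi <- 2 * pi * (seq_len(counts[i]) - 1) / counts[i] +
      (i %% 2) * pi / counts[i]
    pos <- rbind(pos, cbind(sin(th[i]) * cos(phi),
                            sin(th[i]) * sin(phi),
                            rep(cos(th[i]), counts[i])))
  }
  positions <- pos * R + matrix(ctr, nrow(pos), 3, byrow = TRUE)
  structure(list(positions = positions, orientations = pos,
                 baseline = baseline, count = nrow(pos)),
            class = "sensor_array")
}

#' @exportS3Method base::print
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d channels, baseline %.3g m\n",
              x$count, x$baseline))
  invisible(x)
}

#' Write / read a sensor array as delimited text
#'
#' Columns: sensor_id, x, y, z, nx, ny, nz, baseline_m.
#'
#' @param array a `sensor_array`
#' @param path output path
#' @return `path` invisibly (write); a `sensor_array` (read).
#' @export
save_sensor_array <- function(array, path) {
  df <- data.frame(sensor_id = seq_len(array$count),
                   x = array$positions[, 1], y = array$positions[, 2],
                   z = array$positions[, 3],
                   nx = array$orientations[, 1],
                   ny = array$orientations[, 2],
                   nz = array$orientations[, 3],
                   baseline_m = array$baseline)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_sensor_array
#' @export
load_sensor_array <- function(path) {
  df <- utils::read.csv(path)
  structure(list(positions = as.matrix(df[, c("x", "y", "z")]),
                 orientations = as.matrix(df[, c("nx", "ny", "nz")]),
                 baseline = df$baseline_m[1], count = nrow(df)),
            class = "sensor_array")
}

#' Gradiometer (or magnetometer) readings of a source snapshot
#'
#' For each channel returns \eqn{B_i = \hat n_i \cdot B(p_i) -
#' \hat n_i \cdot B(p_i + b\,\hat n_i)} in gradiometer mode (the hardware
#' first-difference that rejects spatially uniform fields), or just the
#' normal component at the inner coil in `"normal_component"` mode.
#'
#' @param sources a `source_field`
#' @param array a `sensor_array`
#' @param mode `"gradiometer"` or `"normal_component"`
#' @return numeric vector of channel readings (T).
#' @export
gradiometer_readings <- function(sources, array,
                                 mode = c("gradiometer",
                                          "normal_component")) {
  mode <- match.arg(mode)
  Bi <- magnetic_field(sources, array$positions)
  inner <- rowSums(Bi * array$orientations)
  if (mode == "normal_component") return(inner)
  outer_pos <- array$positions + array$baseline * array$orientations
  Bo <- magnetic_field(sources, outer_pos)
  inner - rowSums(Bo * array$orientations)
}

#' Coarse volume-conductor potential (optional secondary-current path)
#'
#' Solves the piecewise-homogeneous Poisson problem
#' \eqn{\nabla\cdot\sigma\nabla\phi = \nabla\cdot J_s} on a regular voxel
#' grid with an insulating (Neumann) outer boundary, using harmonic-mean
#' face conductivities and dipole sources deposited as charge pairs. Returns
#' the potential and the secondary (volume) current density
#' \eqn{-\sigma\nabla\phi} per voxel, which can be added to the primary
#' Biot-Savart sum as voxel dipoles `J * h^3`. This is a deliberately coarse
#' desk-scale solver: the default forward path omits volume currents.
#'
#' @param sources a `source_field` (or list with `positions`, `Q`)
#' @param conductivity function `f(points)` returning per-point conductivity
#'   (S/m) for an n x 3 matrix, defining the compartments
#' @param box half-width of the cubic solution domain (m), centered at origin
#' @param n voxels per axis
#' @return list with `phi` (n^3 vector), `grid` (n^3 x 3 voxel centers),
#'   `J2` (n^3 x 3 secondary current density, A/m^2), `Q2` (voxel dipole
#'   moments), `h` (voxel size), `sigma` (per-voxel conductivity).
#' @export
solve_volume_potential <- function(sources, conductivity, box = 0.25,
                                   n = 24) {
  h <- 2 * box / n
  ax <- seq(-box + h / 2, box - h / 2, length.out = n)
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  sig <- conductivity(grid)
  stopifnot(length(sig) == nrow(grid), all(sig >= 0))
  N <- n^3
  idx <- function(i, j, k) (k - 1L) * n * n + (j - 1L) * n + i
  gi <- rep(rep(seq_len(n), times = n), times = n)
  gj <- rep(rep(seq_len(n), each = n), times = n)
  gk <- rep(seq_len(n), each = n * n)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(N)
  for (dim in 1:3) {
    gc <- switch(dim, gi, gj, gk)
    sel <- gc < n
    from <- which(sel)
    to <- from + c(1L, n, n * n)[dim]
    w <- 2 * sig[from] * sig[to] / pmax(sig[from] + sig[to], 1e-300)
    w <- w * h # face area / h = h^2 / h
    ii <- c(ii, from, to); jj <- c(jj, to, from); xx <- c(xx, -w, -w)
    diag_acc[from] <- diag_acc[from] + w
    diag_acc[to] <- diag_acc[to] + w
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                            x = c(xx, diag_acc), dims = c(N, N))
  # dipole sources as +/- charge pairs separated by h/2 along Q
  b <- numeric(N)
  nearest <- function(p) {
    i <- pmin(pmax(round((p[1] + box - h / 2) / h) + 1, 1), n)
    j <- pmin(pmax(round((p[2] + box - h / 2) / h) + 1, 1), n)
    k <- pmin(pmax(round((p[3] + box - h / 2) / h) + 1, 1), n)
    idx(as.integer(i), as.integer(j), as.integer(k))
  }
  Q <- sources$Q; P <- sources$positions
  for (e in seq_len(nrow(Q))) {
    q <- sqrt(sum(Q[e, ]^2))
    if (q == 0) next
    u <- Q[e, ] / q
    ip <- nearest(P[e, ] + (h / 2) * u)
    im <- nearest(P[e, ] - (h / 2) * u)
    if (ip == im) next
    # current monopole strength I = |Q|/d with d the realized separation
    d <- sqrt(sum((grid[ip, ] - grid[im, ])^2))
    b[ip] <- b[ip] + q / d
    b[im] <- b[im] - q / d
  }
  # Neumann-singular system: pin one DOF, then remove the mean
  A[1, ] <- 0; A[1, 1] <- 1; b[1] <- 0
  phi <- as.numeric(Matrix::solve(A, b))
  phi <- phi - mean(phi)
  # central-difference gradient -> secondary current density
  grad <- matrix(0, N, 3)
  for (dim in 1:3) {
    gc <- switch(dim, gi, gj, gk)
    stepn <- c(1L, n, n * n)[dim]
    hi <- which(gc < n); lo <- which(gc > 1)
    g <- numeric(N); cnt <- numeric(N)
    g[hi] <- g[hi] + (phi[hi + stepn] - phi[hi]) / h
    cnt[hi] <- cnt[hi] + 1
    g[lo] <- g[lo] + (phi[lo] - phi[lo - stepn]) / h
    cnt[lo] <- cnt[lo] + 1
    grad[, dim] <- g / pmax(cnt, 1)
  }
  J2 <- -sig * grad
  list(phi = phi, grid = grid, J2 = J2, Q2 = J2 * h^3, h = h, sigma = sig)
}
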