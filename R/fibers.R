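#' Partition a uterine surface into fiber regions
#'
#' Rejection-samples `n_regions` seed elements so that all pairwise
#' (Euclidean) seed distances are at least `min_sep`, then assigns every
#' element to its nearest seed. This reproduces the division of the
#' myometrium into contiguous same-fiber regions (25 regions with a 4 cm
#' minimum seed separation by default).
#'
#' @param mesh a [surface_mesh()]
#' @param n_regions number of regions
#' @param min_sep minimum pairwise seed separation (m)
#' @param rng_seed integer seed for reproducibility
#' @param max_restarts bounded number of full restarts before giving up
#' @return object of class `fiber_partition`: list with `seeds` (element
#'   indices), `seed_points` (coordinates), `region` (per-element region id,
#'   1..n_regions), `min_sep`, `rng_seed`.
#' @export
partition_regions <- function(mesh, n_regions = 25, min_sep = 0.04,
                              rng_seed = 1, max_restarts = 50) {
  ctr <- mesh$face_centers
  ne <- nrow(ctr)
  if (ne < n_regions) stop("mesh has fewer elements than requested regions")
  set.seed(rng_seed)
  for (restart in seq_len(max_restarts)) {
    seeds <- integer(0)
    ok <- TRUE
    for (i in seq_len(n_regions)) {
      placed <- FALSE
      for (try in seq_len(400)) {
        cand <- sample.int(ne, 1)
        if (length(seeds) == 0 ||
            min(sqrt(rowSums((ctr[seeds, , drop = FALSE] -
                              matrix(ctr[cand, ], length(seeds), 3,
                                     byrow = TRUE))^2))) >= min_sep) {
          seeds <- c(seeds, cand); placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      sp <- ctr[seeds, , drop = FALSE]
      d2 <- outer(rowSums(ctr^2), rep(1, n_regions)) +
        outer(rep(1, ne), rowSums(sp^2)) - 2 * ctr %*% t(sp)
      region <- max.col(-d2, ties.method = "first")
      return(structure(list(seeds = seeds, seed_points = sp,
                            region = region, min_sep = min_sep,
                            rng_seed = rng_seed),
                       class = "fiber_partition"))
    }
  }
  stop("could not place ", n_regions, " seeds at separation ", min_sep,
       " m after ", max_restarts, " restarts: mesh too small for packing")
}

#' Draw per-region fiber angles
#'
#' One angle per region from Normal(0, sd); 0 means fibers run along the
#' vertical (y) axis of the uterus. The default spread of pi/4 rad models the
#' absence of a well-ordered global fiber architecture.
#'
#' @param partition a [partition_regions()] result
#' @param sd standard deviation of the angle distribution (rad)
#' @param rng_seed integer seed
#' @return numeric vector of per-region angles (rad).
#' @export
sample_fiber_angles <- function(partition, sd = pi / 4, rng_seed = 1) {
  set.seed(rng_seed)
  stats::rnorm(length(partition$seeds), mean = 0, sd = sd)
}

#' Fiber direction from a surface normal and fiber angle
#'
#' Builds the in-surface fiber direction at a point with outward unit normal
#' `n = (nx, ny, nz)`. With `s = sqrt(nx^2 + nz^2)`, the tangent basis is
#' `t1 = (nx*ny, -s^2, nz*ny)/s` (direction of steepest vertical descent) and
#' `t2 = (-nz, 0, nx)/s` (horizontal tangent); the fiber runs
#' `a3 = cos(alpha) t1 + sin(alpha) t2`, so `alpha = 0` is the vertical
#' (fundus-to-cervix) direction. Where the normal is (numerically) parallel
#' to the vertical axis the construction is singular and the fixed fallback
#' basis `t1 = (1,0,0)`, `t2 = (0,0,1)` is used.
#'
#' @param normal unit 3-vector (or n x 3 matrix of unit normals)
#' @param alpha fiber angle(s) (rad), scalar or length-n
#' @param tol singularity tolerance on `s`
#' @return unit 3-vector (or n x 3 matrix) tangent to the surface.
#' @export
fiber_orientation <- function(normal, alpha, tol = 1e-8) {
  nm <- if (is.matrix(normal)) normal else matrix(normal, 1, 3)
  n <- nrow(nm)
  alpha <- rep_len(alpha, n)
  s <- sqrt(nm[, 1]^2 + nm[, 3]^2)
  t1 <- cbind(nm[, 1] * nm[, 2], -s^2, nm[, 3] * nm[, 2]) / pmax(s, tol)
  t2 <- cbind(-nm[, 3], 0, nm[, 1]) / pmax(s, tol)
  polar <- s < tol
  if (any(polar)) {
    t1[polar, ] <- matrix(c(1, 0, 0), sum(polar), 3, byrow = TRUE)
    t2[polar, ] <- matrix(c(0, 0, 1), sum(polar), 3, byrow = TRUE)
  }
  a3 <- t1 * cos(alpha) + t2 * sin(alpha)
  a3 <- a3 / sqrt(rowSums(a3^2))
  if (!is.matrix(normal)) a3[1, ] else a3
}

#' Per-element fiber field on a surface
#'
#' Combines a region partition (or a fixed angle) with the per-element
#' outward normals into per-element fiber directions.
#'
#' @param mesh a [surface_mesh()]
#' @param angles either a single fixed angle (rad) applied everywhere or a
#'   per-region angle vector from [sample_fiber_angles()]
#' @param partition a [partition_regions()] result; required when `angles`
#'   is per-region
#' @return object of class `fiber_field`: list with `alpha` (per-element
#'   angle), `a3` (per-element unit direction), `partition` (or NULL).
#' @export
fiber_field <- function(mesh, angles, partition = NULL) {
  ne <- nrow(mesh$faces)
  if (length(angles) == 1 && is.null(partition)) {
    alpha <- rep(angles, ne)
  } else {
    stopifnot(!is.null(partition), length(angles) == length(partition$seeds))
    alpha <- angles[partition$region]
  }
  a3 <- fiber_orientation(mesh$face_normals, alpha)
  structure(list(alpha = alpha, a3 = a3, partition = partition),
            class = "fiber_field")
}

#' Anisotropic conductivity tensor for a fiber direction
#'
#' \deqn{G = (\sigma_l - \sigma_t)\, a_3 a_3^T + \sigma_t I_3,} symmetric
#' positive definite with eigenvalue \eqn{\sigma_l} along the fiber and
#' \eqn{\sigma_t} across it.
#'
#' @param a3 unit fiber direction (3-vector)
#' @param sigma_l longitudinal conductivity (S/m)
#' @param sigma_t transverse conductivity (S/m)
#' @return 3x3 symmetric matrix (S/m).
#' @export
conductivity_tensor <- function(a3, sigma_l, sigma_t) {
  stopifnot(sigma_l > 0, sigma_t > 0)
  (sigma_l - sigma_t) * tcrossprod(a3) + sigma_t * diag(3)
}

#' Tissue conductivity settings
#'
#' The published tissue constants: extracellular longitudinal conductivity
#' `sigma_el = 0.68 S/m` and anisotropy ratio `zeta`; the transverse
#' conductivity is `sigma_el * t_ratio` (default ratio 1/5), and the
#' intracellular tensor is `zeta` times the extracellular one (equal
#' anisotropy ratio assumption underlying the monodomain reduction).
#'
#' @param sigma_el extracellular longitudinal conductivity (S/m)
#' @param zeta intra/extracellular anisotropy ratio
#' @param t_ratio transverse-to-longitudinal conductivity ratio
#' @param a_m membrane surface-to-volume ratio (1/m)
#' @return object of class `tissue_params`.
#' @export
tissue_params <- function(sigma_el = 0.68, zeta = 0.518, t_ratio = 1 / 5,
                          a_m = 575870) {
  stopifnot(sigma_el > 0, zeta > 0, t_ratio > 0, a_m > 0)
  structure(list(sigma_el = sigma_el, sigma_et = sigma_el * t_ratio,
                 sigma_il = zeta * sigma_el,
                 sigma_it = zeta * sigma_el * t_ratio,
                 zeta = zeta, a_m = a_m),
            class = "tissue_params")
}

#' Resting value of the recovery variable
#'
#' On the leading front of a traveling wave the slow variable is pinned at
#' its resting value \eqn{w = (\beta v_{mr} + \delta)/\gamma}.
#'
#' @param params an [fhn_params()] object
#' @param v_mr resting potential (V)
#' @return resting `w` (V).
#' @export
resting_recovery <- function(params, v_mr) {
  (params$beta * v_mr + params$delta) / params$gamma
}

#' Analytic traveling-wave speed along the fiber direction
#'
#' With the recovery variable frozen at rest, the monodomain equation along
#' the fiber reduces to a scalar bistable reaction-diffusion equation whose
#' front speed is
#' \deqn{c = \frac{|\tilde v_1 - 2\tilde v_2 + \tilde v_3|}{c_m}
#'   \sqrt{\frac{k\,\sigma_{el}\,\zeta}{2\,\varepsilon_1 a_m (\zeta+1)}},}
#' where \eqn{\tilde v_1 \le \tilde v_2 \le \tilde v_3} are the roots of
#' \deqn{f(v) = (v-v_1)(v_2-v)(v-v_3) - (\beta v_{mr}+\delta)/(k\gamma).}
#'
#' The cubic sits very close to a tangency for the default parameters: with
#' the printed (rounded) resting potential -0.056 V it has one real root and
#' a complex pair, while with the model's exact resting potential
#' ([resting_potential()]) all three roots are real. When a complex pair
#' occurs the real parts are used and the `path` diagnostic reports
#' `"real_part_fallback"`; otherwise `"three_real_roots"`.
#'
#' @param params an [fhn_params()] object
#' @param tissue a [tissue_params()] object
#' @param v_mr resting potential (V); default is the model's computed
#'   resting potential
#' @return object of class `wavespeed`: list with `speed` (m/s), `roots`
#'   (complex), `roots_used` (real, ascending), `path`, `diffusion` (m^2/s).
#' @examples
#' ws <- wavespeed_analytic(fhn_params(), tissue_params())
#' ws$speed # about 0.0428 m/s
#' @export
wavespeed_analytic <- function(params, tissue = tissue_params(),
                               v_mr = resting_potential(params)) {
  S <- params$v1 + params$v2 + params$v3
  P <- params$v1 * params$v2 + params$v1 * params$v3 + params$v2 * params$v3
  C <- (params$beta * v_mr + params$delta) / (params$k * params$gamma)
  # f(v) = -v^3 + S v^2 - P v + v1 v2 v3 - C
  r <- polyroot(c(params$v1 * params$v2 * params$v3 - C, -P, S, -1))
  scale <- max(abs(r))
  real3 <- all(abs(Im(r)) < 1e-7 * scale)
  rr <- sort(Re(r))
  path <- if (real3) "three_real_roots" else "real_part_fallback"
  d <- rr[1] - 2 * rr[2] + rr[3]
  speed <- abs(d) / params$c_m *
    sqrt(params$k * tissue$sigma_el * tissue$zeta /
           (2 * params$eps1 * tissue$a_m * (tissue$zeta + 1)))
  structure(list(speed = speed, roots = r, roots_used = rr, path = path,
                 diffusion = tissue$zeta * tissue$sigma_el /
                   ((tissue$zeta + 1) * tissue$a_m * params$c_m),
                 v_mr = v_mr),
            class = "wavespeed")
}

#' @exportS3Method base::print
print.wavespeed <- function(x, ...) {
  cat(sprintf("traveling-wave speed: %.4f m/s (%s)\n", x$speed, x$path))
  cat(sprintf("  roots used: %s\n",
              paste(sprintf("%.5f", x$roots_used), collapse = ", ")))
  cat(sprintf("  diffusion coefficient: %.3e m^2/s  v_mr: %.4f V\n",
              x$diffusion, x$v_mr))
  invisible(x)
}
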