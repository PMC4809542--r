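#' Triangulated surface mesh
#'
#' Lightweight container for a closed triangulated surface: an n x 3 matrix of
#' vertex coordinates (m) and an m x 3 integer matrix of triangle vertex
#' indices. Outward unit normals (per vertex and per element) and element
#' areas are computed on construction. The y axis is vertical (fundus at +y);
#' all lengths are SI meters.
#'
#' @param vertices n x 3 numeric matrix (m)
#' @param faces m x 3 integer matrix of 1-based vertex indices
#' @param check if `TRUE`, drop-degenerate check and diagnostics are run
#' @return Object of class `surface_mesh` with fields `vertices`, `faces`,
#'   `face_normals`, `vertex_normals`, `face_areas`, `face_centers`,
#'   `watertight` (logical diagnostic), `euler` (Euler characteristic).
#' @export
surface_mesh <- function(vertices, faces, check = TRUE) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            min(faces) >= 1, max(faces) <= nrow(vertices))
  e1 <- vertices[faces[, 2], , drop = FALSE] -
    vertices[faces[, 1], , drop = FALSE]
  e2 <- vertices[faces[, 3], , drop = FALSE] -
    vertices[faces[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(cr^2))
  if (check && any(a2 < 1e-18))
    stop("degenerate (zero-area) triangle in mesh")
  fn <- cr / a2
  areas <- a2 / 2
  vn <- matrix(0, nrow(vertices), 3)
  for (j in 1:3) {
    for (d in 1:3) {
      acc <- tapply(cr[, d], faces[, j], sum)
      vn[as.integer(names(acc)), d] <- vn[as.integer(names(acc)), d] + acc
    }
  }
  vn <- vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
  centers <- (vertices[faces[, 1], , drop = FALSE] +
                vertices[faces[, 2], , drop = FALSE] +
                vertices[faces[, 3], , drop = FALSE]) / 3
  # watertightness: every undirected edge shared by exactly two faces
  ed <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  watertight <- all(cnt == 2)
  euler <- nrow(vertices) - length(cnt) + nrow(faces)
  structure(list(vertices = vertices, faces = faces,
                 face_normals = fn, vertex_normals = vn,
                 face_areas = areas, face_centers = centers,
                 watertight = watertight, euler = euler),
            class = "surface_mesh")
}

#' @exportS3Method base::print
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "surface_mesh: %d vertices, %d faces, area %.4g m^2, %s, Euler %d\n",
    nrow(x$vertices), nrow(x$faces), sum(x$face_areas),
    if (x$watertight) "watertight" else "NOT watertight", x$euler))
  invisible(x)
}

#' Signed volume enclosed by a mesh
#'
#' Divergence-theorem volume \eqn{\frac{1}{3}\sum_e (c_e \cdot n_e) A_e};
#' positive for consistently outward-oriented closed surfaces.
#'
#' @param mesh a [surface_mesh()]
#' @return enclosed volume (m^3).
#' @export
mesh_volume <- function(mesh) {
  sum(rowSums(mesh$face_centers * mesh$face_normals) * mesh$face_areas) / 3
}

# Unit icosahedron vertices/faces.
icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

#' Unit icosphere by recursive subdivision
#'
#' Icosahedron subdivided `subdiv` times with midpoint vertices projected to
#' the unit sphere; vertices count is `10 * 4^subdiv + 2`.
#'
#' @param subdiv subdivision depth (0 = icosahedron)
#' @return list with unit-sphere `v` (vertices) and `f` (faces).
#' @export
icosphere <- function(subdiv = 3) {
  m <- icosahedron()
  for (s in seq_len(subdiv)) {
    v <- m$v; f <- m$f
    ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ekey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    uk <- unique(ekey)
    mid_idx <- match(ekey, uk) + nrow(v)
    ue <- ed[!duplicated(ekey), , drop = FALSE]
    mids <- (v[ue[, 1], ] + v[ue[, 2], ]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    n <- nrow(f)
    a <- f[, 1]; b <- f[, 2]; c3 <- f[, 3]
    ab <- mid_idx[1:n]; bc <- mid_idx[n + 1:n]; ca <- mid_idx[2 * n + 1:n]
    f2 <- rbind(cbind(a, ab, ca), cbind(b, bc, ab),
                cbind(c3, ca, bc), cbind(ab, bc, ca))
    m <- list(v = v, f = f2)
  }
  m
}

#' Geometry specification for the volume conductor
#'
#' Printed defaults: 16 cm uterus outer radius, 1 cm wall, 12 cm fetus,
#' 21 cm abdomen, 2 cm anterior uterus-abdomen offset.
#'
#' @param uterus_radius outer radius of the myometrium (m)
#' @param wall_thickness uniform myometrial wall thickness (m)
#' @param fetus_radius fetal sphere radius (m)
#' @param abdomen_radius abdominal sphere radius (m)
#' @param abdomen_offset anterior clearance between uterus and abdomen (m)
#' @param subdiv icosphere subdivision depth used when meshing
#' @return object of class `geometry_spec`.
#' @export
geometry_spec <- function(uterus_radius = 0.16, wall_thickness = 0.01,
                          fetus_radius = 0.12, abdomen_radius = 0.21,
                          abdomen_offset = 0.02, subdiv = 4) {
  stopifnot(fetus_radius < uterus_radius - wall_thickness,
            wall_thickness > 0, subdiv >= 0)
  structure(list(uterus_radius = uterus_radius,
                 wall_thickness = wall_thickness,
                 fetus_radius = fetus_radius,
                 abdomen_radius = abdomen_radius,
                 abdomen_offset = abdomen_offset,
                 subdiv = subdiv),
            class = "geometry_spec")
}

#' Spherical uterus (mid-wall surface)
#'
#' The myometrium is represented by its mid-wall surface: a sphere at radius
#' `uterus_radius - wall_thickness/2` (0.155 m with defaults), with the wall
#' thickness carried alongside for volumetric source scaling.
#'
#' @param spec a [geometry_spec()]
#' @return a [surface_mesh()] with attribute `thickness` (m).
#' @export
make_spherical_uterus <- function(spec = geometry_spec()) {
  r <- spec$uterus_radius - spec$wall_thickness / 2
  ico <- icosphere(spec$subdiv)
  if (nrow(ico$f) < 100)
    warning("mesh resolution very coarse (< 100 elements)")
  m <- surface_mesh(ico$v * r, ico$f)
  attr(m, "thickness") <- spec$wall_thickness
  m
}

#' Pear-shaped uterus (synthetic anatomical stand-in)
#'
#' A smooth closed surface emulating the late-pregnancy uterine shape: an
#' icosphere with a y-dependent radial modulation
#' \eqn{\rho(u) = r (1 + e\,u - q\,u^2)} with `u = y` on the unit sphere, so
#' the fundus (+y) is broader than the lower segment. With
#' `elongation = taper = 0` this is exactly the sphere. The default
#' modulation is mild (a few percent radial variation, volume within a few
#' percent of the sphere) so that the organ differs from the sphere in shape
#' rather than in overall scale, as a near-term uterus does. This is a
#' synthetic stand-in for a subject-specific anatomical mesh, not derived
#' from imaging.
#'
#' @param spec a [geometry_spec()]
#' @param elongation linear modulation coefficient `e`
#' @param taper quadratic modulation coefficient `q`
#' @return a [surface_mesh()] with attribute `thickness`.
#' @export
make_pear_uterus <- function(spec = geometry_spec(), elongation = 0.08,
                             taper = 0.05) {
  r <- spec$uterus_radius - spec$wall_thickness / 2
  ico <- icosphere(spec$subdiv)
  u <- ico$v[, 2]
  s <- 1 + elongation * u - taper * u^2
  if (any(s <= 0.2))
    stop("modulation too strong: surface would self-intersect")
  m <- surface_mesh(ico$v * (r * s), ico$f)
  if (mesh_volume(m) <= 0 || !m$watertight)
    stop("pear surface failed the closed-surface check")
  attr(m, "thickness") <- spec$wall_thickness
  m
}

#' Abdominal surface: sphere or concave cap
#'
#' In `"sphere"` mode: a sphere of radius `abdomen_radius` whose center is
#' shifted on the anterior (+z) axis so its front face clears the uterus outer
#' surface by `abdomen_offset` (0.21 m sphere centered at z = -0.03 m with
#' defaults). In `"concave_cap"` mode: the anterior polar cap of the same
#' sphere (half-angle `cap_half_angle`), an open surface whose concave side
#' faces the body -- the stand-in for the concave SQUID-array surface the
#' abdomen rests against.
#'
#' @param spec a [geometry_spec()]
#' @param shape `"sphere"` or `"concave_cap"`
#' @param cap_half_angle cap half-angle (rad) for cap mode
#' @return a [surface_mesh()] (cap mode is not watertight by design); the
#'   underlying sphere center/radius are stored as attributes `center` and
#'   `radius`.
#' @export
make_abdomen_surface <- function(spec = geometry_spec(),
                                 shape = c("sphere", "concave_cap"),
                                 cap_half_angle = pi / 3) {
  shape <- match.arg(shape)
  R <- spec$abdomen_radius
  zc <- spec$uterus_radius + spec$abdomen_offset - R
  ico <- icosphere(spec$subdiv)
  v <- ico$v * R
  v[, 3] <- v[, 3] + zc
  if (shape == "sphere") {
    m <- surface_mesh(v, ico$f)
  } else {
    # keep faces whose vertices all lie within the anterior cap
    ang <- acos(pmin(1, pmax(-1, ico$v[, 3])))
    keepv <- ang <= cap_half_angle
    keepf <- keepv[ico$f[, 1]] & keepv[ico$f[, 2]] & keepv[ico$f[, 3]]
    f <- ico$f[keepf, , drop = FALSE]
    used <- sort(unique(as.vector(f)))
    remap <- integer(nrow(v)); remap[used] <- seq_along(used)
    m <- surface_mesh(v[used, , drop = FALSE],
                      matrix(remap[f], ncol = 3), check = FALSE)
  }
  attr(m, "center") <- c(0, 0, zc)
  attr(m, "radius") <- R
  attr(m, "shape") <- shape
  m
}

#' Great-circle (arc) distance between two points via a sphere fit
#'
#' Arc length between two on-sphere points, using the centroid of the mesh
#' vertices as the sphere center.
#'
#' @param mesh a [surface_mesh()]
#' @param i,j vertex indices
#' @return arc distance (m).
#' @export
arc_distance <- function(mesh, i, j) {
  ctr <- colMeans(mesh$vertices)
  a <- mesh$vertices[i, ] - ctr; b <- mesh$vertices[j, ] - ctr
  ra <- sqrt(sum(a^2)); rb <- sqrt(sum(b^2))
  th <- acos(pmin(1, pmax(-1, sum(a * b) / (ra * rb))))
  th * (ra + rb) / 2
}
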