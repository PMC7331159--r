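#' Indexed triangle surface
#'
#' The package's mesh container: an indexed triangle mesh carrying a `role`
#' tag identifying what the surface represents in the joint model
#' (`"bone"`, `"subchondral"`, or `"cartilage"`).
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix, one-based vertex indices, consistently
#'   oriented (counter-clockwise seen from outside).
#' @param role character role tag.
#' @param side optional `"scapular"` or `"humeral"`.
#' @return object of class `TriSurface`.
#' @export
tri_surface <- function(vertices, faces, role = "cartilage", side = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, role = role, side = side),
            class = "TriSurface")
}

#' @export
print.TriSurface <- function(x, ...) {
  cat(sprintf("TriSurface [%s%s]: %d vertices, %d faces\n", x$role,
              if (!is.null(x$side)) paste0(", ", x$side) else "",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Per-face and per-vertex quantities of a triangle surface
#'
#' @param surface `TriSurface`.
#' @return `face_normals` computes unit face normals (m x 3);
#'   `vertex_normals` area-weighted averaged unit vertex normals (n x 3);
#'   `face_areas` triangle areas (mm^2); `vertex_areas` barycentric-lumped
#'   vertex areas (one third of each incident triangle).
#' @name mesh-quantities
NULL

face_cross <- function(surface) {
  V <- surface$vertices; F <- surface$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' @rdname mesh-quantities
#' @export
face_normals <- function(surface) {
  cr <- face_cross(surface)
  cr / pmax(sqrt(rowSums(cr^2)), 1e-300)
}

#' @rdname mesh-quantities
#' @export
face_areas <- function(surface) {
  0.5 * sqrt(rowSums(face_cross(surface)^2))
}

#' @rdname mesh-quantities
#' @export
vertex_normals <- function(surface) {
  cr <- face_cross(surface)  # area-weighted (magnitude = 2*area)
  n <- matrix(0, nrow(surface$vertices), 3)
  for (k in 1:3) {
    acc <- rowsum(cr, group = surface$faces[, k],
                  reorder = FALSE)
    rows <- as.integer(rownames(acc))
    n[rows, ] <- n[rows, ] + acc
  }
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

#' @rdname mesh-quantities
#' @export
vertex_areas <- function(surface) {
  fa <- face_areas(surface)
  a <- numeric(nrow(surface$vertices))
  for (k in 1:3) {
    acc <- rowsum(fa, group = surface$faces[, k], reorder = FALSE)
    rows <- as.integer(rownames(acc))
    a[rows] <- a[rows] + acc[, 1]
  }
  a / 3
}

#' Total surface area
#' @param surface `TriSurface`.
#' @return area in mm^2.
#' @export
surface_area <- function(surface) sum(face_areas(surface))

mean_edge_length <- function(surface) {
  V <- surface$vertices; F <- surface$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  mean(sqrt(rowSums((V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE])^2)))
}

#' Transform a surface by a rigid pose
#' @param surface `TriSurface`.
#' @param pose `RigidPose`.
#' @return transformed `TriSurface`.
#' @export
transform_surface <- function(surface, pose) {
  surface$vertices <- apply_pose(pose, surface$vertices)
  surface
}

## ---- parametric builders --------------------------------------------------

#' Triangulated spherical cap
#'
#' Builds a latitude/longitude triangulation of a spherical cap about the +Z
#' axis. `radius_fn` may vary the radius per direction, which is how cartilage
#' layers of non-uniform thickness are constructed.
#'
#' @param radius cap radius, mm (ignored when `radius_fn` given).
#' @param half_angle_deg polar half-angle of the cap, degrees.
#' @param center sphere center, length 3.
#' @param n_theta number of latitude rings (>= 2).
#' @param n_phi number of longitude steps (>= 3).
#' @param orientation `"outward"` (normals away from center) or `"inward"`.
#' @param radius_fn optional `function(theta, phi)` (radians) returning the
#'   radius for each direction; vectorized.
#' @return `TriSurface` with consistently oriented faces.
#' @export
sphere_cap_surface <- function(radius, half_angle_deg, center = c(0, 0, 0),
                               n_theta = 24, n_phi = 48,
                               orientation = c("outward", "inward"),
                               radius_fn = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(half_angle_deg > 0, half_angle_deg <= 180, n_theta >= 2, n_phi >= 3)
  th_max <- deg2rad(half_angle_deg)
  thetas <- seq(0, th_max, length.out = n_theta + 1)[-1]
  phis <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  grid <- expand.grid(phi = phis, theta = thetas)
  th <- c(0, grid$theta)
  ph <- c(0, grid$phi)
  r <- if (is.null(radius_fn)) rep(radius, length(th)) else radius_fn(th, ph)
  if (any(!is.finite(r)) || any(r <= 0)) stop("radius function must be positive")
  V <- cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
  V <- sweep(V, 2, center, "+")
  # faces: pole fan to first ring, then quad strips
  idx <- function(i, j) 1 + (i - 1) * n_phi + ((j - 1) %% n_phi) + 1
  faces <- matrix(0L, 0, 3)
  fan <- cbind(1L, idx(1, 1:n_phi), idx(1, 2:(n_phi + 1)))
  faces <- rbind(faces, fan)
  if (n_theta > 1) {
    for (i in 1:(n_theta - 1)) {
      a <- idx(i, 1:n_phi); b <- idx(i, 2:(n_phi + 1))
      c_ <- idx(i + 1, 1:n_phi); d <- idx(i + 1, 2:(n_phi + 1))
      faces <- rbind(faces, cbind(a, c_, d), cbind(a, d, b))
    }
  }
  if (orientation == "inward") faces <- faces[, c(1, 3, 2)]
  tri_surface(V, faces)
}

#' Flat rectangular plate surface
#'
#' Regular-grid triangulation of the rectangle `[0, lx] x [0, ly]` at height
#' `z`, normals along +Z. A convenience for oracle tests.
#'
#' @param lx,ly side lengths, mm.
#' @param z plate height, mm.
#' @param nx,ny grid subdivisions.
#' @return `TriSurface`.
#' @export
plate_surface <- function(lx, ly, z = 0, nx = 10, ny = 10) {
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  g <- expand.grid(x = xs, y = ys)
  V <- cbind(g$x, g$y, z)
  idx <- function(i, j) (j - 1) * (nx + 1) + i
  faces <- matrix(0L, 0, 3)
  for (j in 1:ny) {
    a <- idx(1:nx, j); b <- idx(2:(nx + 1), j)
    c_ <- idx(1:nx, j + 1); d <- idx(2:(nx + 1), j + 1)
    faces <- rbind(faces, cbind(a, b, d), cbind(a, d, c_))
  }
  tri_surface(V, faces)
}

## close an annular rim between two cap surfaces built with identical
## (n_theta, n_phi) grids, producing a watertight solid boundary
close_cap_solid <- function(outer, inner, n_phi) {
  no <- nrow(outer$vertices)
  V <- rbind(outer$vertices, inner$vertices)
  Fo <- outer$faces
  Fi <- inner$faces[, c(1, 3, 2)] + no  # flip inner so normals point out of solid
  last_ring_o <- (no - n_phi + 1):no
  last_ring_i <- last_ring_o + no
  rim <- matrix(0L, 0, 3)
  for (j in seq_len(n_phi)) {
    a <- last_ring_o[j]; b <- last_ring_o[j %% n_phi + 1]
    c_ <- last_ring_i[j]; d <- last_ring_i[j %% n_phi + 1]
    rim <- rbind(rim, c(a, b, d), c(a, d, c_))
  }
  tri_surface(V, rbind(Fo, Fi, rim), role = "solid")
}
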