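#' Specification of a synthetic shoulder model
#'
#' The synthetic joint is an idealized conforming ball-and-socket: the humeral
#' head is a sphere cap, the glenoid cavity a concentric socket whose
#' articulating surface coincides with the humeral cartilage surface at the
#' neutral pose (zero gap, zero interpenetration). Cartilage thickness varies
#' smoothly over each surface around a target mean. The idealization keeps
#' closed-form oracles available for thickness and interpenetration while the
#' downstream pipeline only ever sees triangle meshes.
#'
#' @param humeral_head_radius subchondral radius of the humeral head, mm.
#' @param glenoid_radius nominal articulating radius of the glenoid socket,
#'   mm. `NULL` (default) derives it from the head radius plus the humeral
#'   thickness field so the two layers conform.
#' @param thickness_mean target mean cartilage thickness, mm (default 0.819,
#'   matching healthy canine shoulder cartilage).
#' @param thickness_sd spatial standard deviation of the thickness field, mm.
#' @param cap_half_angle_humeral,cap_half_angle_glenoid polar half-angles of
#'   the humeral and glenoid caps, degrees. The glenoid cap must fit inside
#'   the humeral cap.
#' @param marker_offsets named list of four 3 x 3 matrices (`scap1`, `scap2`,
#'   `hum1`, `hum2`): marker triad ball centers in each bone's body frame, mm.
#'   `NULL` uses a default layout of 8 mm balls on rigid posts.
#' @param n_theta,n_phi mesh resolution (latitude rings / longitude steps).
#' @param seed integer substream seed for the thickness field.
#' @return object of class `ShoulderSpec`.
#' @export
shoulder_spec <- function(humeral_head_radius = 10,
                          glenoid_radius = NULL,
                          thickness_mean = 0.819,
                          thickness_sd = 0.086,
                          cap_half_angle_humeral = 80,
                          cap_half_angle_glenoid = 45,
                          marker_offsets = NULL,
                          n_theta = 24, n_phi = 48,
                          seed = 1L) {
  stopifnot(humeral_head_radius > 0, thickness_mean > 0, thickness_sd >= 0,
            cap_half_angle_humeral > 0, cap_half_angle_glenoid > 0)
  if (is.null(marker_offsets)) marker_offsets <- default_marker_offsets(humeral_head_radius)
  stopifnot(setequal(names(marker_offsets), c("scap1", "scap2", "hum1", "hum2")))
  structure(list(humeral_head_radius = humeral_head_radius,
                 glenoid_radius = glenoid_radius,
                 thickness_mean = thickness_mean,
                 thickness_sd = thickness_sd,
                 cap_half_angle_humeral = cap_half_angle_humeral,
                 cap_half_angle_glenoid = cap_half_angle_glenoid,
                 marker_offsets = marker_offsets,
                 n_theta = n_theta, n_phi = n_phi,
                 seed = as.integer(seed)),
            class = "ShoulderSpec")
}

## equilateral triad of 8 mm reflective balls, 25 mm side, on posts well away
## from the joint (distances loosely emulate pin-mounted clusters)
default_marker_offsets <- function(r) {
  triad <- function(center, normal) {
    n <- unit(normal)
    u <- unit(cross3(n, if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
    v <- cross3(n, u)
    s <- 25 / sqrt(3)  # circumradius of a 25 mm equilateral triangle
    t(sapply(0:2, function(k) center + s * (cos(2 * pi * k / 3) * u +
                                              sin(2 * pi * k / 3) * v)))
  }
  list(scap1 = triad(c(0, 3 * r, 5 * r), c(0, 1, 1)),
       scap2 = triad(c(0, -3 * r, 5 * r), c(0, -1, 1)),
       hum1 = triad(c(3 * r, 0, -4 * r), c(1, 0, -1)),
       hum2 = triad(c(-3 * r, 0, -7 * r), c(-1, 0, -1)))
}

## smooth random field on the sphere: mean + low-order harmonic perturbation,
## normalized over a fixed reference grid so the continuous function (not the
## sampled vertices) has the requested mean and sd over the cap
smooth_thickness_field <- function(mean, sd, cap_half_angle_deg, seed) {
  coefs <- with_seed(seed, rnorm(5))
  raw_fn <- function(theta, phi) {
    coefs[1] * sin(theta) * cos(phi) + coefs[2] * sin(theta) * sin(phi) +
      coefs[3] * cos(2 * theta) + coefs[4] * sin(2 * theta) * cos(phi) +
      coefs[5] * sin(theta)^2 * sin(2 * phi)
  }
  th <- seq(1e-4, deg2rad(cap_half_angle_deg), length.out = 80)
  ph <- seq(0, 2 * pi, length.out = 160)
  g <- expand.grid(theta = th, phi = ph)
  w <- sin(g$theta)  # area weight on the sphere
  r <- raw_fn(g$theta, g$phi)
  mu <- sum(w * r) / sum(w)
  s <- sqrt(sum(w * (r - mu)^2) / sum(w))
  if (sd == 0 || s < 1e-12) return(function(theta, phi) rep(mean, length(theta)))
  function(theta, phi) mean + (raw_fn(theta, phi) - mu) * (sd / s)
}

#' Generate a synthetic shoulder model
#'
#' Builds six triangle surfaces (bone, subchondral interface, and cartilage
#' surface for scapula and humerus), ground-truth per-vertex thickness fields,
#' marker triads rigidly attached in each bone's body frame, and the
#' anatomical center frames used for 6-DOF decomposition. Both bones' body
#' frames coincide with the lab frame at the neutral pose and the shared
#' center of curvature sits at the origin.
#'
#' Normal conventions: cartilage (articulating) surfaces carry outward normals
#' of their cartilage solid; subchondral surfaces carry normals pointing from
#' bone into cartilage, as required by the thickness definition.
#'
#' @param spec a [shoulder_spec()].
#' @return object of class `ShoulderModel`: list with `humerus` and `scapula`
#'   (each `bone` / `subchondral` / `cartilage` `TriSurface`s), `thickness`
#'   (ground-truth per-vertex fields on the subchondral meshes),
#'   `thickness_fn`, `triads`, `frames` (anatomical glenoid and head frames),
#'   `geometry` and the `spec`.
#' @export
make_shoulder <- function(spec) {
  stopifnot(inherits(spec, "ShoulderSpec"))
  r_h <- spec$humeral_head_radius
  t_hum <- smooth_thickness_field(spec$thickness_mean, spec$thickness_sd,
                                  spec$cap_half_angle_humeral,
                                  substream_seed(spec$seed, "thickness_humeral"))
  t_sca <- smooth_thickness_field(spec$thickness_mean, spec$thickness_sd,
                                  spec$cap_half_angle_glenoid,
                                  substream_seed(spec$seed, "thickness_scapular"))
  art_fn <- function(theta, phi) r_h + t_hum(theta, phi)  # articulating radius
  if (!is.null(spec$glenoid_radius) &&
      abs(spec$glenoid_radius - (r_h + spec$thickness_mean)) > 0.5)
    stop("non-conforming spec: glenoid_radius incompatible with head radius + thickness")
  if (spec$cap_half_angle_glenoid > spec$cap_half_angle_humeral)
    stop("non-conforming spec: glenoid cap exceeds humeral cartilage coverage")

  nt <- spec$n_theta; np <- spec$n_phi
  cap <- function(radius_fn, half_angle, orientation)
    sphere_cap_surface(NA, half_angle, n_theta = nt, n_phi = np,
                       orientation = orientation, radius_fn = radius_fn)
  const_fn <- function(r) function(theta, phi) rep(r, length(theta))

  hum_sub <- cap(const_fn(r_h), spec$cap_half_angle_humeral, "outward")
  hum_car <- cap(art_fn, spec$cap_half_angle_humeral, "outward")
  hum_bone <- cap(const_fn(r_h - 1.5), spec$cap_half_angle_humeral, "outward")
  gle_car <- cap(art_fn, spec$cap_half_angle_glenoid, "inward")
  gle_sub_fn <- function(theta, phi) art_fn(theta, phi) + t_sca(theta, phi)
  gle_sub <- cap(gle_sub_fn, spec$cap_half_angle_glenoid, "inward")
  gle_bone <- cap(function(th, ph) gle_sub_fn(th, ph) + 1.5,
                  spec$cap_half_angle_glenoid, "outward")

  role_side <- function(s, role, side) { s$role <- role; s$side <- side; s }
  vertex_angles <- function(s) {
    v <- s$vertices
    r <- sqrt(rowSums(v^2))
    list(theta = acos(pmin(1, pmax(-1, v[, 3] / r))), phi = atan2(v[, 2], v[, 1]))
  }
  ang_h <- vertex_angles(hum_sub)
  ang_g <- vertex_angles(gle_sub)

  model <- structure(list(
    humerus = list(bone = role_side(hum_bone, "bone", "humeral"),
                   subchondral = role_side(hum_sub, "subchondral", "humeral"),
                   cartilage = role_side(hum_car, "cartilage", "humeral")),
    scapula = list(bone = role_side(gle_bone, "bone", "scapular"),
                   subchondral = role_side(gle_sub, "subchondral", "scapular"),
                   cartilage = role_side(gle_car, "cartilage", "scapular")),
    thickness = list(humeral = t_hum(ang_h$theta, ang_h$phi),
                     scapular = t_sca(ang_g$theta, ang_g$phi)),
    thickness_fn = list(humeral = t_hum, scapular = t_sca),
    triads = spec$marker_offsets,
    frames = list(glenoid = rigid_pose(), head = rigid_pose()),
    geometry = list(center = c(0, 0, 0), head_radius = r_h,
                    articular_radius_fn = art_fn,
                    cap_half_angle_humeral = spec$cap_half_angle_humeral,
                    cap_half_angle_glenoid = spec$cap_half_angle_glenoid),
    spec = spec), class = "ShoulderModel")
  model
}

#' @export
print.ShoulderModel <- function(x, ...) {
  cat(sprintf("ShoulderModel: head radius %.1f mm, mean thickness %.3f mm (humeral) / %.3f mm (scapular)\n",
              x$geometry$head_radius, mean(x$thickness$humeral),
              mean(x$thickness$scapular)))
  invisible(x)
}

#' Write all shoulder model surfaces to a directory
#'
#' Surfaces are written as binary PLY (`<bone>_<role>.ply`) with the
#' ground-truth thickness attached to the subchondral meshes; triads and
#' geometry as JSON.
#'
#' @param model `ShoulderModel`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_shoulder <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (bone in c("humerus", "scapula")) {
    for (role in c("bone", "subchondral", "cartilage")) {
      props <- NULL
      if (role == "subchondral") {
        side <- if (bone == "humerus") "humeral" else "scapular"
        props <- list(thickness_mm = model$thickness[[side]])
      }
      write_ply(model[[bone]][[role]], file.path(dir, paste0(bone, "_", role, ".ply")),
                vertex_props = props)
      write_stl(model[[bone]][[role]], file.path(dir, paste0(bone, "_", role, ".stl")))
    }
  }
  jsonlite::write_json(
    list(triads = lapply(model$triads, function(m) unname(as.matrix(m))),
         head_radius = model$geometry$head_radius,
         center = model$geometry$center),
    file.path(dir, "shoulder_ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
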