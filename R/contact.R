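#' Cartilage thickness map
#'
#' Thickness at each subchondral vertex is the distance along the outward
#' subchondral normal (pointing from bone into cartilage) to the first
#' intersection with the articulating cartilage surface. Vertices whose ray
#' misses the cartilage surface are masked. The map is also resampled onto
#' the cartilage surface by nearest-vertex lookup.
#'
#' @param subchondral `TriSurface`, normals oriented into the cartilage.
#' @param cartilage `TriSurface` of the articulating surface, same side and
#'   frame.
#' @param max_missing_frac error threshold on the fraction of missing rays
#'   (a high miss rate means the surfaces are misaligned).
#' @return object of class `ThicknessMap`: `thickness` (per subchondral
#'   vertex, mm, NA where masked), `on_cartilage` (resampled onto cartilage
#'   vertices), `mask`, `side`.
#' @export
thickness_map <- function(subchondral, cartilage, max_missing_frac = 0.5) {
  n <- vertex_normals(subchondral)
  th <- cpp_ray_mesh_first(subchondral$vertices, n,
                           cartilage$vertices, cartilage$faces, 1e-9)
  miss <- is.na(th)
  if (mean(miss) > max_missing_frac)
    stop(sprintf("thickness rays missing for %.0f%% of vertices; surfaces likely misaligned",
                 100 * mean(miss)))
  idx <- cpp_nearest_rows(cartilage$vertices, subchondral$vertices)
  structure(list(thickness = th, on_cartilage = th[idx], mask = !miss,
                 side = subchondral$side),
            class = "ThicknessMap")
}

#' @export
print.ThicknessMap <- function(x, ...) {
  cat(sprintf("ThicknessMap [%s]: mean %.3f mm (sd %.3f), %d/%d vertices defined\n",
              x$side %||% "?", mean(x$thickness, na.rm = TRUE),
              sd(x$thickness, na.rm = TRUE), sum(x$mask), length(x$mask)))
  invisible(x)
}

## watertight cartilage solid: articulating surface + subchondral interface +
## rim closure; requires both caps built on the same (n_theta, n_phi) grid
cartilage_solid <- function(cartilage, subchondral) {
  nv <- nrow(cartilage$vertices)
  if (nv != nrow(subchondral$vertices))
    stop("open mesh: cartilage and subchondral surfaces are incompatible, cannot close solid")
  n_phi <- ring_size(cartilage)
  close_cap_solid(cartilage, subchondral, n_phi)
}

## longitude count of a cap built by sphere_cap_surface (pole + rings)
ring_size <- function(surface) {
  nv <- nrow(surface$vertices)
  nf <- nrow(surface$faces)
  # nv = 1 + n_theta * n_phi ; nf = n_phi + 2 * (n_theta - 1) * n_phi
  np <- (2 * (nv - 1) - nf)
  if (np < 3 || (nv - 1) %% np != 0)
    stop("surface is not a cap-grid mesh; cannot derive ring size")
  np
}

#' Per-vertex interpenetration of two posed cartilage layers
#'
#' For each vertex of surface A (with its subchondral interface), the local
#' contact normal is the subchondral normal at that vertex. The ray through
#' the vertex along that normal is intersected with the closed solid of the
#' other cartilage layer; if the vertex lies inside the solid, the overlap is
#' its depth beyond the solid's articulating boundary, measured along the
#' normal (0 where disjoint).
#'
#' @param cartilage_a,subchondral_a posed surfaces of side A (lab frame).
#' @param cartilage_b,subchondral_b posed surfaces of side B (lab frame).
#' @return numeric vector: overlap depth (mm) per vertex of `cartilage_a`.
#' @export
overlap_depth <- function(cartilage_a, subchondral_a,
                          cartilage_b, subchondral_b) {
  solid_b <- cartilage_solid(cartilage_b, subchondral_b)
  normals <- vertex_normals(subchondral_a)  # contact normal, A's thickness direction
  hits <- cpp_line_mesh_hits(cartilage_a$vertices, normals,
                             solid_b$vertices, solid_b$faces)
  vapply(hits, function(ts) {
    if (length(ts) < 2) return(0)
    # intervals of the solid along the line; depth of t=0 inside its interval
    ints <- matrix(ts[seq_len(2 * (length(ts) %/% 2))], ncol = 2, byrow = TRUE)
    inside <- ints[, 1] <= 1e-9 & ints[, 2] >= -1e-9
    if (!any(inside)) return(0)
    max(0, -ints[which(inside)[1], 1])
  }, numeric(1))
}

#' Contact strain map from overlap and thickness
#'
#' Contact strain is the geometric surrogate used for in vivo measurements:
#' overlap depth of the rigidly posed cartilage layers divided by the local
#' undeformed thickness. The denominator is, by default, the combined
#' (scapular + humeral) thickness along the contact normal; `"own-layer"`
#' divides by the carrying surface's own thickness instead. Contact is
#' declared where overlap exceeds `threshold` (default 0.25 mm, the in-plane
#' image resolution); strain is reported only inside the contact mask.
#'
#' @param overlap per-vertex overlap depth, mm.
#' @param own_thickness per-vertex thickness of the surface carrying the map, mm.
#' @param other_thickness per-vertex thickness of the opposing layer sampled
#'   at the same vertices, mm (ignored for `"own-layer"`).
#' @param threshold contact threshold, mm.
#' @param denominator `"combined"` or `"own-layer"`.
#' @param frame_index optional frame tag.
#' @return object of class `StrainMap`: `strain` (fraction, 0 outside
#'   contact), `overlap`, `contact_mask`, `frame_index`.
#' @export
contact_strain <- function(overlap, own_thickness, other_thickness = NULL,
                           threshold = 0.25,
                           denominator = c("combined", "own-layer"),
                           frame_index = NA_integer_) {
  denominator <- match.arg(denominator)
  denom <- if (denominator == "combined") {
    if (is.null(other_thickness))
      stop("combined denominator requires other_thickness")
    own_thickness + other_thickness
  } else own_thickness
  mask <- !is.na(overlap) & overlap > threshold
  bad <- mask & (!is.finite(denom) | denom <= 0)
  if (any(bad)) {
    warning(sum(bad), " contacting vertices have zero/undefined thickness; masked")
    mask[bad] <- FALSE
  }
  strain <- numeric(length(overlap))
  strain[mask] <- overlap[mask] / denom[mask]
  structure(list(strain = strain, overlap = overlap, contact_mask = mask,
                 threshold = threshold, frame_index = frame_index),
            class = "StrainMap")
}

#' Cumulate per-frame strain maps over a gait cycle
#'
#' The cumulative contact mask is the union of per-frame masks and the
#' cumulative contact area its area. Per-vertex cumulative strain is the
#' maximum over frames by default (peak-load interpretation, frame-order
#' invariant); `"mean"` averages over the frames in contact at each vertex.
#'
#' @param frames list of `StrainMap`s sharing one surface parameterization.
#' @param vertex_area per-vertex lumped areas of the carrying surface, mm^2.
#' @param mode `"max"` or `"mean"`.
#' @return object of class `CumulativeMap`: `strain`, `contact_mask`,
#'   `contact_area` (mm^2), `contact_area_ratio` (%), `total_area`.
#' @export
cumulate <- function(frames, vertex_area, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (length(frames) == 0) stop("empty frame list")
  S <- sapply(frames, function(f) f$strain)
  M <- sapply(frames, function(f) f$contact_mask)
  S <- matrix(S, ncol = length(frames))
  M <- matrix(M, ncol = length(frames))
  mask <- rowSums(M) > 0
  strain <- numeric(nrow(S))
  if (mode == "max") {
    strain <- apply(S, 1, max)
  } else {
    cnt <- rowSums(M)
    strain[mask] <- rowSums(S * M)[mask] / cnt[mask]
  }
  area <- sum(vertex_area[mask])
  total <- sum(vertex_area)
  structure(list(strain = strain, contact_mask = mask, contact_area = area,
                 contact_area_ratio = 100 * area / total, total_area = total,
                 mode = mode, n_frames = length(frames)),
            class = "CumulativeMap")
}

#' @export
print.CumulativeMap <- function(x, ...) {
  cat(sprintf("CumulativeMap (%s over %d frames): contact area %.1f mm^2 (%.1f%%), mean strain %.2f%%\n",
              x$mode, x$n_frames, x$contact_area, x$contact_area_ratio,
              mean_cumulative_strain(x)))
  invisible(x)
}

#' Area-weighted mean cumulative contact strain
#'
#' @param cmap `CumulativeMap`.
#' @param vertex_area per-vertex lumped areas, mm^2 (uniform weights if
#'   omitted).
#' @return mean strain over the cumulative contact area, percent. An empty
#'   mask yields 0 with a warning.
#' @export
mean_cumulative_strain <- function(cmap, vertex_area = NULL) {
  m <- cmap$contact_mask
  if (!any(m)) { warning("empty cumulative contact mask"); return(0) }
  w <- if (is.null(vertex_area)) rep(1, length(m)) else vertex_area
  100 * sum(cmap$strain[m] * w[m]) / sum(w[m])
}

#' Strain maps along a cycle of relative poses
#'
#' Convenience driver: poses the humeral cartilage through each relative pose,
#' computes overlap against the (fixed) glenoid layer, and returns per-frame
#' strain maps on the humeral cartilage surface plus their cumulation.
#'
#' @param shoulder `ShoulderModel`.
#' @param poses list of humerus-in-glenoid `RigidPose`s.
#' @param threshold contact threshold, mm.
#' @param denominator strain denominator mode (see [contact_strain()]).
#' @param cumulative_mode `"max"` or `"mean"`.
#' @return list with `frames` (list of `StrainMap`), `cumulative`
#'   (`CumulativeMap`), `thickness` (humeral `ThicknessMap`), `vertex_area`.
#' @export
strain_over_cycle <- function(shoulder, poses, threshold = 0.25,
                              denominator = "combined",
                              cumulative_mode = "max") {
  hum <- shoulder$humerus; sca <- shoulder$scapula
  th_h <- thickness_map(hum$subchondral, hum$cartilage)
  th_s <- thickness_map(sca$subchondral, sca$cartilage)
  # opposing-layer thickness sampled at humeral cartilage vertices
  idx_s <- cpp_nearest_rows(hum$cartilage$vertices, sca$subchondral$vertices)
  other <- th_s$thickness[idx_s]
  va <- vertex_areas(hum$cartilage)
  frames <- lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    ca <- transform_surface(hum$cartilage, p)
    sa <- transform_surface(hum$subchondral, p)
    ov <- overlap_depth(ca, sa, sca$cartilage, sca$subchondral)
    contact_strain(ov, th_h$on_cartilage, other, threshold = threshold,
                   denominator = denominator, frame_index = i)
  })
  cum <- cumulate(frames, va, mode = cumulative_mode)
  list(frames = frames, cumulative = cum, thickness = th_h, vertex_area = va)
}
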