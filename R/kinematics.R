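#' Marker triad in a bone's body frame
#'
#' @param body_frame_points 3 x 3 matrix of ball centers, mm, body frame.
#' @param labels optional marker identifiers.
#' @param tol minimum triangle area (mm^2) below which the triad is
#'   considered degenerate.
#' @return object of class `MarkerTriad`.
#' @export
marker_triad <- function(body_frame_points, labels = c("a", "b", "c"),
                         tol = 1e-6) {
  p <- as.matrix(body_frame_points)
  stopifnot(all(dim(p) == c(3, 3)))
  area <- 0.5 * vnorm(cross3(p[2, ] - p[1, ], p[3, ] - p[1, ]))
  if (area <= tol) stop("degenerate triad: points are (near-)collinear")
  structure(list(body_frame_points = p, labels = labels), class = "MarkerTriad")
}

#' Least-squares rigid pose from point correspondences
#'
#' Kabsch/Procrustes fit: finds the proper rotation and translation minimizing
#' the sum of squared distances between posed body-frame points and observed
#' lab-frame points. Reflections are rejected by construction (the SVD sign
#' correction), so the result is always a proper rigid motion.
#'
#' @param body 3-or-more x 3 matrix of body-frame points (or a
#'   [marker_triad()]).
#' @param observed matching matrix of observed lab-frame points, mm.
#' @param frame_index optional frame tag carried on the result.
#' @return `RigidPose` with `residual_rms` (mm).
#' @export
estimate_rigid_pose <- function(body, observed, frame_index = NA_integer_) {
  if (inherits(body, "MarkerTriad")) body <- body$body_frame_points
  P <- as.matrix(body); Q <- as.matrix(observed)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3, nrow(P) >= 3)
  if (anyNA(Q)) stop("observed points contain missing values")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_p <- svd(Pc)$d
  if (sv_p[2] < 1e-9 * max(1, sv_p[1]))
    stop("degenerate configuration: body points are (near-)collinear")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  fitted <- sweep(P %*% t(R), 2, t, "+")
  rms <- sqrt(mean(rowSums((fitted - Q)^2)))
  rigid_pose(R, t, frame_index = frame_index, residual_rms = rms)
}

#' Track a bone's pose over all frames of a recording
#'
#' Estimates one rigid pose per frame from every marker belonging to the bone
#' (both triads pooled into a single least-squares fit).
#'
#' @param tracks named list of n_frames x 3 marker matrices.
#' @param body_points named list of body-frame coordinates matching a subset
#'   of `names(tracks)` (one 3-vector per marker) or a single k x 3 matrix
#'   with rownames.
#' @return list of `RigidPose` (NULL for frames where the fit failed, with a
#'   message).
#' @export
track_poses <- function(tracks, body_points) {
  if (is.matrix(body_points))
    body_points <- setNames(lapply(seq_len(nrow(body_points)),
                                   function(i) body_points[i, ]),
                            rownames(body_points))
  nm <- intersect(names(body_points), names(tracks))
  if (length(nm) < 3) stop("need at least 3 matching markers")
  P <- do.call(rbind, body_points[nm])
  nfr <- nrow(tracks[[nm[1]]])
  lapply(seq_len(nfr), function(f) {
    Q <- do.call(rbind, lapply(nm, function(m) tracks[[m]][f, ]))
    tryCatch(estimate_rigid_pose(P, Q, frame_index = f),
             error = function(e) { message("frame ", f, " skipped: ",
                                           conditionMessage(e)); NULL })
  })
}

#' Register model surfaces into a tracked frame
#'
#' Applies one rigid map to every surface (all pairwise vertex distances are
#' preserved); used to place image-derived models at the marker-tracked pose.
#'
#' @param surfaces a `TriSurface` or list of them.
#' @param pose `RigidPose` for the frame; `NULL` skips the frame with a log
#'   message and returns `NULL`.
#' @return transformed surface(s).
#' @export
register_model_to_frame <- function(surfaces, pose) {
  if (is.null(pose)) { message("frame skipped: no pose"); return(NULL) }
  if (inherits(surfaces, "TriSurface")) return(transform_surface(surfaces, pose))
  lapply(surfaces, transform_surface, pose = pose)
}

#' Rigid iterative-closest-point alignment of two surfaces
#'
#' Best-fit alignment of two overlapping subchondral bone profiles, the
#' operation used to fuse bone models with cartilage models segmented from a
#' different modality. Point-to-point ICP on mesh vertices with a Kabsch
#' update each iteration.
#'
#' @param moving,fixed `TriSurface`s; the returned pose maps `moving` onto
#'   `fixed`.
#' @param init initial `RigidPose` guess.
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the RMS change, mm.
#' @return `RigidPose` with attributes `converged` (logical), `rms` (final
#'   closest-point RMS, mm) and `iterations`.
#' @export
align_by_subchondral <- function(moving, fixed, init = rigid_pose(),
                                 max_iter = 500, tol = 1e-5) {
  src0 <- moving$vertices
  pose <- init
  last_rms <- Inf
  converged <- FALSE
  it <- 0
  match_fun <- function(src) {
    if (nrow(fixed$faces) >= 4)
      cpp_closest_on_mesh(src, fixed$vertices, fixed$faces)
    else  # degenerate/point-cloud target: nearest vertex
      fixed$vertices[cpp_nearest_rows(src, fixed$vertices), , drop = FALSE]
  }
  while (it < max_iter) {
    it <- it + 1
    src <- apply_pose(pose, src0)
    match <- match_fun(src)
    rms <- sqrt(mean(rowSums((src - match)^2)))
    pose <- estimate_rigid_pose(src0, match)
    if (abs(last_rms - rms) < tol) { converged <- TRUE; break }
    last_rms <- rms
  }
  src <- apply_pose(pose, src0)
  match <- match_fun(src)
  rms <- sqrt(mean(rowSums((src - match)^2)))
  if (!converged)
    stop(sprintf("ICP did not converge in %d iterations (last RMS %.4g mm)",
                 max_iter, rms))
  attr(pose, "converged") <- converged
  attr(pose, "rms") <- rms
  attr(pose, "iterations") <- it
  pose
}

#' Six-DOF relative motion of the humeral head in the glenoid frame
#'
#' Translation is the humeral-head center expressed in the glenoid anatomical
#' frame; rotation is the intrinsic Z-Y'-X'' Euler decomposition of the
#' head-frame orientation relative to the glenoid frame. Samples within 1
#' degree of gimbal lock (|ry| near 90) are flagged.
#'
#' @param scapula_pose,humerus_pose lab-frame `RigidPose`s of the two bones.
#' @param glenoid_frame anatomical frame of the glenoid in the scapula body
#'   frame (`RigidPose`: rotation columns = axes, translation = center).
#' @param head_frame anatomical frame of the humeral head in the humerus body
#'   frame.
#' @return named 6-vector `(tx, ty, tz, rx, ry, rz)` (mm, degrees) with
#'   attribute `gimbal_warning`.
#' @export
relative_dof <- function(scapula_pose, humerus_pose,
                         glenoid_frame = rigid_pose(),
                         head_frame = rigid_pose()) {
  G <- compose_pose(scapula_pose, glenoid_frame)   # glenoid frame in lab
  H <- compose_pose(humerus_pose, head_frame)      # head frame in lab
  rel <- compose_pose(invert_pose(G), H)
  ang <- euler_zyx_angles(rel$rotation)
  out <- c(rel$translation,
           wrap_deg(c(ang$rx, ang$ry, ang$rz)))
  names(out) <- dof_names
  attr(out, "gimbal_warning") <- ang$gimbal_warning
  out
}

#' Anatomical frames from subchondral geometry
#'
#' Fits a least-squares sphere to a subchondral surface to locate the joint
#' center; cap principal directions provide reproducible in-plane axes. The
#' first principal direction of the vertex cloud (projected onto the plane
#' normal to the mean surface normal) is taken as the posterior-anterior
#' axis, the second as medial-lateral.
#'
#' @param subchondral `TriSurface` of the subchondral interface.
#' @return `RigidPose` whose translation is the fitted center and whose
#'   rotation columns are (posterior-anterior, medial-lateral, cap-normal)
#'   axes, plus attribute `radius`.
#' @export
anatomical_frame <- function(subchondral) {
  fit <- fit_sphere(subchondral$vertices)
  vn <- vertex_normals(subchondral)
  axis_n <- unit(colMeans(vn))
  V <- sweep(subchondral$vertices, 2, colMeans(subchondral$vertices))
  proj <- V - outer(as.numeric(V %*% axis_n), axis_n)
  pc <- svd(proj, nu = 0, nv = 2)$v
  x_ax <- unit(pc[, 1] - sum(pc[, 1] * axis_n) * axis_n)
  y_ax <- cross3(axis_n, x_ax)
  # deterministic sign convention: x toward positive lab X when possible
  if (x_ax[1] < 0) { x_ax <- -x_ax; y_ax <- -y_ax }
  R <- cbind(x_ax, y_ax, axis_n)
  if (det(R) < 0) { R[, 2] <- -R[, 2] }
  pose <- rigid_pose(R, fit$center)
  attr(pose, "radius") <- fit$radius
  pose
}
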