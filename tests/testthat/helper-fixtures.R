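# shared fixtures, built once per test run

.fix <- new.env()

# uniform-thickness conforming shoulder at the default mesh resolution
fix_shoulder_uniform <- function() {
  if (is.null(.fix$sh_uniform))
    .fix$sh_uniform <- make_shoulder(shoulder_spec(thickness_sd = 0, seed = 1))
  .fix$sh_uniform
}

# default (spatially varying thickness) shoulder
fix_shoulder <- function() {
  if (is.null(.fix$sh))
    .fix$sh <- make_shoulder(shoulder_spec(seed = 7))
  .fix$sh
}

# coarse shoulder for expensive loops
fix_shoulder_coarse <- function() {
  if (is.null(.fix$sh_coarse))
    .fix$sh_coarse <- make_shoulder(shoulder_spec(thickness_sd = 0,
                                                  n_theta = 16, n_phi = 32,
                                                  seed = 1))
  .fix$sh_coarse
}

random_pose <- function() {
  rigid_pose(random_rotation(), runif(3, -20, 20))
}

random_triad <- function() {
  repeat {
    p <- matrix(runif(9, -30, 30), 3, 3)
    area <- 0.5 * sqrt(sum(cartstrain:::cross3(p[2, ] - p[1, ],
                                               p[3, ] - p[1, ])^2))
    if (area > 10) return(p)
  }
}

# DofTrace wrapper for synthetic matrices
as_dof_trace <- function(dof, frame_rate = 120) {
  colnames(dof) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(list(dof = dof, frame_rate = frame_rate,
                 frames = seq_len(nrow(dof)),
                 gimbal = rep(FALSE, nrow(dof))),
            class = "DofTrace")
}

# closed-form overlap of conforming spheres (articular radius R) whose
# centers approach by delta: depth along the humeral surface normal at polar
# angle theta from the approach axis
sphere_overlap_oracle <- function(theta, delta, R) {
  ov <- R + delta * cos(theta) - sqrt(pmax(R^2 - delta^2 * sin(theta)^2, 0))
  pmax(ov, 0)
}

# track a gait recording end to end up to the retained-cycle set
track_cycles <- function(shoulder, gait, band_tol = 0.05) {
  bs <- cartstrain:::triad_points(shoulder$triads, c("scap1", "scap2"))
  bh <- cartstrain:::triad_points(shoulder$triads, c("hum1", "hum2"))
  trace <- dof_trace(track_poses(gait$tracks, bs),
                     track_poses(gait$tracks, bh),
                     frame_rate = gait$frame_rate)
  reject_outlier_cycles(segment_cycles(trace), band_tol = band_tol)
}
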