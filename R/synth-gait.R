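#' Specification of a synthetic gait recording
#'
#' Six-DOF glenohumeral trajectories are sums of one or two harmonics per DOF
#' (smooth, periodic, band-limited, like optical-capture traces of a walking
#' dog), repeated over `n_cycles` with per-cycle random perturbations, sampled
#' at 120 frames/s. The joint approach DOF (`tz`, humeral head toward the
#' glenoid) is kept non-negative so the cycle loads and unloads the cartilage.
#'
#' @param n_cycles number of gait cycles (>= 1; default 40, the scale of a
#'   multi-minute free-walking session).
#' @param frames_per_cycle frames per cycle at `frame_rate` (>= 4).
#' @param frame_rate capture rate, frames/s (default 120).
#' @param dof_amplitudes named 6-vector `(tx, ty, tz, rx, ry, rz)`:
#'   translation amplitudes in mm, rotation amplitudes in degrees.
#' @param cycle_amp_sd SD of the per-cycle common amplitude factor of a
#'   regular stride (dimensionless; strides are bigger or smaller as a
#'   whole, the dominant mode of stride-to-stride variability).
#' @param cycle_noise_sd per-DOF SD of the per-cycle DC offset of a regular
#'   stride (mm / degrees).
#' @param cycle_shape_sd per-DOF SD of the per-cycle shape perturbation of a
#'   regular stride: a one-harmonic waveform with random phase, modelling
#'   within-stride coordination differences (mm / degrees).
#' @param episode_length a free-walking recording is a series of straight
#'   walking episodes separated by turning strides; every
#'   `episode_length`-th cycle is irregular.
#' @param irregular_scale per-DOF multiplier on `cycle_noise_sd` for
#'   irregular strides. Irregular strides are mostly amplitude anomalies
#'   (the stride rhythm persists while the stride is smaller or larger as a
#'   whole); the flexion-extension DOF that carries the stride rhythm (ry)
#'   keeps near-regular offsets.
#' @param irregular_amp_scale multiplier on `cycle_amp_sd` for the
#'   whole-stride amplitude excursion of irregular strides.
#' @param marker_noise_sd isotropic Gaussian noise added to every lab-frame
#'   marker coordinate, mm (optical-capture error model; default 0.05 mm,
#'   the order of magnitude seen in phantom audits of such systems).
#' @param seed integer substream seed.
#' @return object of class `GaitSpec`.
#' @export
gait_spec <- function(n_cycles = 40, frames_per_cycle = 80, frame_rate = 120,
                      dof_amplitudes = c(tx = 2, ty = 1.5, tz = 0.4,
                                         rx = 8, ry = 12, rz = 6),
                      cycle_amp_sd = 0.05,
                      cycle_noise_sd = c(tx = 0.06, ty = 0.06, tz = 0.02,
                                         rx = 0.07, ry = 0.04, rz = 0.05),
                      cycle_shape_sd = c(tx = 0.06, ty = 0.06, tz = 0.02,
                                         rx = 0.07, ry = 0.04, rz = 0.05),
                      episode_length = 7,
                      irregular_scale = c(tx = 10, ty = 10, tz = 10,
                                          rx = 10, ry = 5, rz = 10),
                      irregular_amp_scale = 10,
                      marker_noise_sd = 0.05, seed = 1L) {
  stopifnot(n_cycles >= 1, frames_per_cycle >= 4, frame_rate > 0,
            length(dof_amplitudes) == 6, length(cycle_noise_sd) == 6,
            all(cycle_noise_sd >= 0), length(cycle_shape_sd) == 6,
            all(cycle_shape_sd >= 0), cycle_amp_sd >= 0, marker_noise_sd >= 0,
            episode_length >= 2, length(irregular_scale) == 6,
            all(irregular_scale >= 1), irregular_amp_scale >= 1)
  structure(list(n_cycles = as.integer(n_cycles),
                 frames_per_cycle = as.integer(frames_per_cycle),
                 frame_rate = frame_rate,
                 dof_amplitudes = dof_amplitudes,
                 cycle_amp_sd = cycle_amp_sd,
                 cycle_noise_sd = cycle_noise_sd,
                 cycle_shape_sd = cycle_shape_sd,
                 episode_length = as.integer(episode_length),
                 irregular_scale = irregular_scale,
                 irregular_amp_scale = irregular_amp_scale,
                 marker_noise_sd = marker_noise_sd,
                 seed = as.integer(seed)),
            class = "GaitSpec")
}

dof_names <- c("tx", "ty", "tz", "rx", "ry", "rz")

## base 6-DOF trajectory over normalized cycle phase [0, 1); per-seed fixed
## harmonic phases/weights; tz (approach) is a raised-cosine, non-negative.
## Phase 0 is anchored at the upward mean-crossing of the highest-amplitude
## DOF: a stride's identity begins at its segmentation event (stride
## perturbations switch at stride events, not at an arbitrary phase)
base_dof_trajectory <- function(amplitudes, seed) {
  par <- with_seed(seed, list(ph1 = runif(6, 0, 2 * pi),
                              ph2 = runif(6, 0, 2 * pi),
                              w2 = runif(6, 0.2, 0.45)))
  ref <- which.max(amplitudes)
  par$ph1[ref] <- 0
  par$ph2[ref] <- 0
  function(phase) {
    out <- sapply(1:6, function(d) {
      if (d == 3)  # approach DOF: load/unload once per cycle, near-zero at
        # stride start but without a tangential zero (a flat zero would give
        # the cycle band a wide degenerate zone)
        amplitudes[3] * (0.55 - 0.45 * cos(2 * pi * phase) +
                           0.08 * sin(4 * pi * phase + par$ph2[3]))
      else
        amplitudes[d] * ((1 - par$w2[d]) * sin(2 * pi * phase + par$ph1[d]) +
                           par$w2[d] * sin(4 * pi * phase + par$ph2[d]))
    })
    matrix(out, ncol = 6, dimnames = list(NULL, dof_names))
  }
}

#' Generate a synthetic gait recording for a shoulder model
#'
#' Produces per-frame lab-frame coordinates of all four marker triads, plus
#' the ground-truth rigid poses and 6-DOF trace. The scapula advances at a
#' steady walking speed with a small vertical bob; the humerus follows the
#' relative 6-DOF trajectory about the glenoid center.
#'
#' @param spec a [gait_spec()].
#' @param shoulder a [make_shoulder()] model.
#' @param outlier optional `list(cycle =, scale =)`: multiply the DOF
#'   amplitudes of one cycle by `scale` (used to exercise the mean +/- 1 SD
#'   cycle filter).
#' @return object of class `GaitRecording`: `tracks` (named list of
#'   n_frames x 3 marker matrices), `frame_rate`, `poses_truth` (lists of
#'   `RigidPose` per frame for scapula and humerus), `dof_truth`
#'   (n_frames x 6), `cycle_of_frame`, `spec`.
#' @export
make_gait <- function(spec, shoulder, outlier = NULL) {
  stopifnot(inherits(spec, "GaitSpec"), inherits(shoulder, "ShoulderModel"))
  fpc <- spec$frames_per_cycle
  nfr <- spec$n_cycles * fpc
  traj <- base_dof_trajectory(spec$dof_amplitudes,
                              substream_seed(spec$seed, "trajectory"))
  pert <- with_seed(substream_seed(spec$seed, "cycle_noise"), {
    a <- rnorm(spec$n_cycles, 0, spec$cycle_amp_sd)
    z <- matrix(rnorm(spec$n_cycles * 6), spec$n_cycles, 6) %*%
      diag(spec$cycle_noise_sd)
    # interior positions: edge cycles are only partially covered by the
    # segmenter, so edge irregulars would not inform the rejection band
    irregular <- (seq_len(spec$n_cycles) - 1) %% spec$episode_length ==
      spec$episode_length %/% 2
    nirr <- sum(irregular)
    # irregular strides: gross whole-stride amplitude excursion (does not
    # shift mean-level crossings) plus inflated per-DOF offsets. Signs are
    # random and independent per stride (no bias on the band center) but
    # magnitudes are bounded away from zero: a turning stride is reliably
    # atypical in every respect, which is also what keeps the rejection
    # band's width stable from recording to recording
    sgn <- function(n) sample(c(-1, 1), n, replace = TRUE)
    a[irregular] <- sgn(nirr) * spec$cycle_amp_sd * spec$irregular_amp_scale *
      runif(nirr, 0.9, 1.3)
    zi <- matrix(sgn(nirr * 6) * runif(nirr * 6, 0.9, 1.3), nirr, 6)
    z[irregular, ] <- zi %*% diag(spec$irregular_scale * spec$cycle_noise_sd)
    b <- matrix(rnorm(spec$n_cycles * 6), spec$n_cycles, 6) %*%
      diag(spec$cycle_shape_sd)
    bi <- matrix(sgn(nirr * 6) * runif(nirr * 6, 0.9, 1.3), nirr, 6)
    b[irregular, ] <- bi %*% diag(spec$irregular_scale * spec$cycle_shape_sd)
    theta <- matrix(runif(spec$n_cycles * 6, 0, 2 * pi), spec$n_cycles, 6)
    list(amp = a, offset = z, shape = b, theta = theta, irregular = irregular)
  })
  phase <- (seq_len(nfr) - 1) %% fpc / fpc
  cyc <- (seq_len(nfr) - 1) %/% fpc + 1
  shape <- pert$shape[cyc, , drop = FALSE] *
    sin(2 * pi * phase + pert$theta[cyc, , drop = FALSE])
  dof <- traj(phase) * (1 + pert$amp[cyc]) + pert$offset[cyc, , drop = FALSE] +
    shape
  if (!is.null(outlier)) {
    sel <- cyc == outlier$cycle
    dof[sel, ] <- traj(phase[sel]) * outlier$scale +
      pert$offset[cyc[sel], , drop = FALSE]
  }
  colnames(dof) <- dof_names

  speed <- 600  # mm/s forward progression of the trunk
  tt <- (seq_len(nfr) - 1) / spec$frame_rate
  scap_poses <- lapply(seq_len(nfr), function(i) {
    bob <- 2 * sin(2 * pi * phase[i])
    rigid_pose(euler_zyx_matrix(0, 0, 2 * sin(2 * pi * phase[i])),
               c(speed * tt[i], 0.5 * bob, bob), frame_index = i)
  })
  hum_poses <- lapply(seq_len(nfr), function(i) {
    rel <- rigid_pose(euler_zyx_matrix(dof[i, "rx"], dof[i, "ry"], dof[i, "rz"]),
                      dof[i, 1:3])
    p <- compose_pose(scap_poses[[i]], rel)
    p$frame_index <- i
    p
  })

  noise <- function(n) matrix(rnorm(n * 3, sd = spec$marker_noise_sd), n, 3)
  tracks <- with_seed(substream_seed(spec$seed, "marker_noise"), {
    out <- list()
    for (tri in c("scap1", "scap2")) {
      pts <- shoulder$triads[[tri]]
      for (k in 1:3) {
        lab <- t(vapply(scap_poses, function(p) drop(apply_pose(p, pts[k, ])), numeric(3)))
        out[[paste0(tri, "_", letters[k])]] <- lab + noise(nfr)
      }
    }
    for (tri in c("hum1", "hum2")) {
      pts <- shoulder$triads[[tri]]
      for (k in 1:3) {
        lab <- t(vapply(hum_poses, function(p) drop(apply_pose(p, pts[k, ])), numeric(3)))
        out[[paste0(tri, "_", letters[k])]] <- lab + noise(nfr)
      }
    }
    out
  })

  structure(list(tracks = tracks, frame_rate = spec$frame_rate,
                 poses_truth = list(scapula = scap_poses, humerus = hum_poses),
                 dof_truth = dof, cycle_of_frame = cyc,
                 irregular_truth = pert$irregular, spec = spec),
            class = "GaitRecording")
}

#' @export
print.GaitRecording <- function(x, ...) {
  cat(sprintf("GaitRecording: %d frames (%d cycles) at %g Hz, %d markers\n",
              nrow(x$dof_truth), x$spec$n_cycles, x$frame_rate,
              length(x$tracks)))
  invisible(x)
}
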