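#' Six-DOF trace of a tracked gait recording
#'
#' Applies [relative_dof()] frame by frame to paired bone pose sequences.
#'
#' @param scapula_poses,humerus_poses lists of `RigidPose` (NULL entries are
#'   dropped pairwise).
#' @param glenoid_frame,head_frame anatomical frames (see [relative_dof()]).
#' @param frame_rate frames per second.
#' @return object of class `DofTrace`: n x 6 matrix `dof` (mm / degrees,
#'   wrapped to (-180, 180]), `frame_rate`, `frames` (original indices),
#'   `gimbal` flags.
#' @export
dof_trace <- function(scapula_poses, humerus_poses,
                      glenoid_frame = rigid_pose(), head_frame = rigid_pose(),
                      frame_rate = 120) {
  ok <- !vapply(scapula_poses, is.null, TRUE) & !vapply(humerus_poses, is.null, TRUE)
  idx <- which(ok)
  rows <- lapply(idx, function(i)
    relative_dof(scapula_poses[[i]], humerus_poses[[i]], glenoid_frame, head_frame))
  dof <- do.call(rbind, rows)
  colnames(dof) <- dof_names
  structure(list(dof = dof, frame_rate = frame_rate, frames = idx,
                 gimbal = vapply(rows, function(r) isTRUE(attr(r, "gimbal_warning")), TRUE)),
            class = "DofTrace")
}

## centered moving-average low-pass used only for cycle segmentation
lowpass_ma <- function(x, window) {
  if (window <= 1) return(x)
  k <- rep(1 / window, window)
  n <- length(x)
  xp <- c(rep(x[1], window), x, rep(x[n], window))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(window + 1):(window + n)])
}

#' Segment a DOF trace into gait cycles
#'
#' Cycle boundaries are successive positive-going crossings of the mean level
#' of a reference DOF after low-pass smoothing; each segment is resampled to
#' 101 samples (0-100% of the gait cycle, the biomechanics convention). By
#' default the reference DOF is the one with the largest peak-to-peak
#' amplitude.
#'
#' @param trace `DofTrace`.
#' @param ref_dof reference DOF name or `"auto"`.
#' @param smooth_s smoothing window, seconds.
#' @param n_samples samples per resampled cycle.
#' @param smooth_dofs apply the same low-pass to all six DOFs before
#'   resampling (default TRUE). Suppresses frame-to-frame tracking jitter,
#'   the standard treatment of optical-capture kinematics before cycle
#'   averaging.
#' @return list of cycles, each an `n_samples` x 6 matrix, with attributes
#'   `boundaries` (start frames, in trace rows) and `ref_dof`.
#' @export
segment_cycles <- function(trace, ref_dof = "auto", smooth_s = 0.05,
                           n_samples = 101, smooth_dofs = TRUE) {
  stopifnot(inherits(trace, "DofTrace"))
  dof <- trace$dof
  if (any(!is.finite(dof))) stop("non-finite DOF samples")
  if (identical(ref_dof, "auto")) {
    p2p <- apply(dof, 2, function(x) diff(range(x)))
    ref_dof <- dof_names[which.max(p2p)]
  }
  x <- dof[, ref_dof]
  if (diff(range(x)) < 1e-9) stop("no cycles detected: reference DOF is constant")
  win <- max(1, round(smooth_s * trace$frame_rate))
  # crossing detection runs on a heavily smoothed reference: a half-period
  # moving average suppresses the second harmonic, so mean-level crossings
  # sit on the steep flank of the fundamental and boundary jitter stays small
  period <- dominant_period(x)
  xs <- lowpass_ma(x, max(win, round(period / 2)))
  level <- mean(xs)
  if (smooth_dofs) dof <- apply(dof, 2, lowpass_ma, window = win)
  i_up <- which(xs[-length(xs)] < level & xs[-1] >= level)
  if (length(i_up) < 2)
    stop("no cycles detected: fewer than 2 upward crossings of the mean level")
  # refine each boundary on the lightly smoothed reference: the heavy
  # half-period window straddles cycle boundaries and lets an atypical
  # neighboring stride drag the crossing by several frames
  # cascade: coarse crossings on the heavy signal, refined on progressively
  # lighter signals within a shrinking radius; smoothing windows that span a
  # cycle boundary let an atypical neighboring stride drag the crossing, so
  # the final position comes from a nearly raw reference
  refine <- function(pos, sig, radius) {
    s_up <- which(sig[-length(sig)] < level & sig[-1] >= level)
    vapply(pos, function(i) {
      cand <- s_up[abs(s_up - i) <= radius]
      if (!length(cand)) return(as.numeric(i))
      j <- cand[which.min(abs(cand - i))]
      j + (level - sig[j]) / (sig[j + 1] - sig[j])
    }, numeric(1))
  }
  up <- refine(i_up, lowpass_ma(x, win), period / 3)
  up <- refine(round(up), lowpass_ma(x, 3), win)
  up <- unique(up)
  # each cycle starts at a detected crossing; its end is the start plus the
  # spectral period rather than the next crossing, so a mislocated boundary
  # (e.g. beside a grossly atypical stride) cannot warp its neighbor
  grid <- seq_len(nrow(dof))
  up <- up[up + period <= nrow(dof)]
  if (length(up) < 1) stop("no complete cycles in trace")
  cycles <- lapply(seq_along(up), function(k) {
    s_new <- seq(up[k], up[k] + period, length.out = n_samples)
    out <- apply(dof, 2, function(col) approx(grid, col, xout = s_new)$y)
    colnames(out) <- dof_names
    out
  })
  attr(cycles, "boundaries") <- up
  attr(cycles, "ref_dof") <- ref_dof
  cycles
}

## dominant period (frames) from the discrete power spectrum
dominant_period <- function(x) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[2:floor(n / 2)]
  k <- which.max(sp)  # k cycles over the record
  n / k
}

resample_cycle <- function(seg, n_samples) {
  n <- nrow(seg)
  s_old <- seq(0, 1, length.out = n)
  s_new <- seq(0, 1, length.out = n_samples)
  out <- apply(seg, 2, function(col) approx(s_old, col, xout = s_new)$y)
  colnames(out) <- dof_names
  out
}

#' Reject abnormal gait cycles with the mean +/- 1 SD band rule
#'
#' The band is the pointwise (per 1% of cycle, per DOF) mean +/- 1 SD envelope
#' over all cycles. A cycle is removed when, for any DOF, the fraction of its
#' samples lying strictly outside the band exceeds `band_tol`. The pass is
#' single-shot: the band is not refitted after removals. Retained cycles are
#' averaged pointwise into the representative cycle.
#'
#' @param cycles list of resampled cycle matrices (from [segment_cycles()]).
#' @param band_tol tolerated fraction of out-of-band samples per DOF
#'   (default 0.05).
#' @return object of class `GaitCycleSet`: `cycles`, `retained_mask`,
#'   `representative` (mean cycle over retained), `band` (list `lo`, `hi`,
#'   `mean`, `sd`), `band_tol`.
#' @export
reject_outlier_cycles <- function(cycles, band_tol = 0.05) {
  n <- length(cycles)
  if (n < 3) stop("need at least 3 cycles to form a mean +/- 1 SD band")
  arr <- simplify2array(cycles)              # samples x 6 x cycles
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), sd)
  eps <- 1e-9  # boundary counts as in-band, robust to float noise
  lo <- mu - sdv - eps; hi <- mu + sdv + eps
  frac_out <- sapply(seq_len(n), function(k) {
    out <- arr[, , k] < lo | arr[, , k] > hi
    apply(out, 2, mean)
  })                                           # 6 x n
  retained <- apply(frac_out, 2, function(f) all(f <= band_tol))
  if (!any(retained))
    stop("all cycles rejected; consider increasing band_tol")
  rep_cycle <- apply(arr[, , retained, drop = FALSE], c(1, 2), mean)
  colnames(rep_cycle) <- dof_names
  structure(list(cycles = cycles, retained_mask = retained,
                 representative = rep_cycle,
                 band = list(lo = lo, hi = hi, mean = mu, sd = sdv),
                 band_tol = band_tol),
            class = "GaitCycleSet")
}

#' @export
print.GaitCycleSet <- function(x, ...) {
  cat(sprintf("GaitCycleSet: %d/%d cycles retained (band tol %.0f%%)\n",
              sum(x$retained_mask), length(x$cycles), 100 * x$band_tol))
  invisible(x)
}

#' Reconstruct relative poses along a representative cycle
#'
#' Turns the representative 6-DOF cycle back into humerus-in-glenoid
#' `RigidPose`s, one per cycle sample, for strain mapping.
#'
#' @param representative 101 x 6 DOF matrix (mm / degrees).
#' @param every keep every `every`-th sample (thins the strain computation).
#' @return list of `RigidPose`.
#' @export
cycle_to_poses <- function(representative, every = 1) {
  idx <- seq(1, nrow(representative), by = every)
  lapply(idx, function(i) {
    d <- representative[i, ]
    rigid_pose(euler_zyx_matrix(d["rx"], d["ry"], d["rz"]), d[1:3],
               frame_index = i)
  })
}
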