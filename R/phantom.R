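#' Measure the phantom over all tracked frames
#'
#' Per frame, each block's pose is estimated from its six marker points (two
#' triads pooled into one least-squares fit); the model ball centers and block
#' axes are transformed to the lab frame, giving the center distance and
#' block angle for that frame. Frames whose pose fit fails are dropped with a
#' count.
#'
#' @param phantom `PhantomRecording` from [make_phantom()], or a compatible
#'   list with `tracks` and `model`.
#' @return object of class `PhantomMeasurement`: per-frame `distance` (mm)
#'   and `angle` (degrees), `truth`, `n_frames`, `n_dropped`.
#' @export
measure_phantom <- function(phantom) {
  model <- phantom$model
  tracks <- phantom$tracks
  nfr <- nrow(tracks[[1]])
  body_pts <- function(blk) {
    pts <- rbind(model[[blk]]$triads$t1, model[[blk]]$triads$t2)
    rownames(pts) <- paste(blk, rep(c("t1", "t2"), each = 3),
                           rep(letters[1:3], 2), sep = "_")
    pts
  }
  measure <- function(f) {
    res <- tryCatch({
      poses <- lapply(c("a", "b"), function(blk) {
        P <- body_pts(blk)
        Q <- do.call(rbind, lapply(rownames(P), function(m) tracks[[m]][f, ]))
        estimate_rigid_pose(P, Q)
      })
      ball_a <- drop(apply_pose(poses[[1]], model$a$ball))
      ball_b <- drop(apply_pose(poses[[2]], model$b$ball))
      ax_a <- as.numeric(poses[[1]]$rotation %*% model$a$axis)
      ax_b <- as.numeric(poses[[2]]$rotation %*% model$b$axis)
      # block angle measured between the -a and +b directions, matching the
      # construction angle (blocks antiparallel at 0 degrees)
      cosang <- sum(-ax_a * ax_b)
      c(vnorm(ball_a - ball_b),
        rad2deg(acos(pmin(1, pmax(-1, cosang)))))
    }, error = function(e) c(NA_real_, NA_real_))
    res
  }
  m <- vapply(seq_len(nfr), measure, numeric(2))
  ok <- !is.na(m[1, ])
  if (sum(ok) < 2) stop("fewer than 2 frames with a valid pose")
  structure(list(distance = m[1, ok], angle = m[2, ok],
                 truth = phantom$truth, n_frames = sum(ok),
                 n_dropped = sum(!ok)),
            class = "PhantomMeasurement")
}

#' Bias and precision of phantom measurements
#'
#' Bias is `mean(measured - truth)`. Precision is the +/- spread of the
#' measurements about their own mean: 1 SD by default, or the 95% central
#' range (`"range95"`, reported as the half-width pair).
#'
#' @param m `PhantomMeasurement`.
#' @param precision_mode `"sd"` or `"range95"`.
#' @param configuration optional configuration label (e.g. `"30"`).
#' @return data.frame of class `BiasPrecision`: one row per quantity with
#'   `bias`, `precision_plus`, `precision_minus`.
#' @export
bias_precision <- function(m, precision_mode = c("sd", "range95"),
                           configuration = NA) {
  precision_mode <- match.arg(precision_mode)
  one <- function(x, truth, quantity) {
    spread <- if (precision_mode == "sd") {
      s <- sd(x); c(s, s)
    } else {
      q <- unname(stats::quantile(x, c(0.975, 0.025)))
      c(q[1] - mean(x), mean(x) - q[2])
    }
    data.frame(quantity = quantity, configuration = configuration,
               bias = mean(x) - truth,
               precision_plus = spread[1], precision_minus = spread[2])
  }
  out <- rbind(one(m$distance, m$truth$distance, "center_distance_mm"),
               one(m$angle, m$truth$angle, "block_angle_deg"))
  class(out) <- c("BiasPrecision", class(out))
  out
}

#' Propagate tracking errors to strain and contact-area errors
#'
#' Emulates the in vivo error analysis: the relative humerus-in-glenoid pose
#' of a loaded shoulder model is perturbed within the bias and precision
#' measured on the phantom, and the average cumulative contact strain and
#' contact area ratio are recomputed. The systematic offset (bias applied as
#' a translation along the joint approach axis and a rotation about the
#' medial-lateral axis) gives the strain/area bias; `n_samples` uniform draws
#' from the +/- precision box over the 6-DOF perturbation space give the
#' precision envelope (min/max deviation from the unperturbed value).
#'
#' @param shoulder `ShoulderModel`.
#' @param base_pose loaded relative pose (must produce contact).
#' @param bp `BiasPrecision` data.frame from [bias_precision()].
#' @param n_samples perturbation draws for the precision envelope.
#' @param threshold contact threshold, mm.
#' @param seed integer seed for the perturbation draws.
#' @return data.frame with rows `mean_strain_pct` and `area_ratio_pct`:
#'   `bias`, `precision_plus`, `precision_minus`, and a `no_contact` flag
#'   set when a perturbation eliminated all contact (the envelope bound is
#'   then reported from the remaining draws).
#' @export
propagate_to_strain <- function(shoulder, base_pose, bp, n_samples = 100,
                                threshold = 0.25, seed = 1L) {
  stopifnot(inherits(bp, "BiasPrecision"))
  d_row <- bp[bp$quantity == "center_distance_mm", ]
  a_row <- bp[bp$quantity == "block_angle_deg", ]
  evaluate <- function(pose) {
    res <- strain_over_cycle(shoulder, list(pose), threshold = threshold)
    c(strain = mean_cumulative_strain(res$cumulative, res$vertex_area),
      area = res$cumulative$contact_area_ratio)
  }
  base <- evaluate(base_pose)

  perturb <- function(dt, da) {
    # dt: 3 translations (mm); da: 3 rotations (degrees)
    compose_pose(rigid_pose(euler_zyx_matrix(da[1], da[2], da[3]), dt), base_pose)
  }
  biased <- evaluate(perturb(c(0, 0, d_row$bias), c(a_row$bias, 0, 0)))
  bias <- biased - base

  pd <- c(d_row$precision_plus, d_row$precision_minus)
  pa <- c(a_row$precision_plus, a_row$precision_minus)
  if (all(c(pd, pa) == 0)) {
    env <- matrix(0, 2, 2)
    no_contact <- FALSE
  } else {
    draws <- with_seed(substream_seed(seed, "propagation"), {
      lapply(seq_len(n_samples), function(i) {
        dt <- runif(3, -pd[2], pd[1])
        da <- runif(3, -pa[2], pa[1])
        evaluate(perturb(dt, da)) - base
      })
    })
    D <- do.call(rbind, draws)
    no_contact <- any(D[, "strain"] == -base["strain"] & base["strain"] > 0)
    env <- rbind(range(D[, "strain"]), range(D[, "area"]))
  }
  out <- data.frame(quantity = c("mean_strain_pct", "area_ratio_pct"),
                    bias = as.numeric(bias),
                    precision_minus = -env[, 1], precision_plus = env[, 2],
                    no_contact = no_contact)
  out
}
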