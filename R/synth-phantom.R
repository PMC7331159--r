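#' Generate a synthetic two-block accuracy phantom
#'
#' Two rigid rectangular blocks, each carrying a plastic ball at one end and
#' two marker triads, set at a fixed relative angle. The whole assembly
#' undergoes a random rigid motion every frame (emulating hand-waving the
#' phantom through the capture volume) while the ball center distance and
#' block angle stay constant — these constants are the ground truth the
#' motion-tracking measurement chain is audited against.
#'
#' @param angle relative block angle, degrees. The physical phantom used
#'   0, 30 and 60; other values are accepted with a warning.
#' @param ball_gap ground-truth distance between the two ball centers, mm.
#' @param noise_sd isotropic marker noise SD, mm.
#' @param n_frames number of captured frames (default 2000).
#' @param seed integer seed.
#' @return object of class `PhantomRecording`: `tracks` (named list of
#'   n_frames x 3 marker matrices), `model` (body-frame triads, ball centers,
#'   block axes per block), `truth` (`distance`, `angle`), `spec`.
#' @export
make_phantom <- function(angle, ball_gap = 100, noise_sd = 0.1,
                         n_frames = 2000, seed = 1L) {
  if (!angle %in% c(0, 30, 60))
    warning("phantom angle ", angle, " outside the standard {0, 30, 60} set")
  stopifnot(ball_gap > 0, noise_sd >= 0, n_frames >= 2)

  triad <- function(center, normal) {
    n <- unit(normal)
    u <- unit(cross3(n, if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
    v <- cross3(n, u)
    s <- 25 / sqrt(3)
    t(sapply(0:2, function(k) center + s * (cos(2 * pi * k / 3) * u +
                                              sin(2 * pi * k / 3) * v)))
  }
  # block A along -X with its ball at (-ball_gap/2, 0, 0); block B rotated by
  # `angle` about Z, ball at (+ball_gap/2, 0, 0)
  Rb <- axis_angle_matrix(c(0, 0, 1), angle)
  model <- list(
    a = list(ball = c(-ball_gap / 2, 0, 0), axis = c(-1, 0, 0),
             triads = list(t1 = triad(c(-ball_gap / 2 - 40, 0, 30), c(0, 0, 1)),
                           t2 = triad(c(-ball_gap / 2 - 90, 0, 30), c(0, 0, 1)))),
    b = list(ball = c(ball_gap / 2, 0, 0), axis = as.numeric(Rb %*% c(1, 0, 0)),
             triads = list(t1 = triad(c(ball_gap / 2, 0, 0) + as.numeric(Rb %*% c(40, 0, 30)), c(0, 0, 1)),
                           t2 = triad(c(ball_gap / 2, 0, 0) + as.numeric(Rb %*% c(90, 0, 30)), c(0, 0, 1)))))

  tracks <- with_seed(substream_seed(seed, "phantom"), {
    out <- list()
    pts <- list()
    for (blk in c("a", "b"))
      for (tr in c("t1", "t2"))
        for (k in 1:3)
          pts[[paste(blk, tr, letters[k], sep = "_")]] <-
            model[[blk]]$triads[[tr]][k, ]
    nm <- names(pts)
    P <- do.call(rbind, pts)
    arr <- array(NA_real_, c(n_frames, 3, length(nm)))
    for (f in seq_len(n_frames)) {
      R <- random_rotation()
      tr <- runif(3, -500, 500)
      lab <- sweep(P %*% t(R), 2, tr, "+")
      arr[f, , ] <- t(lab + matrix(rnorm(length(nm) * 3, sd = noise_sd),
                                   length(nm), 3))
    }
    out <- lapply(seq_along(nm), function(j) arr[, , j, drop = TRUE])
    names(out) <- nm
    out
  })

  structure(list(tracks = tracks, model = model,
                 truth = list(distance = ball_gap, angle = angle),
                 spec = list(angle = angle, ball_gap = ball_gap,
                             noise_sd = noise_sd, n_frames = as.integer(n_frames),
                             seed = as.integer(seed))),
            class = "PhantomRecording")
}

#' Specification of a coupled regional pre/post scenario
#'
#' Ground truth for correlation-recovery studies: regional strain changes
#' drawn uniformly over `delta_strain_range`, with T2* change linearly coupled
#' through `coupling_slope` plus Gaussian noise. When `coupling_noise_sd` is
#' `NULL` it is derived in closed form so the population correlation equals
#' `target_r` (with uniform strain the population r is
#' `slope*sd_x / sqrt(slope^2 sd_x^2 + sigma^2)`).
#'
#' @param n_regions number of regions pooled into the correlation (>= 3).
#' @param delta_strain_range range of regional strain change, percent.
#' @param coupling_slope ms of T2* change per percent strain change.
#' @param coupling_noise_sd SD of the coupling noise, ms, or `NULL`.
#' @param target_r population correlation used to derive the noise SD
#'   (default 0.726, the strength of coupling reported for shoulder cartilage
#'   three months after unilateral tendon resection).
#' @param seed integer seed.
#' @return object of class `CoupledScenarioSpec`.
#' @export
coupled_spec <- function(n_regions = 54, delta_strain_range = c(-3, 3),
                         coupling_slope = 1.0, coupling_noise_sd = NULL,
                         target_r = 0.726, seed = 1L) {
  stopifnot(n_regions >= 3, length(delta_strain_range) == 2,
            diff(delta_strain_range) > 0)
  sd_x <- diff(delta_strain_range) / sqrt(12)
  if (is.null(coupling_noise_sd)) {
    stopifnot(abs(target_r) > 0, abs(target_r) <= 1)
    coupling_noise_sd <- abs(coupling_slope) * sd_x * sqrt(1 / target_r^2 - 1)
  }
  stopifnot(coupling_noise_sd >= 0)
  denom <- sqrt(coupling_slope^2 * sd_x^2 + coupling_noise_sd^2)
  population_r <- if (denom == 0) 0 else sign(coupling_slope) *
    abs(coupling_slope) * sd_x / denom
  structure(list(n_regions = as.integer(n_regions),
                 delta_strain_range = delta_strain_range,
                 coupling_slope = coupling_slope,
                 coupling_noise_sd = coupling_noise_sd,
                 population_r = population_r,
                 seed = as.integer(seed)),
            class = "CoupledScenarioSpec")
}

#' Generate a coupled regional Delta-strain / Delta-T2* sample
#'
#' @param spec a [coupled_spec()].
#' @return list with `delta_strain` (%), `delta_t2star` (ms), the generating
#'   `slope`, the `population_r`, and the realized `sample_r`.
#' @export
make_coupled_scenario <- function(spec) {
  stopifnot(inherits(spec, "CoupledScenarioSpec"))
  with_seed(substream_seed(spec$seed, "coupled"), {
    x <- runif(spec$n_regions, spec$delta_strain_range[1], spec$delta_strain_range[2])
    eps <- if (spec$coupling_noise_sd > 0)
      rnorm(spec$n_regions, 0, spec$coupling_noise_sd) else 0
    y <- spec$coupling_slope * x + eps
    list(delta_strain = x, delta_t2star = y, slope = spec$coupling_slope,
         population_r = spec$population_r,
         sample_r = if (sd(y) == 0) NA_real_ else unname(cor(x, y)))
  })
}
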