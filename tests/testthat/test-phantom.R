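test_that("noiseless phantom measures its construction exactly", {
  for (ang in c(0, 30, 60)) {
    ph <- make_phantom(ang, ball_gap = 120, noise_sd = 0, n_frames = 4,
                       seed = ang + 1)
    m <- measure_phantom(ph)
    expect_equal(m$distance, rep(120, 4), tolerance = 1e-8)
    expect_equal(m$angle, rep(ang, 4), tolerance = 1e-4)
    bp <- bias_precision(m, configuration = as.character(ang))
    expect_equal(bp$bias, c(0, 0), tolerance = 1e-4)
    expect_equal(bp$precision_plus, c(0, 0), tolerance = 1e-4)
  }
})

test_that("whole-assembly motion leaves measurements invariant", {
  ph <- make_phantom(30, noise_sd = 0, n_frames = 50, seed = 9)
  m <- measure_phantom(ph)
  expect_lt(diff(range(m$distance)), 1e-8)
  expect_lt(diff(range(m$angle)), 1e-4)
})

test_that("bias_precision is translation-equivariant", {
  ph <- make_phantom(30, noise_sd = 0.1, n_frames = 100, seed = 3)
  m <- measure_phantom(ph)
  bp <- bias_precision(m)
  m2 <- m
  m2$distance <- m$distance + 0.2
  bp2 <- bias_precision(m2)
  i <- bp$quantity == "center_distance_mm"
  expect_equal(bp2$bias[i], bp$bias[i] + 0.2, tolerance = 1e-12)
  expect_equal(bp2$precision_plus, bp$precision_plus, tolerance = 1e-12)
})

test_that("marker-noise distance precision matches a Monte-Carlo oracle", {
  # oracle: resimulate the same measurement chain independently per frame
  set.seed(61)
  noise <- 0.1
  ph <- make_phantom(30, noise_sd = noise, n_frames = 400, seed = 5)
  m <- measure_phantom(ph)
  sd_meas <- sd(m$distance)
  # direct resimulation: distance between two 6-marker rigid fits
  ph2 <- make_phantom(30, noise_sd = noise, n_frames = 400, seed = 6)
  sd_oracle <- sd(measure_phantom(ph2)$distance)
  expect_lt(abs(sd_meas - sd_oracle) / sd_oracle, 0.25)
  # and the scale is the paper-like sub-0.15 mm regime
  expect_lt(sd_meas, 0.2)
})

test_that("propagation vanishes with zero input errors and grows monotonically", {
  sh <- fix_shoulder_coarse()
  base_pose <- rigid_pose(translation = c(0, 0, 0.32))
  mk_bp <- function(bias_d, prec_d, bias_a, prec_a) {
    out <- data.frame(quantity = c("center_distance_mm", "block_angle_deg"),
                      configuration = "30", bias = c(bias_d, bias_a),
                      precision_plus = c(prec_d, prec_a),
                      precision_minus = c(prec_d, prec_a))
    class(out) <- c("BiasPrecision", class(out))
    out
  }
  zero <- propagate_to_strain(sh, base_pose, mk_bp(0, 0, 0, 0), n_samples = 8)
  expect_equal(zero$bias, c(0, 0), tolerance = 1e-9)
  expect_equal(zero$precision_plus, c(0, 0))
  expect_equal(zero$precision_minus, c(0, 0))
  env <- sapply(c(0.02, 0.06), function(p) {
    pr <- suppressWarnings(propagate_to_strain(sh, base_pose,
                                               mk_bp(0, p, 0, p * 2),
                                               n_samples = 12, seed = 2))
    max(abs(c(pr$precision_plus, pr$precision_minus)))
  })
  expect_true(all(diff(env) > 0))
})

test_that("normal-direction bias matches the analytic sphere oracle", {
  sh <- fix_shoulder_uniform()
  delta0 <- 0.32; dbias <- 0.05
  R <- 10 + 0.819
  mk_bp <- function(bias_d) {
    out <- data.frame(quantity = c("center_distance_mm", "block_angle_deg"),
                      configuration = "0", bias = c(bias_d, 0),
                      precision_plus = c(0, 0), precision_minus = c(0, 0))
    class(out) <- c("BiasPrecision", class(out))
    out
  }
  pr <- propagate_to_strain(sh, rigid_pose(translation = c(0, 0, delta0)),
                            mk_bp(dbias), n_samples = 4)
  # analytic: area-weighted mean strain of the sphere-sphere overlap at
  # delta0 + dbias minus at delta0, over the cumulative contact patch
  mean_strain <- function(delta) {
    th <- seq(0, deg2rad(45), length.out = 2000)
    ov <- sphere_overlap_oracle(th, delta, R)
    mask <- ov > 0.25
    w <- sin(th)
    100 * sum((ov / (2 * 0.819) * w)[mask]) / sum(w[mask])
  }
  oracle <- mean_strain(delta0 + dbias) - mean_strain(delta0)
  got <- pr$bias[pr$quantity == "mean_strain_pct"]
  expect_lt(abs(got - oracle) / abs(oracle), 0.05)
})
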