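test_that("uniform-thickness shoulder builds additive sphere caps", {
  sh <- make_shoulder(shoulder_spec(humeral_head_radius = 10,
                                    thickness_mean = 0.8, thickness_sd = 0,
                                    seed = 1))
  r_outer <- sqrt(rowSums(sh$humerus$cartilage$vertices^2))
  expect_equal(r_outer, rep(10.8, length(r_outer)), tolerance = 1e-9)
  r_sub <- sqrt(rowSums(sh$humerus$subchondral$vertices^2))
  expect_equal(r_sub, rep(10, length(r_sub)), tolerance = 1e-9)
})

test_that("sampled thickness field hits the target mean within 2%", {
  sh <- fix_shoulder()
  va <- vertex_areas(sh$humerus$subchondral)
  m <- sum(sh$thickness$humeral * va) / sum(va)
  expect_lt(abs(m - 0.819) / 0.819, 0.02)
  expect_true(all(sh$thickness$humeral > 0))
  expect_true(all(sh$thickness$scapular > 0))
})

test_that("neutral pose is conforming: zero interpenetration, zero gap", {
  sh <- fix_shoulder()
  ov <- overlap_depth(sh$humerus$cartilage, sh$humerus$subchondral,
                      sh$scapula$cartilage, sh$scapula$subchondral)
  # zero to mesh tolerance: chord sag of the faceted socket at this
  # resolution is ~1.5e-3 mm
  expect_lt(max(ov), 2e-3)
  # glenoid articulating surface radius equals humeral outer radius per ray
  th <- acos(pmin(1, sh$scapula$cartilage$vertices[, 3] /
                    sqrt(rowSums(sh$scapula$cartilage$vertices^2))))
  ph <- atan2(sh$scapula$cartilage$vertices[, 2], sh$scapula$cartilage$vertices[, 1])
  expect_equal(sqrt(rowSums(sh$scapula$cartilage$vertices^2)),
               10 + sh$thickness_fn$humeral(th, ph), tolerance = 1e-9)
})

test_that("shoulder generation is deterministic and validates conformity", {
  a <- make_shoulder(shoulder_spec(seed = 42))
  b <- make_shoulder(shoulder_spec(seed = 42))
  expect_identical(a$humerus$cartilage$vertices, b$humerus$cartilage$vertices)
  expect_identical(a$thickness, b$thickness)
  expect_error(make_shoulder(shoulder_spec(cap_half_angle_glenoid = 85,
                                           cap_half_angle_humeral = 80)),
               "non-conforming")
  expect_error(make_shoulder(shoulder_spec(glenoid_radius = 14)),
               "non-conforming")
})

test_that("noiseless gait yields identical cycles and exact pose recovery", {
  sh <- fix_shoulder_coarse()
  g <- make_gait(gait_spec(n_cycles = 4, marker_noise_sd = 0,
                           cycle_amp_sd = 0, cycle_noise_sd = rep(0, 6),
                           cycle_shape_sd = rep(0, 6), episode_length = 100,
                           seed = 3), sh)
  expect_equal(g$dof_truth[1:80, ], g$dof_truth[81:160, ], tolerance = 1e-12)
  bs <- cartstrain:::triad_points(sh$triads, c("scap1", "scap2"))
  bh <- cartstrain:::triad_points(sh$triads, c("hum1", "hum2"))
  tr <- dof_trace(track_poses(g$tracks, bs), track_poses(g$tracks, bh),
                  frame_rate = 120)
  expect_lt(max(abs(tr$dof - g$dof_truth)), 1e-9)
})

test_that("gait generation is deterministic in the seed", {
  sh <- fix_shoulder_coarse()
  g1 <- make_gait(gait_spec(n_cycles = 3, seed = 5), sh)
  g2 <- make_gait(gait_spec(n_cycles = 3, seed = 5), sh)
  expect_identical(g1$tracks, g2$tracks)
  g3 <- make_gait(gait_spec(n_cycles = 3, seed = 6), sh)
  expect_false(identical(g1$tracks, g3$tracks))
  expect_error(gait_spec(frames_per_cycle = 3), "frames_per_cycle")
})

test_that("noiseless two-tissue volume fits exactly and flags fluid", {
  sh <- fix_shoulder_coarse()
  es <- echo_spec(voxel_size = rep(0.6, 3), noise_sd = 0,
                  tissue_t2star = list(cartilage = c(25, 0), fluid = c(55, 0)),
                  seed = 1)
  v <- make_multiecho_volume(es, sh)
  m <- map_volume(v)
  cart <- v$labels == 1
  expect_equal(unname(m$t2star[cart]), rep(25, sum(cart)), tolerance = 1e-6)
  fluid <- v$labels == 2
  expect_true(all(m$reason[fluid] == "cutoff_exceeded"))
  expect_error(echo_spec(voxel_size = c(0, 1, 1)), "voxel size")
})

test_that("55 +/- 2 ms fluid is almost entirely removed by the 50 ms cutoff", {
  # Monte-Carlo oracle for the Gaussian tail below the cutoff
  set.seed(101)
  mc <- mean(rnorm(2e5, 55, 2) <= 50)
  expect_lt(mc, 0.03)
  sh <- fix_shoulder_coarse()
  v <- make_multiecho_volume(echo_spec(voxel_size = rep(0.5, 3), noise_sd = 0,
                                       seed = 2), sh)
  m <- map_volume(v)
  fluid <- v$labels == 2
  removed <- mean(m$reason[fluid] == "cutoff_exceeded")
  expect_gt(removed, 0.97)
})

test_that("volume generation is deterministic in the seed", {
  sh <- fix_shoulder_coarse()
  v1 <- make_multiecho_volume(echo_spec(voxel_size = rep(0.8, 3), seed = 4), sh)
  v2 <- make_multiecho_volume(echo_spec(voxel_size = rep(0.8, 3), seed = 4), sh)
  expect_identical(v1$data, v2$data)
})

test_that("phantom honors its ground truth and warns off-grid angles", {
  ph <- make_phantom(30, ball_gap = 100, noise_sd = 0, n_frames = 5, seed = 1)
  m <- measure_phantom(ph)
  expect_equal(m$distance, rep(100, 5), tolerance = 1e-9)
  expect_equal(m$angle, rep(30, 5), tolerance = 1e-9)
  expect_warning(make_phantom(45, n_frames = 2, seed = 1), "outside the standard")
  ph0 <- make_phantom(0, noise_sd = 0, n_frames = 3, seed = 2)
  bp <- bias_precision(measure_phantom(ph0))
  # bias sign convention: measured - truth
  expect_equal(bp$bias, c(0, 0), tolerance = 1e-4)
})

test_that("coupled scenario recovers exact correlations in the noise-free limit", {
  s1 <- make_coupled_scenario(coupled_spec(coupling_noise_sd = 0, seed = 1))
  expect_equal(s1$sample_r, 1)
  s2 <- make_coupled_scenario(coupled_spec(coupling_slope = -2,
                                           coupling_noise_sd = 0, seed = 1))
  expect_equal(s2$sample_r, -1)
  # derived noise SD yields the requested population correlation
  sp <- coupled_spec(target_r = 0.726, seed = 1)
  expect_equal(sp$population_r, 0.726, tolerance = 1e-12)
  sd_x <- diff(sp$delta_strain_range) / sqrt(12)
  expect_equal(sp$coupling_noise_sd,
               sp$coupling_slope * sd_x * sqrt(1 / 0.726^2 - 1),
               tolerance = 1e-12)
})
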