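test_that("thickness of concentric sphere caps matches the radial construction", {
  sub <- sphere_cap_surface(10, 80, n_theta = 24, n_phi = 48)
  car <- sphere_cap_surface(10.8, 80, n_theta = 24, n_phi = 48)
  tm <- thickness_map(sub, car)
  expect_true(all(tm$mask))
  expect_equal(tm$thickness, rep(0.8, length(tm$thickness)), tolerance = 1e-3)
})

test_that("thickness of parallel plates equals their separation", {
  sub <- plate_surface(10, 10, z = 0, nx = 8, ny = 8)
  car <- plate_surface(10, 10, z = 1.2, nx = 8, ny = 8)
  tm <- thickness_map(sub, car)
  expect_equal(tm$thickness[tm$mask], rep(1.2, sum(tm$mask)), tolerance = 1e-9)
})

test_that("thickness map recovers the generator's varying ground truth", {
  sh <- fix_shoulder()
  tm <- thickness_map(sh$humerus$subchondral, sh$humerus$cartilage)
  err <- tm$thickness - sh$thickness$humeral
  rms <- sqrt(mean(err^2, na.rm = TRUE))
  expect_lt(rms, 0.02 * mean(sh$thickness$humeral))
})

test_that("misaligned surfaces raise a thickness error", {
  sub <- plate_surface(10, 10, z = 0)
  far <- plate_surface(10, 10, z = -5)  # behind the normals
  expect_error(thickness_map(sub, far), "misaligned")
})

test_that("overlap matches the closed-form sphere interpenetration", {
  sh <- fix_shoulder_uniform()
  R <- 10 + 0.819
  v <- sh$humerus$cartilage$vertices
  theta <- acos(pmin(1, v[, 3] / sqrt(rowSums(v^2))))
  sel <- theta < deg2rad(40)  # inside glenoid coverage, away from the rim
  for (delta in c(0.3)) {
    pose <- rigid_pose(translation = c(0, 0, delta))
    ov <- overlap_depth(transform_surface(sh$humerus$cartilage, pose),
                        transform_surface(sh$humerus$subchondral, pose),
                        sh$scapula$cartilage, sh$scapula$subchondral)
    expect_equal(max(ov), delta, tolerance = 0.02 * delta)
    oracle <- sphere_overlap_oracle(theta[sel], delta, R)
    rms <- sqrt(mean((ov[sel] - oracle)^2))
    expect_lt(rms / delta, 0.03)
  }
})

test_that("contact strain implements ratio, threshold and masking", {
  # overlap 0.30 / combined 1.6 mm -> 18.75%
  sm <- contact_strain(rep(0.3, 5), rep(0.8, 5), rep(0.8, 5))
  expect_equal(sm$strain, rep(0.1875, 5))
  expect_true(all(sm$contact_mask))
  # uniform overlap below the 0.25 mm threshold -> no contact anywhere
  sm2 <- contact_strain(rep(0.20, 5), rep(0.8, 5), rep(0.8, 5))
  expect_false(any(sm2$contact_mask))
  expect_equal(sm2$strain, rep(0, 5))
  # zero overlap -> all-zero strain
  sm3 <- contact_strain(rep(0, 5), rep(0.8, 5), rep(0.8, 5))
  expect_equal(sm3$strain, rep(0, 5))
  # zero combined thickness at a contacting vertex is masked with a warning
  expect_warning(sm4 <- contact_strain(c(0.3, 0.3), c(0, 0.8), c(0, 0.8)),
                 "masked")
  expect_false(sm4$contact_mask[1])
  # own-layer denominator option
  sm5 <- contact_strain(rep(0.3, 2), rep(0.8, 2), denominator = "own-layer")
  expect_equal(sm5$strain, rep(0.375, 2))
})

test_that("cumulation is max/union and frame-order invariant", {
  va <- rep(1, 4)
  f1 <- contact_strain(c(0.3, 0, 0, 0), rep(0.8, 4), rep(0.8, 4))
  f2 <- contact_strain(c(0, 0.4, 0, 0), rep(0.8, 4), rep(0.8, 4))
  c1 <- cumulate(list(f1), va)
  expect_equal(c1$strain, f1$strain)
  c12 <- cumulate(list(f1, f2), va)
  expect_equal(c12$contact_area, 2)  # disjoint patches add
  c21 <- cumulate(list(f2, f1), va)
  expect_equal(c12$strain, c21$strain)
  expect_equal(c12$contact_mask, c21$contact_mask)
  expect_true(all(c12$strain >= f1$strain) && all(c12$strain >= f2$strain))
  expect_error(cumulate(list(), va), "empty")
})

test_that("mean cumulative strain is area-weighted", {
  cm <- structure(list(strain = c(0.1, 0.1, 0.2, 0.2),
                       contact_mask = rep(TRUE, 4)), class = "CumulativeMap")
  expect_equal(mean_cumulative_strain(cm), 15)
  expect_equal(mean_cumulative_strain(cm, vertex_area = c(1, 1, 3, 3)), 17.5)
  cm$contact_mask <- rep(FALSE, 4)
  expect_warning(z <- mean_cumulative_strain(cm), "empty")
  expect_equal(z, 0)
})

test_that("strain measures are monotone in approach and threshold", {
  sh <- fix_shoulder_coarse()
  res <- lapply(c(0.28, 0.34, 0.42), function(delta) {
    r <- strain_over_cycle(sh, list(rigid_pose(translation = c(0, 0, delta))))
    c(max_ov = max(r$frames[[1]]$overlap),
      area = r$cumulative$contact_area,
      mean_strain = mean_cumulative_strain(r$cumulative, r$vertex_area))
  })
  m <- do.call(rbind, res)
  expect_true(all(diff(m[, "max_ov"]) > 0))
  expect_true(all(diff(m[, "area"]) >= 0))
  expect_true(all(diff(m[, "mean_strain"]) > 0))
  # threshold monotonicity: contact area non-increasing in the threshold
  pose <- rigid_pose(translation = c(0, 0, 0.4))
  areas <- sapply(c(0.1, 0.25, 0.35), function(th) {
    r <- strain_over_cycle(sh, list(pose), threshold = th)
    r$cumulative$contact_area
  })
  expect_true(all(diff(areas) <= 0))
})

test_that("strain maps are invariant under a common rigid motion", {
  sh <- fix_shoulder_coarse()
  delta_pose <- rigid_pose(translation = c(0, 0, 0.35))
  ca <- transform_surface(sh$humerus$cartilage, delta_pose)
  sa <- transform_surface(sh$humerus$subchondral, delta_pose)
  ov0 <- overlap_depth(ca, sa, sh$scapula$cartilage, sh$scapula$subchondral)
  common <- rigid_pose(euler_zyx_matrix(20, -35, 60), c(15, -8, 30))
  ov1 <- overlap_depth(transform_surface(ca, common),
                       transform_surface(sa, common),
                       transform_surface(sh$scapula$cartilage, common),
                       transform_surface(sh$scapula$subchondral, common))
  expect_equal(ov0, ov1, tolerance = 1e-6)
})
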