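TE5 <- c(3.83, 9.37, 14.91, 20.46, 26.01)

test_that("noiseless exponentials are fit exactly across the range", {
  set.seed(41)
  for (i in 1:40) {
    t2 <- runif(1, 5, 100); s0 <- runif(1, 100, 2000)
    fit <- fit_t2star(s0 * exp(-TE5 / t2), TE5)
    expect_equal(fit$t2star, t2, tolerance = 1e-6)
    expect_equal(fit$s0, s0, tolerance = 1e-4)
    expect_equal(fit$r2, 1, tolerance = 1e-9)
  }
})

test_that("fit is scale-equivariant in the signal amplitude", {
  set.seed(42)
  sig <- 1000 * exp(-TE5 / 30) + rnorm(5, sd = 10)
  f1 <- fit_t2star(sig, TE5)
  f2 <- fit_t2star(5 * sig, TE5)
  expect_equal(f2$t2star, f1$t2star, tolerance = 1e-6)
  expect_equal(f2$s0, 5 * f1$s0, tolerance = 1e-4)
})

test_that("log-linear estimator is available and exact when noiseless", {
  fit <- fit_t2star(800 * exp(-TE5 / 25), TE5, method = "loglinear")
  expect_equal(fit$t2star, 25, tolerance = 1e-9)
})

test_that("voxels over the cutoff are flagged, not refused", {
  sh <- fix_shoulder_coarse()
  es <- echo_spec(voxel_size = rep(0.6, 3), noise_sd = 0,
                  tissue_t2star = list(cartilage = c(25, 0), fluid = c(60, 0)),
                  seed = 1)
  v <- make_multiecho_volume(es, sh)
  m <- map_volume(v)
  fluid <- v$labels == 2
  expect_equal(unname(m$t2star[fluid]), rep(60, sum(fluid)), tolerance = 1e-6)
  expect_true(all(!m$valid[fluid]))
  expect_true(all(m$reason[fluid] == "cutoff_exceeded"))
})

test_that("all-zero volumes fail every voxel fit", {
  vol <- structure(list(data = array(0, c(3, 3, 3, 5)), echo_times = TE5,
                        voxel_size = c(1, 1, 1), origin = c(0, 0, 0)),
                   class = "EchoVolume")
  m <- map_volume(vol)
  expect_true(all(!m$valid))
  expect_true(all(m$reason == "fit_failed"))
})

test_that("lowering the cutoff never adds valid voxels", {
  sh <- fix_shoulder_coarse()
  v <- make_multiecho_volume(echo_spec(voxel_size = rep(0.6, 3), seed = 3), sh)
  m50 <- map_volume(v, cutoff_ms = 50)
  m40 <- map_volume(v, cutoff_ms = 40)
  expect_true(all(m50$valid | !m40$valid))
  expect_gte(sum(m50$valid), sum(m40$valid))
})

test_that("noisy fit bias and SD match a grid-search oracle", {
  set.seed(43)
  t2 <- 30; s0 <- 1000; noise <- 0.02 * s0
  n <- 3000
  S <- matrix(rep(s0 * exp(-TE5 / t2), each = n), n, 5) +
    matrix(rnorm(n * 5, sd = noise), n, 5)
  fit <- cartstrain:::fit_t2star_batch(S, TE5)
  # oracle: profile-S0 grid search over T2* at 0.02 ms resolution
  grid <- seq(15, 60, by = 0.02)
  E <- exp(-outer(1 / grid, TE5))           # nT2 x 5
  ee <- rowSums(E^2)
  crit <- (S %*% t(E))^2 / rep(ee, each = n)
  t2_grid <- grid[max.col(crit, ties.method = "first")]
  expect_lt(abs(mean(fit$t2star) - mean(t2_grid)), 0.05)
  expect_lt(abs(sd(fit$t2star) - sd(t2_grid)) / sd(t2_grid), 0.1)
})

test_that("projection averages valid voxels along the thickness segment", {
  sh <- fix_shoulder_coarse()
  es <- echo_spec(voxel_size = rep(0.4, 3), noise_sd = 0,
                  tissue_t2star = list(cartilage = c(25, 0), fluid = c(55, 0)),
                  seed = 1)
  v <- make_multiecho_volume(es, sh)
  m <- map_volume(v)
  p <- project_to_surface(m, sh$humerus$cartilage, sh$humerus$subchondral)
  # uniform 25 ms cartilage projects to 25 ms; fluid at 55 ms is excluded
  expect_equal(unname(p$t2star[p$mask]), rep(25, sum(p$mask)), tolerance = 0.01)
  expect_gt(mean(p$mask), 0.5)
})

test_that("through-thickness gradient projects to its mid-value", {
  # build a volume with a linear T2* gradient along z over a flat slab
  nx <- 20; nz <- 30
  vs <- c(0.5, 0.5, 0.1)
  t2 <- array(NA_real_, c(nx, nx, nz))
  zmm <- (seq_len(nz) - 1) * vs[3]
  for (k in seq_len(nz)) t2[, , k] <- 20 + 10 * zmm[k] / zmm[nz]  # 20 -> 30
  map <- structure(list(t2star = t2, valid = array(TRUE, dim(t2)),
                        voxel_size = vs, origin = c(0, 0, 0)),
                   class = "T2StarMap")
  sub <- plate_surface(8, 8, z = 0.2, nx = 6, ny = 6)
  car <- plate_surface(8, 8, z = zmm[nz] - 0.2, nx = 6, ny = 6)
  sub$vertices[, 1:2] <- sub$vertices[, 1:2] + 0.5
  car$vertices[, 1:2] <- car$vertices[, 1:2] + 0.5
  p <- project_to_surface(map, car, sub)
  expect_equal(unname(p$t2star[p$mask]), rep(25, sum(p$mask)), tolerance = 0.5)
})

test_that("thickness sensitivity is zero for uniform fields and zero offsets", {
  sh <- fix_shoulder_coarse()
  es <- echo_spec(voxel_size = rep(0.5, 3), noise_sd = 0,
                  tissue_t2star = list(cartilage = c(25, 0), fluid = c(55, 0)),
                  seed = 1)
  m <- map_volume(make_multiecho_volume(es, sh))
  expect_equal(t2star_thickness_sensitivity(m, sh$humerus$cartilage,
                                            sh$humerus$subchondral, delta = 0),
               0)
  s <- t2star_thickness_sensitivity(m, sh$humerus$cartilage,
                                    sh$humerus$subchondral, delta = 0.125)
  expect_lt(s, 0.5)  # uniform field: only boundary/partial-volume residue
})
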