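cap_axis <- list(center = c(0, 0, 0), ml_axis = c(0, 1, 0),
                 posterior_axis = c(1, 0, 0))

test_that("region binning spans posterior to anterior in 20-degree bands", {
  sh <- fix_shoulder_uniform()
  b <- bin_regions(sh$humerus$cartilage, cap_axis)
  # humeral cap (80 deg half-angle) spans 160 degrees in the sagittal plane
  expect_equal(b$n_regions, 8L)
  # vertex nearest the posterior extreme lands in region 1
  expect_equal(b$region[which.min(b$angle_deg)], 1L)
  expect_equal(b$region[which.max(b$angle_deg)], b$n_regions)
  # regions partition the surface
  expect_false(any(is.na(b$region)))
})

test_that("a 180-degree band splits into 9 regions of equal area", {
  hemi <- sphere_cap_surface(10, 90, n_theta = 40, n_phi = 80)
  b <- bin_regions(hemi, cap_axis)
  expect_equal(b$n_regions, 9L)
  va <- vertex_areas(hemi)
  areas <- regional_means(rep(1, length(va)), b, va)$area
  # equal-width angular bands of a hemisphere have equal area
  expect_lt(max(abs(areas / mean(areas) - 1)), 0.03)
})

test_that("regional means agree with brute-force accumulation", {
  sh <- fix_shoulder_uniform()
  b <- bin_regions(sh$humerus$cartilage, cap_axis)
  va <- vertex_areas(sh$humerus$cartilage)
  # constant map
  rm1 <- regional_means(rep(3.5, length(va)), b, va)
  expect_equal(rm1$mean, rep(3.5, b$n_regions))
  # map = region id
  rm2 <- regional_means(as.numeric(b$region), b, va)
  expect_equal(rm2$mean, as.numeric(seq_len(b$n_regions)))
  # random field vs direct summation
  set.seed(51)
  x <- rnorm(length(va))
  rm3 <- regional_means(x, b, va)
  for (k in seq_len(b$n_regions)) {
    sel <- b$region == k
    expect_equal(rm3$mean[k], sum(x[sel] * va[sel]) / sum(va[sel]))
  }
  # empty regions are flagged, not dropped
  x2 <- x; x2[b$region == 2] <- NA
  rm4 <- regional_means(x2, b, va)
  expect_true(rm4$empty[2])
  expect_equal(nrow(rm4), b$n_regions)
})

test_that("pearson matches its definition and the t-test reference", {
  p1 <- pearson(1:10, 2 * (1:10) + 1)
  expect_equal(p1$r, 1)
  expect_lt(p1$p, 1e-6)
  expect_equal(pearson(1:10, -(1:10))$r, -1)
  set.seed(52)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  ours <- pearson(x, y)
  ref <- cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "variance")
})

test_that("ICC(2,1) behaves at the reference points", {
  set.seed(53)
  subj <- rnorm(20, 0, 3)
  M <- cbind(subj, subj, subj)
  r <- icc(M)
  expect_equal(r$icc, 1, tolerance = 1e-9)
  # independent columns: ICC near zero, CI covers zero
  N <- matrix(rnorm(60), 20, 3)
  r0 <- icc(N)
  expect_lt(abs(r0$icc), 0.35)
  expect_lt(r0$ci[1], 0.05)
  expect_error(icc(M[1:3, ]), ">= 2 raters")
  Mna <- M; Mna[1, 1] <- NA
  expect_error(icc(Mna), "missing")
})

test_that("ICC recovers the variance-ratio ground truth in simulation", {
  set.seed(54)
  est <- replicate(60, {
    s <- rnorm(70, 0, 3)
    icc(matrix(rep(s, 3) + rnorm(210, 0, 1), 70, 3))$icc
  })
  expect_lt(abs(mean(est) - 0.9), 0.02)
  # monotone in the variance ratio
  est_lo <- replicate(40, {
    s <- rnorm(70, 0, 1)
    icc(matrix(rep(s, 3) + rnorm(210, 0, 1), 70, 3))$icc
  })
  expect_lt(mean(est_lo), mean(est))
})

test_that("RMS difference summarizes matched samples", {
  a <- rnorm(70)
  expect_equal(rms_difference(list(list(a, a)))$mean, 0)
  expect_equal(rms_difference(list(list(a, a + 0.5)))$mean, 0.5)
  set.seed(55)
  sigma <- 0.12
  reps <- replicate(40, rms_difference(list(list(rnorm(70, sd = sigma),
                                                 rep(0, 70))))$rms)
  expect_lt(abs(mean(reps) - sigma) / sigma, 0.05)
  expect_error(rms_difference(list(list(1:3, 1:4))), "mismatch")
})

test_that("regional delta table is exact post minus pre and flags gaps", {
  rm <- data.frame(region = 1:4, mean = c(1, 2, NA, 4), area = c(1, 1, 0, 1),
                   n_vertices = c(5L, 5L, 0L, 5L),
                   empty = c(FALSE, FALSE, TRUE, FALSE))
  tab <- regional_table(rm, rm, rm, rm)
  expect_equal(tab$delta_strain, c(0, 0, NA, 0))
  expect_true(tab$incomplete[3])
  expect_false(any(tab$incomplete[-3]))
  # identical pre/post yields an all-zero, fully significant-free delta set
  expect_true(all(tab$delta_t2[!tab$incomplete] == 0))
})
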