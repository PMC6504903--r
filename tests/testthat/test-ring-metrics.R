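# Radial profiles, diameter metrology, Monte Carlo errors and flux
# partitioning.

# 2D image whose central band profiles are exactly two Gaussians per axis
two_gauss_image <- function(n = 257, cx = 85, cy = 85, sigma = 25,
                            amp = 100, baseline = 5) {
  x <- 0:(n - 1) - (n - 1) / 2
  gx <- amp * (exp(-(x - cx)^2 / (2 * sigma^2)) + exp(-(x + cx)^2 / (2 * sigma^2)))
  gy <- amp * (exp(-(x - cy)^2 / (2 * sigma^2)) + exp(-(x + cy)^2 / (2 * sigma^2)))
  outer(rep(1, n), gx) + outer(gy, rep(1, n)) + baseline
}

test_that("radial profile of a uniform image is flat", {
  rp <- radial_profile(matrix(4.5, 81, 81))
  expect_true(all(abs(rp$intensity - 4.5) < 1e-9))
  expect_identical(rp$radius_px, 0:40)
  expect_true(all(diff(rp$radius_px) > 0))
})

test_that("radial profile locates a blurred annulus", {
  n <- 101; ctr <- 50
  ang <- seq(0, 2 * pi, length.out = 720)
  img <- matrix(0, n, n)
  img[cbind(round(ctr + 20 * sin(ang)) + 1, round(ctr + 20 * cos(ang)) + 1)] <- 1
  img <- matrix(torusalign:::gauss_blur(img, c(1, 1)), n, n)
  rp <- radial_profile(img)
  expect_lte(abs(rp$radius_px[which.max(rp$intensity)] - 20), 1)
})

test_that("radial profile argmax matches a simulated averaged toroid", {
  sim <- simulate_toroid_volume(scene_spec(diameter_nm = 170, theta_deg = 0,
                                           phi_deg = 0, photons = 2e6,
                                           poisson = FALSE, read_noise = 0))
  al <- flatten_transform(sim$volume, sim$truth$pose, out_dim = 151)
  rp <- radial_profile(average_particles(list(al)))
  expect_lte(abs(rp$radius_px[which.max(rp$intensity)] - 42.5), 1)
})

test_that("two-Gaussian fits recover an exact diameter", {
  img <- two_gauss_image()
  d <- diameter_from_average(img)
  expect_true(d$symmetric)
  expect_equal(d$diameter_nm, 170, tolerance = 1e-6)
  expect_equal(d$vertical_nm, 170, tolerance = 1e-6)
  expect_equal(d$horizontal_nm, 170, tolerance = 1e-6)
})

test_that("anisotropic maps report both components", {
  img <- two_gauss_image(cx = 83.5, cy = 97)
  d <- diameter_from_average(img)
  expect_false(d$symmetric)
  expect_true(is.na(d$diameter_nm))
  expect_equal(d$horizontal_nm, 167, tolerance = 0.5)
  expect_equal(d$vertical_nm, 194, tolerance = 0.5)
})

test_that("an unresolved profile raises the below-resolution error", {
  img <- two_gauss_image(cx = 20, cy = 20, sigma = 25)
  expect_error(diameter_from_average(img), "below resolution")
})

test_that("Monte Carlo errors behave: zero residuals, 1/sqrt(2) pooling, scaling", {
  d0 <- monte_carlo_error(diameter_from_average(two_gauss_image()),
                          n_reps = 50, seed = 1)
  expect_lt(d0$se_nm, 1e-6 * d0$diameter_nm)

  set.seed(3)
  noisy <- two_gauss_image() + matrix(rnorm(257^2, 0, 2), 257, 257)
  d1 <- monte_carlo_error(diameter_from_average(noisy), n_reps = 150, seed = 2)
  expect_gt(d1$se_nm, 0)
  pooled <- sqrt(d1$se_vertical_nm^2 + d1$se_horizontal_nm^2) / 2
  expect_equal(d1$se_nm, pooled, tolerance = 0.35)

  noisier <- two_gauss_image() + matrix(rnorm(257^2, 0, 4), 257, 257)
  d2 <- monte_carlo_error(diameter_from_average(noisier), n_reps = 150, seed = 2)
  expect_equal(d2$se_nm / d1$se_nm, 2, tolerance = 0.25)

  expect_warning(monte_carlo_error(diameter_from_average(noisy), n_reps = 10,
                                   seed = 1), "20")
})

test_that("fiducial normalization rescales diameters and errors", {
  img_s <- two_gauss_image(cx = 70, cy = 70)   # sample 140
  img_f <- two_gauss_image(cx = 90, cy = 90)   # fiducial 180
  ds <- diameter_from_average(img_s)
  df <- diameter_from_average(img_f)
  expect_equal(normalize_diameters(ds, df, 180)$diameter_nm, ds$diameter_nm,
               tolerance = 1e-6)
  expect_equal(normalize_diameters(ds, df, 170)$diameter_nm, 140 * 170 / 180,
               tolerance = 1e-3)
  expect_equal(normalize_diameters(df, df, 170)$diameter_nm, 170, tolerance = 1e-6)
  bad <- df; bad$diameter_nm <- 0
  expect_error(normalize_diameters(ds, bad, 170), "positive")
  # quadrature propagation of the two relative errors
  ds$se_nm <- 1.4; df$se_nm <- 1.8
  dn <- normalize_diameters(ds, df, 170)
  expect_equal(dn$se_nm,
               dn$diameter_nm * sqrt((1.4 / 140)^2 + (1.8 / 180)^2),
               tolerance = 1e-2)
})

test_that("diameter distributions compare by a two-tailed t-test", {
  set.seed(8)
  a <- rnorm(100, 170, 1); b <- rnorm(100, 135, 1)
  expect_gt(compare_diameters(a, a)$p.value, 0.99)
  expect_lt(compare_diameters(a, b)$p.value, 1e-10)
  t1 <- compare_diameters(a, b); t2 <- compare_diameters(b, a)
  expect_equal(unname(t1$statistic), -unname(t2$statistic), tolerance = 1e-12)
  expect_equal(t1$p.value, t2$p.value, tolerance = 1e-12)
  expect_error(compare_diameters(rep(1, 30), rep(2, 30)), "variance")
  expect_warning(compare_diameters(rnorm(5), rnorm(5)), "20")
})

test_that("flux partitioning is exact, disjoint and permutation-consistent", {
  n <- 101
  ring <- annulus_mask(c(n, n), r_inner = 15, r_outer = 25)
  bridge <- sector_mask(c(n, n), r_range = c(26, 45), angle_range_deg = c(-60, 60))
  img <- matrix(0, n, n); img[ring] <- 2
  expect_equal(unname(toroid_bridge_fraction(img, ring, bridge)), c(1, 0))

  img2 <- matrix(0, n, n); img2[ring] <- 1; img2[bridge] <- 1
  fr <- toroid_bridge_fraction(img2, ring, bridge)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr[1]), sum(ring) / (sum(ring) + sum(bridge)), tolerance = 1e-9)
  sw <- toroid_bridge_fraction(img2, bridge, ring)
  expect_equal(unname(sw[1]), unname(fr[2]), tolerance = 1e-12)

  expect_error(toroid_bridge_fraction(img2, ring, ring & bridge), "non-empty")
  expect_error(toroid_bridge_fraction(img2, ring, ring), "overlap")
})

test_that("background mode subtraction holds under an intensity offset", {
  simb <- simulate_toroid_volume(scene_preset("mps3-like", seed = 2))
  m <- truth_partition_masks(simb$truth, dim(simb$volume$data)[2:3])
  fr <- toroid_bridge_fraction(simb$volume, m$ring, m$bridge)
  expect_equal(unname(fr[1]), 0.45, tolerance = 0.05)
  expect_equal(sum(fr), 1)
})
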