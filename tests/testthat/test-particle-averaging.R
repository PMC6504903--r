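# Flattening, oriented/random rotation and averaging.

test_that("flattening with an identity pose reproduces the volume", {
  sim <- simulate_toroid_volume(small_scene(diameter_nm = 100, theta_deg = 0,
                                            phi_deg = 0, seed = 1,
                                            dim = c(61, 61, 61)))
  al <- flatten_transform(sim$volume, sim$truth$pose, out_dim = 61)
  expect_equal(al$volume$data, sim$volume$data,
               tolerance = 1e-6 * max(sim$volume$data))
  expect_equal(al$rotation_applied, 0)
})

test_that("flattening a tilted particle yields a flat centered ring", {
  sp <- small_scene(diameter_nm = 160, theta_deg = 25, phi_deg = 210, seed = 2)
  sim <- simulate_toroid_volume(sp)
  fit <- fit_particle(sim$volume, make_seeds(sim$truth, 2, 3))
  al <- flatten_transform(sim$volume, fit$pose, out_dim = 151)
  ctr <- 75
  s <- particle_seed("refit", "sim",
                     rbind(c(ctr + 40, ctr), c(ctr, ctr + 40),
                           c(ctr - 40, ctr), c(ctr, ctr - 40)), z_hint = ctr)
  refit <- fit_particle(al$volume, s)
  expect_lt(refit$pose$theta * 180 / pi, 2)
  expect_lt(max(abs(c(refit$pose$xc, refit$pose$yc, refit$pose$zc) - ctr)), 0.5)
})

test_that("flattening conserves integrated intensity within 1%", {
  set.seed(20)
  for (i in 1:6) {
    sp <- small_scene(diameter_nm = 120, theta_deg = runif(1, 0, 35),
                      phi_deg = runif(1, 0, 360), seed = 30 + i,
                      poisson = FALSE, read_noise = 0)
    sim <- simulate_toroid_volume(sp)
    al <- flatten_transform(sim$volume, sim$truth$pose, out_dim = 131)
    expect_equal(sum(al$volume$data) / sum(sim$volume$data), 1, tolerance = 0.01)
  }
})

test_that("a ring outside the resampling support is refused", {
  v <- volume_image(array(1, c(11, 41, 41)), c(2, 2, 2))
  expect_error(flatten_transform(v, ring_pose(20, 20, 5, r = 30)), "support")
})

test_that("orientation by a secondary reference points where asked", {
  a <- array(0, c(61, 61, 61))
  a[31, 31, 51] <- 100  # blob 20 px east of center
  al <- as_aligned(torusalign:::gauss_blur(a, c(2, 2, 2)))
  up <- orient_by_secondary(al, c(20, 0), "up")
  expect_equal(up$rotation_applied, pi / 2)
  proj <- apply(up$volume$data, c(2, 3), sum)
  pk <- which(proj == max(proj), arr.ind = TRUE)
  ang <- atan2(pk[1] - 31, pk[2] - 31) * 180 / pi
  expect_lt(abs(ang - 90), 5)

  same <- orient_by_secondary(al, c(0, 12), "up")
  expect_equal(same$rotation_applied, 0)
  expect_equal(same$volume$data, al$volume$data)
  expect_error(orient_by_secondary(al, c(0, 0), "up"), "undefined")
})

test_that("random rotation is seeded, uniform, and symmetry-preserving", {
  sim <- simulate_toroid_volume(small_scene(diameter_nm = 100, theta_deg = 0,
                                            phi_deg = 0, seed = 4,
                                            poisson = FALSE, read_noise = 0,
                                            dim = c(31, 81, 81)))
  al <- flatten_transform(sim$volume, sim$truth$pose, out_dim = 81)
  r1 <- randomize_rotation(al, 77)
  r2 <- randomize_rotation(al, 77)
  expect_identical(r1$volume$data, r2$volume$data)
  # a flat ring is radially symmetric: rotation changes only by the
  # bilinear interpolation error on PSF-width features
  expect_lt(max(abs(r1$volume$data - al$volume$data)),
            0.06 * max(al$volume$data))

  tiny <- as_aligned(array(1, c(9, 9, 9)))
  angles <- vapply(1:1000, function(s)
    randomize_rotation(tiny, s)$rotation_applied, 0)
  expect_gt(stats::ks.test(angles / (2 * pi), "punif")$p.value, 0.01)
})

test_that("averaging is exact on identical inputs and permutation-invariant", {
  sim <- simulate_toroid_volume(small_scene(seed = 5, diameter_nm = 90,
                                            theta_deg = 10))
  al <- flatten_transform(sim$volume, sim$truth$pose, out_dim = 41)
  avg5 <- average_particles(rep(list(al), 5))
  expect_equal(avg5$volume$data, al$volume$data, tolerance = 1e-12)
  expect_equal(avg5$n, 5)

  set.seed(6)
  parts <- lapply(1:4, function(i) {
    p <- al; p$volume$data <- p$volume$data + runif(1, 0, 2); p
  })
  a <- average_particles(parts, normalize_outliers = FALSE)
  b <- average_particles(rev(parts), normalize_outliers = FALSE)
  expect_equal(a$volume$data, b$volume$data, tolerance = 1e-12)
  # linearity without outlier normalization
  manual <- Reduce(`+`, lapply(parts, function(p) p$volume$data)) / 4
  expect_equal(a$volume$data, manual, tolerance = 1e-12)
})

test_that("a much brighter particle is renormalized before averaging", {
  base <- as_aligned(array(3, c(9, 9, 9)))
  bright <- base; bright$volume$data <- bright$volume$data * 10
  avg <- average_particles(list(base, bright), normalize_outliers = TRUE)
  expect_equal(avg$volume$data, base$volume$data, tolerance = 1e-6)
  expect_equal(sort(avg$provenance$scale), c(0.1, 1))
  raw <- average_particles(list(base, bright), normalize_outliers = FALSE)
  expect_equal(raw$volume$data, 5.5 * base$volume$data, tolerance = 1e-12)
})

test_that("averaging noise falls as 1/sqrt(n)", {
  clean <- array(10, c(9, 33, 33))
  sigma <- 2
  set.seed(7)
  parts <- lapply(1:50, function(i) {
    as_aligned(pmax(clean + array(rnorm(length(clean), 0, sigma), dim(clean)), 0))
  })
  avg <- average_particles(parts, normalize_outliers = FALSE)
  bg_sd <- sd(avg$volume$data)
  expect_equal(bg_sd, sigma / sqrt(50), tolerance = 0.2)
})

test_that("shape mismatches are refused", {
  a <- as_aligned(array(1, c(9, 9, 9)))
  b <- as_aligned(array(1, c(11, 11, 11)))
  expect_error(average_particles(list(a, b)), "shape")
})
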