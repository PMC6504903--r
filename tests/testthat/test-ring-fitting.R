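# Cross-section extraction, initialization and the global spot fit.

test_that("cross sections of a constant volume are constant", {
  v <- volume_image(array(7, c(10, 41, 41)), c(2, 2, 2))
  cs <- extract_cross_sections(v, c(20, 20, 5), half_length = 12)
  for (img in cs$images) expect_true(all(abs(img - 7) < 1e-12))
  expect_identical(vapply(cs$images, nrow, 0L), rep(10L, 4))
})

test_that("strips average across their 2-pixel width", {
  a <- array(0, c(6, 40, 40))
  a[, 21, ] <- 2   # plane y = 20 (0-based) bright, y = 21 dark
  v <- volume_image(a, c(2, 2, 2))
  cs <- extract_cross_sections(v, c(19.5, 20.5, 3), half_length = 10)
  # 0-degree strip samples y = 20 and y = 21: average of 2 and 0
  expect_true(all(abs(cs$images[[1]] - 1) < 1e-9))
})

test_that("extraction is linear in the source volume", {
  set.seed(2)
  a <- array(runif(8 * 31 * 31), c(8, 31, 31))
  b <- array(runif(8 * 31 * 31), c(8, 31, 31))
  va <- volume_image(a, c(2, 2, 2)); vb <- volume_image(b, c(2, 2, 2))
  vab <- volume_image(a + b, c(2, 2, 2))
  g <- c(15, 15, 4)
  csa <- extract_cross_sections(va, g, 9)
  csb <- extract_cross_sections(vb, g, 9)
  csab <- extract_cross_sections(vab, g, 9)
  for (k in 1:4)
    expect_equal(csab$images[[k]], csa$images[[k]] + csb$images[[k]],
                 tolerance = 1e-12)
})

test_that("a strip exiting the volume is refused with advice", {
  v <- volume_image(array(0, c(6, 21, 21)), c(2, 2, 2))
  expect_error(extract_cross_sections(v, c(10, 10, 3), half_length = 30), "crop")
  expect_error(extract_cross_sections(v, c(40, 10, 3), half_length = 2), "outside")
})

test_that("a flat toroid's 0-degree section shows spots 2r apart", {
  sp <- small_scene(diameter_nm = 160, theta_deg = 0, phi_deg = 0, seed = 6)
  sim <- simulate_toroid_volume(sp)
  g <- c(sim$truth$pose$xc, sim$truth$pose$yc, sim$truth$pose$zc)
  cs <- extract_cross_sections(sim$volume, g, half_length = 60)
  lat <- colSums(cs$images[[1]])
  pk_pos <- cs$t[cs$t > 10][which.max(lat[cs$t > 10])]
  pk_neg <- cs$t[cs$t < -10][which.max(lat[cs$t < -10])]
  expect_equal(pk_pos - pk_neg, 80, tolerance = 1 / 80)
})

test_that("pose initialization follows the seed geometry", {
  a <- array(0, c(20, 101, 101))
  zprof <- exp(-((0:19) - 9)^2 / 8)
  for (z in 1:20) a[z, , ] <- zprof[z]
  v <- volume_image(a, c(2, 2, 2))
  s <- particle_seed("p", "c", rbind(c(90, 50), c(50, 90), c(10, 50), c(50, 10)))
  init <- initialize_pose(s, v)
  expect_equal(init$r, 40)
  expect_equal(c(init$xc, init$yc), c(50, 50))
  expect_equal(init$zc, 9)
  expect_equal(init$theta, 0)

  s2 <- particle_seed("p", "c", rbind(c(90, 50), c(90, 50.5), c(90, 51), c(90.5, 50)))
  expect_error(initialize_pose(s2, v), "degenerate")
})

test_that("perturbed seeds stay within the documented radius window", {
  sim <- simulate_toroid_volume(small_scene(diameter_nm = 160, seed = 8))
  for (s in 1:5) {
    seeds <- make_seeds(sim$truth, jitter_px = 2, seed = s)
    init <- initialize_pose(seeds, sim$volume)
    expect_true(init$r >= 36 && init$r <= 44)
  }
})

test_that("the analytic Jacobian matches numeric differentiation", {
  sim <- simulate_toroid_volume(small_scene(seed = 3, theta_deg = 25))
  g <- c(sim$truth$pose$xc + 0.7, sim$truth$pose$yc - 0.4, sim$truth$pose$zc)
  cs <- extract_cross_sections(sim$volume, g, half_length = 40)
  pc <- torusalign:::.fit_plane_const()
  geom <- list(t = cs$t, zgrid = 0:(nrow(cs$images[[1]]) - 1), center_guess = g)
  par <- c(g[1] + 1.1, g[2] - 0.6, g[3] + 0.3, 26, 0.35, 2.1, 5.2,
           rep(40, 4), c(1.1, 0.95, 1, 1.05), rep(1.5, 4))
  phi <- 0.8
  J <- torusalign:::.ring_model(par, phi, geom, pc, jac = TRUE)$J
  num <- vapply(seq_along(par), function(i) {
    h <- max(1e-6, abs(par[i]) * 1e-7)
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    (torusalign:::.ring_model(pp, phi, geom, pc) -
       torusalign:::.ring_model(pm, phi, geom, pc)) / (2 * h)
  }, numeric(length(geom$t) * length(geom$zgrid) * 4))
  expect_lt(max(abs(J - num)) / max(abs(num)), 1e-6)
})

test_that("a noiseless tilted toroid is recovered to spec accuracy", {
  sp <- scene_spec(diameter_nm = 160, theta_deg = 20, phi_deg = 60,
                   photons = 2e6, poisson = FALSE, read_noise = 0)
  sim <- simulate_toroid_volume(sp)
  seeds <- make_seeds(sim$truth, jitter_px = 2, seed = 1)
  fit <- fit_particle(sim$volume, seeds)
  expect_lt(abs(fit$pose$r - 40), 0.5)
  expect_lt(abs(fit$pose$theta - 20 * pi / 180) * 180 / pi, 2)
  expect_lte(angdiff_deg(fit$pose$phi, 60 * pi / 180), 10)
  # grid optimality and linked constraints
  expect_lte(fit$cost, min(fit$phi_grid_profile) * (1 + 1e-9))
  expect_length(unique(fit$gaussians$sigma_lat), 1L)
  expect_length(unique(fit$gaussians$sigma_z), 1L)
  ratio <- tapply(fit$gaussians$amplitude, fit$gaussians$section_deg,
                  function(a) a[1] / a[2])
  expect_true(all(ratio >= 0.5 - 1e-6 & ratio <= 2 + 1e-6))
})

test_that("a flat ring fits with low tilt and an undetermined phi flag", {
  sp <- small_scene(diameter_nm = 160, theta_deg = 0, phi_deg = 0,
                    seed = 12, poisson = FALSE, read_noise = 0)
  sim <- simulate_toroid_volume(sp)
  seeds <- make_seeds(sim$truth, jitter_px = 1, seed = 2)
  fit <- fit_particle(sim$volume, seeds)
  expect_lte(fit$pose$theta * 180 / pi, 2)
  expect_true("phi_undetermined" %in% fit$constraint_flags)
})

test_that("an oversized radius guess activates the radius bound", {
  sim <- simulate_toroid_volume(small_scene(diameter_nm = 160, seed = 13,
                                            theta_deg = 10,
                                            dim = c(57, 221, 221)))
  ctr <- c(sim$truth$pose$xc, sim$truth$pose$yc)
  # clicks at 2.5x the true radius: the fit may shrink only to half the
  # 100 px guess and must report the active bound
  seeds <- particle_seed("big", "sim",
                         rbind(c(ctr[1] + 100, ctr[2]), c(ctr[1], ctr[2] + 100),
                               c(ctr[1] - 100, ctr[2]), c(ctr[1], ctr[2] - 100)),
                         z_hint = round(sim$truth$pose$zc))
  fit <- fit_particle(sim$volume, seeds)
  expect_true("radius" %in% fit$constraint_flags)
  # the radius ends pinned at a factor-of-two bound of the 100 px guess
  expect_true(min(abs(fit$pose$r - c(50, 200))) < 1e-3)
})

test_that("fitting is equivariant under integer translations", {
  sp <- small_scene(diameter_nm = 140, theta_deg = 18, phi_deg = 110,
                    seed = 14, poisson = FALSE, read_noise = 0)
  sim <- simulate_toroid_volume(sp)
  seeds <- make_seeds(sim$truth, jitter_px = 1, seed = 3)
  fit1 <- fit_particle(sim$volume, seeds)
  shifted <- sim$volume$data[, -(1:3), -(1:5)]
  v2 <- volume_image(shifted, sim$volume$voxel_size)
  seeds2 <- particle_seed("t", "sim", seeds$points - rep(c(5, 3), each = 4),
                          z_hint = seeds$z_hint)
  fit2 <- fit_particle(v2, seeds2)
  expect_equal(fit2$pose$xc, fit1$pose$xc - 5, tolerance = 0.1)
  expect_equal(fit2$pose$yc, fit1$pose$yc - 3, tolerance = 0.1)
  expect_equal(fit2$pose$r, fit1$pose$r, tolerance = 0.1)
  expect_equal(fit2$pose$theta, fit1$pose$theta, tolerance = 0.1 * pi / 180 * 10)
})

test_that("fit quality separates model-matched data from a wrong pose", {
  # sections synthesized from the spot model itself: the fit must reach
  # machine-level residuals and report exactly eight spots
  g <- c(40, 40, 12)
  pc <- torusalign:::.fit_plane_const()
  geom <- list(t = -34:34, zgrid = 0:24, center_guess = g)
  par_true <- c(g[1] + 1, g[2] - 1, g[3], 22, 0.3, 2, 5,
                c(60, 55, 50, 65), c(1.2, 0.9, 1, 1.1), c(2, 2.5, 1.8, 2.2))
  mu <- torusalign:::.ring_model(par_true, 40 * pi / 180, geom, pc)
  imgs <- lapply(1:4, function(k) {
    matrix(mu[((k - 1) * 25 * 69 + 1):(k * 25 * 69)], 25)
  })
  cs <- structure(list(images = imgs, t = geom$t, angles_deg = c(0, 45, 90, 135),
                       planes = c("yz", "45", "xz", "135"), center_guess = g,
                       voxel_size = c(2, 2, 2)),
                  class = "cross_section_set")
  init <- ring_pose(g[1], g[2], g[3], 22)
  attr(init, "init") <- list(center = g, r = 22)
  fit <- fit_ring(cs, init)
  q <- fit_quality(fit)
  expect_true(q$pass)
  expect_lt(q$residual_rms, 1e-6 * max(fit$gaussians$amplitude))
  expect_identical(q$n_spots, 8L)
  expect_length(q$model, 4L)

  # constrain the fit far from the true ring: residuals must fail the bar
  sim <- simulate_toroid_volume(small_scene(diameter_nm = 150, seed = 15,
                                            theta_deg = 0))
  ctr <- c(sim$truth$pose$xc, sim$truth$pose$yc)
  off <- particle_seed("off", "sim",
                       rbind(c(ctr[1] + 18, ctr[2] + 30), c(ctr[1] - 2, ctr[2] + 50),
                             c(ctr[1] - 22, ctr[2] + 30), c(ctr[1] - 2, ctr[2] + 10)),
                       z_hint = round(sim$truth$pose$zc))
  bad <- fit_particle(sim$volume, off)
  expect_false(fit_quality(bad)$pass)
})
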