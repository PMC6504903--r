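# Cross-section extraction, pose initialization and the constrained
# global fit of eight asymmetric 2D Gaussians over a gridded rotation
# angle.

# section angles (degrees) and the plane each section contains
.section_angles <- c(0, 45, 90, 135)
.section_planes <- c("yz", "45", "xz", "135")

#' Extract the four angled cross sections through a guess center
#'
#' For each section angle (0, 45, 90, 135 degrees) samples the volume by
#' bilinear interpolation along a strip through `center_guess`, averaging
#' across the strip's 2-pixel width (two parallel lines offset by +/-0.5
#' pixel perpendicular to the strip axis). Each section is a
#' `(z, lateral)` image spanning the source volume's full z extent.
#'
#' @param volume A [volume_image()].
#' @param center_guess `(x, y, z)` in 0-based pixels.
#' @param half_length Strip half-length in pixels; defaults to the
#'   largest value for which all strips stay inside the volume.
#' @return An object of class `"cross_section_set"`: `images` (list of
#'   four `nz x (2L+1)` matrices), `t` (lateral coordinates, pixels,
#'   relative to the guess center), `angles_deg`, `planes`,
#'   `center_guess`.
#' @export
extract_cross_sections <- function(volume, center_guess, half_length = NULL) {
  stopifnot(inherits(volume, "volume_image"), length(center_guess) == 3)
  d <- dim(volume$data)
  gx <- center_guess[1]; gy <- center_guess[2]
  if (gx < 0 || gx > d[3] - 1 || gy < 0 || gy > d[2] - 1 ||
      center_guess[3] < 0 || center_guess[3] > d[1] - 1)
    stop("center guess lies outside the volume")
  # max half-length keeping both +/-0.5-offset lines inside at all angles
  lims <- c(gx - 0.5, d[3] - 1 - gx - 0.5, gy - 0.5, d[2] - 1 - gy - 0.5)
  l_max <- floor(min(lims))
  if (is.null(half_length)) half_length <- l_max
  if (half_length > l_max)
    stop("cross-section strip exits the volume (half-length ", half_length,
         " > ", l_max, "); crop or pad the volume to at least 4x the guess radius")
  if (half_length < 1) stop("volume too small around the guess center")
  tv <- seq(-half_length, half_length)
  nz <- d[1]
  zi <- rep(0:(nz - 1), times = length(tv))
  ti <- rep(tv, each = nz)
  imgs <- vector("list", length(.section_angles))
  for (k in seq_along(.section_angles)) {
    a <- .section_angles[k] * pi / 180
    ux <- cos(a); uy <- sin(a)
    # perpendicular offsets +/- 0.5 px define the 2-px-wide strip
    m <- 0.5 * (interp3(volume$data, gx + ti * ux - 0.5 * uy,
                        gy + ti * uy + 0.5 * ux, zi) +
                  interp3(volume$data, gx + ti * ux + 0.5 * uy,
                          gy + ti * uy - 0.5 * ux, zi))
    imgs[[k]] <- matrix(m, nrow = nz)
  }
  structure(list(images = imgs, t = tv, angles_deg = .section_angles,
                 planes = .section_planes, center_guess = center_guess,
                 voxel_size = volume$voxel_size),
            class = "cross_section_set")
}

#' Initialize a ring pose from four seed points
#'
#' The radius starts at half the mean of the two opposite-point
#' distances, the lateral center at the centroid of the four points, the
#' z center at the intensity maximum of the averaged (peak-normalized,
#' lightly smoothed) z profiles through the four points, and the tilt at
#' zero. When the seed carries a `z_hint` the maximum is searched in a
#' window around the hinted slice.
#'
#' @param seed A [particle_seed()].
#' @param volume A [volume_image()].
#' @return A [ring_pose()] with attribute `"init"` recording the
#'   initialized values used later as fit-constraint anchors.
#' @export
initialize_pose <- function(seed, volume) {
  stopifnot(inherits(seed, "particle_seed"), inherits(volume, "volume_image"))
  check_seed_bounds(seed, volume)
  p <- seed$points
  d1 <- sqrt(sum((p[1, ] - p[3, ])^2))
  d2 <- sqrt(sum((p[2, ] - p[4, ])^2))
  if (min(d1, d2) < 2)
    stop("degenerate seed points (coincident crossings) for particle '",
         seed$particle_id, "'")
  # collinearity check via the quadrilateral area
  area <- 0.5 * abs(sum(p[, 1] * p[c(2:4, 1), 2] - p[c(2:4, 1), 1] * p[, 2]))
  if (area < 1) stop("degenerate seed points (collinear) for particle '",
                     seed$particle_id, "'")
  r0 <- mean(c(d1, d2)) / 2
  ctr <- unname(colMeans(p))
  nz <- dim(volume$data)[1]
  # peak-normalize each column profile before averaging: the 0/180 and
  # 90/270 pairs straddle the center symmetrically in z, and an
  # imprecise click must not let one crossing dominate the vote
  zprof <- rowMeans(vapply(seq_len(4), function(i) {
    pr <- interp3(volume$data, rep(p[i, 1], nz), rep(p[i, 2], nz), 0:(nz - 1))
    if (max(pr) > 0) pr / max(pr) else pr
  }, numeric(nz)))
  # light smoothing suppresses spurious maxima from imprecise clicks on
  # tilted rings, whose crossing spots straddle the center in z
  if (nz >= 5) {
    kern <- exp(-(-3:3)^2 / (2 * 2^2)); kern <- kern / sum(kern)
    zprof <- as.numeric(stats::filter(zprof, kern, sides = 2, circular = TRUE))
  }
  if (!is.na(seed$z_hint)) {
    win <- max(5L, round(nz / 10))
    zs <- max(1L, round(seed$z_hint) + 1L - win):min(nz, round(seed$z_hint) + 1L + win)
    zc0 <- zs[which.max(zprof[zs])] - 1
  } else {
    zc0 <- which.max(zprof) - 1
  }
  pose <- ring_pose(ctr[1], ctr[2], zc0, r0, theta = 0, phi = 0)
  attr(pose, "init") <- list(center = c(ctr[1], ctr[2], zc0), r = r0)
  pose
}

#' Control settings for the ring fit
#'
#' @param phi_step_deg Grid step for the rotation angle, degrees.
#' @param maxiter,ftol Levenberg-Marquardt termination settings.
#' @param sigma_lat_init,sigma_z_init Initial Gaussian sigmas, pixels.
#' @param sigma_lat_bounds,sigma_z_bounds Allowed sigma ranges, pixels.
#' @param phi_flat_tol Relative cost spread across the phi grid below
#'   which the rotation angle is flagged undetermined.
#' @return Named list of settings.
#' @export
fit_control <- function(phi_step_deg = 10, maxiter = 500, ftol = 1e-10,
                        sigma_lat_init = 2, sigma_z_init = 5,
                        sigma_lat_bounds = c(0.4, 25),
                        sigma_z_bounds = c(0.4, 60),
                        phi_flat_tol = 0.01) {
  list(phi_step_deg = phi_step_deg, maxiter = maxiter, ftol = ftol,
       sigma_lat_init = sigma_lat_init, sigma_z_init = sigma_z_init,
       sigma_lat_bounds = sigma_lat_bounds, sigma_z_bounds = sigma_z_bounds,
       phi_flat_tol = phi_flat_tol)
}

# per-plane constants used by the inner model: unit normal n and lateral
# unit vector u of the section containing each plane
.fit_plane_const <- function() {
  lapply(.section_planes, function(p) .plane_defs[[p]])
}

# crossing angles and spot centers for all four sections, plus the
# derivative factors for the analytic Jacobian.
#
# param order: 1 xc, 2 yc, 3 zc, 4 r, 5 theta
.spot_centers <- function(par, phi, guess, pc, derivs = FALSE) {
  xc <- par[1]; yc <- par[2]; zc <- par[3]; r <- par[4]; th <- par[5]
  ct <- cos(th); st <- sin(th); cp <- cos(phi); sp <- sin(phi)
  out <- vector("list", 4L)
  for (k in 1:4) {
    n <- pc[[k]]$n; u <- pc[[k]]$u
    alpha <- -n[1] * sp + n[2] * cp
    beta <- n[1] * cp + n[2] * sp
    A <- r * alpha; B <- r * ct * beta
    C <- n[1] * (xc - guess[1]) + n[2] * (yc - guess[2])
    R0 <- sqrt(A^2 + B^2)
    sarg <- max(-1, min(1, -C / R0))
    delta <- atan2(A, B)
    s0 <- asin(sarg)
    rho <- c(s0 - delta, pi - s0 - delta)
    cr <- cos(rho); sr <- sin(rho)
    au <- u[1] * sp - u[2] * cp
    bu <- u[1] * cp + u[2] * sp
    toff <- u[1] * (xc - guess[1]) + u[2] * (yc - guess[2])
    tt <- toff + r * (-au * cr + ct * bu * sr)
    zz <- zc - r * st * sr
    spot <- list(rho = rho, t = tt, z = zz)
    if (derivs) {
      Frho <- -A * sr + B * cr
      Frho <- sign(Frho) * pmax(abs(Frho), 1e-6 * R0)
      # dF/dp at the solutions (F = A cos + B sin + C)
      dF <- rbind(xc = rep(n[1], 2), yc = rep(n[2], 2), zc = c(0, 0),
                  r = -rep(C, 2) / r, theta = -B * tan(th) * sr)
      drho <- -sweep(dF, 2, Frho, "/")
      dt_drho <- r * (au * sr + ct * bu * cr)
      dz_drho <- -r * st * cr
      dt_ex <- rbind(xc = rep(u[1], 2), yc = rep(u[2], 2), zc = c(0, 0),
                     r = (tt - toff) / r, theta = -r * st * bu * sr)
      dz_ex <- rbind(xc = c(0, 0), yc = c(0, 0), zc = c(1, 1),
                     r = -st * sr, theta = -r * ct * sr)
      spot$dt <- dt_ex + sweep(drho, 2, dt_drho, "*")
      spot$dz <- dz_ex + sweep(drho, 2, dz_drho, "*")
    }
    out[[k]] <- spot
  }
  out
}

# Full model evaluation over the four section grids.
#
# geom carries t (lateral coords), zgrid (absolute z coords of the rows
# used) and center_guess.
#
# par layout (19): xc, yc, zc, r, theta, sig_l, sig_z,
#                  m1..m4 (pair-mean amplitudes), s1..s4 (sqrt ratio),
#                  b1..b4 (baselines)
.ring_model <- function(par, phi, geom, pc, jac = FALSE) {
  sl <- par[6]; sz <- par[7]
  m <- par[8:11]; s <- par[12:15]; b <- par[16:19]
  spots <- .spot_centers(par[1:5], phi, geom$center_guess, pc, derivs = jac)
  tv <- geom$t
  zgrid <- geom$zgrid
  nz <- length(zgrid); nt <- length(tv)
  npx <- nz * nt
  mu <- numeric(4L * npx)
  J <- if (jac) matrix(0, 4L * npx, 19L) else NULL
  for (k in 1:4) {
    rows <- ((k - 1L) * npx + 1L):(k * npx)
    Mk <- matrix(b[k], nz, nt)
    jb <- if (jac) matrix(0, npx, 19L) else NULL
    for (j in 1:2) {
      amp <- if (j == 1) m[k] * s[k] else m[k] / s[k]
      t0 <- spots[[k]]$t[j]; z0 <- spots[[k]]$z[j]
      dt_v <- tv - t0; dz_v <- zgrid - z0
      gt <- exp(-dt_v^2 / (2 * sl^2))
      gz <- exp(-dz_v^2 / (2 * sz^2))
      G <- outer(gz, gt)
      Mk <- Mk + amp * G
      if (jac) {
        vG <- as.vector(G)
        vDt <- amp * as.vector(outer(gz, gt * dt_v)) / sl^2
        vDz <- amp * as.vector(outer(gz * dz_v, gt)) / sz^2
        jb[, 1:5] <- jb[, 1:5] +
          vDt %o% spots[[k]]$dt[, j] + vDz %o% spots[[k]]$dz[, j]
        jb[, 6] <- jb[, 6] + amp * as.vector(outer(gz, gt * dt_v^2)) / sl^3
        jb[, 7] <- jb[, 7] + amp * as.vector(outer(gz * dz_v^2, gt)) / sz^3
        jb[, 7 + k] <- jb[, 7 + k] + vG * (if (j == 1) s[k] else 1 / s[k])
        jb[, 11 + k] <- jb[, 11 + k] + vG * (if (j == 1) m[k] else -m[k] / s[k]^2)
      }
    }
    mu[rows] <- Mk
    if (jac) {
      jb[, 15 + k] <- 1
      J[rows, ] <- jb
    }
  }
  if (jac) list(mu = mu, J = J) else mu
}

#' Global constrained fit of the tilted-ring model to cross sections
#'
#' For each rotation angle `phi` on a 10-degree grid, runs a bounded
#' Levenberg-Marquardt least-squares fit of eight asymmetric 2D Gaussians
#' whose centers are pinned to the plane-crossing predictions of the
#' current pose. The Gaussian sigmas are linked across all eight spots,
#' the amplitude pair of each section is constrained within a factor of
#' two, the lateral center within 20% of the guess radius from its
#' initialization, the radius within a factor of two of its
#' initialization, the z center within one slice, and the tilt below 45
#' degrees. The grid angle with minimal cost wins. Each grid angle's
#' start point uses a tilt pre-estimate read from the antisymmetric z
#' offsets of the spot pairs across the four sections, which makes the
#' per-angle fits well-conditioned even though the tilt is initialized
#' at zero in the reported initialization.
#'
#' @param cs A [extract_cross_sections()] result.
#' @param init A [ring_pose()] from [initialize_pose()].
#' @param control A [fit_control()] list.
#' @return An object of class `"ring_fit"`: `pose`, `gaussians` (data
#'   frame of the 8 fitted spots), `residual_rms`, `phi_grid_profile`
#'   (named cost vector over the full 0..350 grid), `constraint_flags`,
#'   `cost`, `quality_images` (observed and model section images),
#'   `init`, `converged`.
#' @export
fit_ring <- function(cs, init, control = fit_control()) {
  stopifnot(inherits(cs, "cross_section_set"), inherits(init, "ring_pose"))
  anchors <- attr(init, "init") %||%
    list(center = c(init$xc, init$yc, init$zc), r = init$r)
  r0 <- anchors$r; c0 <- anchors$center
  pc <- .fit_plane_const()
  nz <- nrow(cs$images[[1]])
  # fit on a z-lattice matched to the axial PSF (step ~ sigma_z/2, four
  # samples per sigma-width); the final model/quality images use the
  # full grid
  zstep <- max(1L, floor(control$sigma_z_init / 2))
  zidx <- seq(1L, nz, by = zstep)
  geom <- list(t = cs$t, zgrid = zidx - 1, center_guess = cs$center_guess)
  geom_full <- list(t = cs$t, zgrid = 0:(nz - 1), center_guess = cs$center_guess)
  dat <- unlist(lapply(cs$images, function(M) as.vector(M[zidx, , drop = FALSE])),
                use.names = FALSE)
  dat_full <- unlist(lapply(cs$images, as.vector), use.names = FALSE)

  lower <- c(c0[1] - 0.2 * r0, c0[2] - 0.2 * r0, c0[3] - 1, r0 / 2, 0,
             control$sigma_lat_bounds[1], control$sigma_z_bounds[1],
             rep(0, 4), rep(1 / sqrt(2), 4), rep(-Inf, 4))
  upper <- c(c0[1] + 0.2 * r0, c0[2] + 0.2 * r0, c0[3] + 1, 2 * r0,
             45 * pi / 180 - 1e-9,
             control$sigma_lat_bounds[2], control$sigma_z_bounds[2],
             rep(Inf, 4), rep(sqrt(2), 4), rep(Inf, 4))

  base0 <- vapply(cs$images, stats::median, 0)
  amp0 <- pmax(vapply(cs$images, max, 0) - base0, 1e-6 + 0.01 * max(dat))
  par0 <- c(c0[1], c0[2], c0[3], init$r, min(max(init$theta, 0.02), 0.7),
            control$sigma_lat_init, control$sigma_z_init,
            amp0, rep(1, 4), base0)
  par0 <- pmin(pmax(par0, lower), upper)

  phis <- seq(0, 350, by = control$phi_step_deg) * pi / 180

  # tilt/phase pre-estimate: for a tilted circle the two spots of each
  # section sit at z offsets -tan(theta) * t * cos(alpha - phi), i.e. an
  # antisymmetric pair whose half-difference traces a cosine in the
  # section angle. Peak positions are read directly off the sections.
  alpha <- .section_angles * pi / 180
  dz_k <- tbar_k <- rep(NA_real_, 4)
  zc_spots <- numeric(0)
  for (k in 1:4) {
    M <- cs$images[[k]]
    ptv <- apply(M, 2, max)
    win_p <- which(cs$t >= 0.45 * r0 & cs$t <= 1.8 * r0)
    win_m <- which(cs$t <= -0.45 * r0 & cs$t >= -1.8 * r0)
    if (!length(win_p) || !length(win_m)) next
    tp <- cs$t[win_p[which.max(ptv[win_p])]]
    tm <- cs$t[win_m[which.max(ptv[win_m])]]
    zof <- function(tc) {
      cols <- which(abs(cs$t - tc) <= 2)
      which.max(rowMeans(M[, cols, drop = FALSE])) - 1
    }
    zp <- zof(tp); zm <- zof(tm)
    dz_k[k] <- (zp - zm) / 2
    tbar_k[k] <- (abs(tp) + abs(tm)) / 2
    zc_spots <- c(zc_spots, zp, zm)
  }
  theta_start <- function(phi) {
    ok <- is.finite(dz_k)
    if (!any(ok)) return(0.05)
    xk <- -tbar_k[ok] * cos(alpha[ok] - phi)
    beta <- sum(xk * dz_k[ok]) / max(sum(xk^2), 1e-9)
    atan(min(max(beta, 0.02), 0.95))
  }
  zc_start <- if (length(zc_spots))
    min(max(mean(zc_spots), lower[3]), upper[3]) else par0[3]

  # stage-1 ranking lattice: additionally decimated laterally
  tidx <- seq(1L, length(cs$t), by = 2L)
  geom_s1 <- list(t = cs$t[tidx], zgrid = zidx - 1, center_guess = cs$center_guess)
  dat_s1 <- unlist(lapply(cs$images,
                          function(M) as.vector(M[zidx, tidx, drop = FALSE])),
                   use.names = FALSE)
  run_lm <- function(phi, par_start, maxit, g, d) {
    minpack.lm::nls.lm(
      par = par_start, lower = lower, upper = upper,
      fn = function(p) .ring_model(p, phi, g, pc) - d,
      jac = function(p) .ring_model(p, phi, g, pc, jac = TRUE)$J,
      control = minpack.lm::nls.lm.control(maxiter = maxit,
                                           ftol = control$ftol, ptol = 1e-10))
  }
  # short bounded pass at every grid angle, then full refinement of the
  # leading candidates (phi is fixed within each pass)
  stage1 <- suppressWarnings(lapply(phis, function(phi) {
    st <- par0; st[3] <- zc_start; st[5] <- theta_start(phi)
    run_lm(phi, st, 10L, geom_s1, dat_s1)
  }))
  fits <- stage1
  refined <- utils::head(order(vapply(stage1, function(f) f$deviance, 0)), 3L)
  for (i in refined) {
    fits[[i]] <- suppressWarnings(
      run_lm(phis[i], stage1[[i]]$par, control$maxiter, geom, dat))
  }
  # cost profile on one consistent lattice for every grid angle
  costs <- vapply(seq_along(fits), function(i) {
    if (i %in% refined) fits[[i]]$deviance
    else sum((.ring_model(fits[[i]]$par, phis[i], geom, pc) - dat)^2)
  }, 0)
  ibest <- which.min(costs)
  if (!(ibest %in% refined)) {
    fits[[ibest]] <- suppressWarnings(
      run_lm(phis[ibest], stage1[[ibest]]$par, control$maxiter, geom, dat))
    costs[ibest] <- fits[[ibest]]$deviance
    ibest <- which.min(costs)
  }
  best <- fits[[ibest]]
  best$phi <- phis[ibest]
  if (!is.finite(best$deviance))
    stop("no rotation angle yielded a converged fit; per-phi costs: ",
         paste(sprintf("%.3g", costs), collapse = ", "))

  p <- best$par
  pose <- ring_pose(p[1], p[2], p[3], p[4], p[5], best$phi)
  attr(pose, "init") <- anchors

  tol <- 1e-6
  flag_names <- c("center_x", "center_y", "center_z", "radius", "theta",
                  "sigma_lat", "sigma_z", paste0("amp", 1:4),
                  paste0("ratio", 1:4), paste0("baseline", 1:4))
  at_bound <- (is.finite(lower) & abs(p - lower) < tol * pmax(abs(lower), 1)) |
    (is.finite(upper) & abs(p - upper) < tol * pmax(abs(upper), 1))
  at_bound[5] <- p[5] > upper[5] - 1e-4  # theta lower bound 0 is a valid optimum
  flags <- flag_names[at_bound]
  # phi carries no information for an essentially flat ring: flag when
  # the grid costs are near-constant or the fitted tilt is negligible
  spread <- (max(costs) - min(costs)) / max(max(costs), 1e-12)
  if (spread < control$phi_flat_tol || p[5] < 3 * pi / 180)
    flags <- c(flags, "phi_undetermined")

  spots <- .spot_centers(p[1:5], best$phi, cs$center_guess, pc)
  gaussians <- do.call(rbind, lapply(1:4, function(k) {
    data.frame(section_deg = .section_angles[k], plane = .section_planes[k],
               side = 1:2, rho = spots[[k]]$rho,
               t = spots[[k]]$t, z = spots[[k]]$z,
               sigma_lat = p[6], sigma_z = p[7],
               amplitude = c(p[7 + k] * p[11 + k], p[7 + k] / p[11 + k]),
               baseline = p[15 + k])
  }))
  model <- .ring_model(p, best$phi, geom_full, pc)
  npx <- nz * length(cs$t)
  model_imgs <- lapply(1:4, function(k) {
    matrix(model[((k - 1) * npx + 1):(k * npx)], nz)
  })
  rms_full <- sqrt(sum((model - dat_full)^2) / length(dat_full))

  prof <- stats::setNames(costs, round(phis * 180 / pi))

  structure(list(pose = pose, gaussians = gaussians,
                 residual_rms = rms_full,
                 cost = best$deviance, phi_grid_profile = prof,
                 constraint_flags = flags,
                 quality_images = list(observed = cs$images, model = model_imgs),
                 init = anchors, converged = best$info %in% 1:4,
                 niter = best$niter),
            class = "ring_fit")
}

#' @export
print.ring_fit <- function(x, ...) {
  print(x$pose)
  cat(sprintf("  residual RMS %.4g over %d-angle phi grid; flags: %s\n",
              x$residual_rms, length(x$phi_grid_profile),
              if (length(x$constraint_flags)) paste(x$constraint_flags, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Machine-readable fit quality report
#'
#' Compares the observed cross sections with the model-simulated ones —
#' a machine surrogate for inspecting fitted versus simulated
#' cross-sectional images. The pass criterion is the fraction of the
#' observed section variance left unexplained by the model (FVU): a
#' model-matched fit leaves only noise, while a misplaced ring leaves
#' most of the spot structure in the residual.
#'
#' @param result A [fit_ring()] result.
#' @param threshold Maximum fraction of unexplained variance for a pass.
#' @return List with `pass`, `fvu`, `residual_rms`, `threshold`,
#'   `n_spots`, and the side-by-side `observed` / `model` images.
#' @export
fit_quality <- function(result, threshold = 0.5) {
  stopifnot(inherits(result, "ring_fit"))
  obs <- unlist(lapply(result$quality_images$observed, as.vector))
  mod <- unlist(lapply(result$quality_images$model, as.vector))
  fvu <- sum((obs - mod)^2) / max(sum((obs - mean(obs))^2), 1e-300)
  list(pass = fvu < threshold, fvu = fvu,
       residual_rms = result$residual_rms,
       threshold = threshold, n_spots = nrow(result$gaussians),
       observed = result$quality_images$observed,
       model = result$quality_images$model)
}

#' Fit a ring to a volume from seed annotations
#'
#' Convenience pipeline: [initialize_pose()], [extract_cross_sections()]
#' with a strip half-length of 2.2 times the initialized radius (clipped
#' to the volume), then [fit_ring()].
#'
#' @param volume A [volume_image()].
#' @param seed A [particle_seed()].
#' @param control A [fit_control()] list.
#' @return A [fit_ring()] result.
#' @export
fit_particle <- function(volume, seed, control = fit_control()) {
  init <- initialize_pose(seed, volume)
  g <- attr(init, "init")$center
  d <- dim(volume$data)
  lmax <- floor(min(g[1] - 0.5, d[3] - 1 - g[1] - 0.5,
                    g[2] - 0.5, d[2] - 1 - g[2] - 0.5))
  cs <- extract_cross_sections(volume, g,
                               half_length = min(ceiling(1.9 * init$r), lmax))
  fit_ring(cs, init, control)
}
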