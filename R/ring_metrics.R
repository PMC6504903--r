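# Radial profiles, two-Gaussian diameter metrology with Monte Carlo
# errors, fiducial normalization, significance testing and toroid/bridge
# flux partitioning.

# reduce an average_map / volume_image / matrix to a 2D (y, x) image
.as_image2d <- function(x, z = "max") {
  if (inherits(x, "average_map")) x <- x$volume
  if (inherits(x, "volume_image")) {
    vol <- x$data
    if (identical(z, "max")) return(apply(vol, c(2, 3), max))
    if (identical(z, "sum")) return(apply(vol, c(2, 3), sum))
    stopifnot(is.numeric(z), z >= 0, z <= dim(vol)[1] - 1)
    return(vol[z + 1, , ])
  }
  stopifnot(is.matrix(x))
  x
}

.voxel_of <- function(x) {
  if (inherits(x, "average_map")) x$volume$voxel_size
  else if (inherits(x, "volume_image")) x$voxel_size
  else c(1, 1, 1)
}

#' Radial intensity profile of an averaged ring image
#'
#' Averages bilinearly interpolated pixel values around ever-expanding
#' circles from the center, sampling each circle at approximately
#' 1-pixel arc lengths.
#'
#' @param avg An [average_particles()] result, a [volume_image()] or a
#'   matrix.
#' @param center `(x, y)` center in pixels; defaults to the image center.
#' @param z `"max"` (maximum projection), `"sum"`, or a 0-based slice
#'   index, for volumetric input.
#' @param max_radius Largest radius in pixels; defaults to the distance
#'   to the nearest image edge.
#' @return A data frame of class `"radial_profile"` with columns
#'   `radius_px`, `radius_nm`, `intensity`, `n_samples`.
#' @export
radial_profile <- function(avg, center = NULL, z = "max", max_radius = NULL) {
  img <- .as_image2d(avg, z)
  vx <- .voxel_of(avg)[3]
  ny <- nrow(img); nx <- ncol(img)
  if (is.null(center)) center <- c((nx - 1) / 2, (ny - 1) / 2)
  if (center[1] < 0 || center[1] > nx - 1 || center[2] < 0 || center[2] > ny - 1)
    stop("profile center lies outside the image")
  if (is.null(max_radius))
    max_radius <- floor(min(center[1], nx - 1 - center[1],
                            center[2], ny - 1 - center[2]))
  radii <- 0:max_radius
  vals <- numeric(length(radii)); cnt <- integer(length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    n <- if (r == 0) 1L else max(8L, round(2 * pi * r))
    ang <- (seq_len(n) - 1) / n * 2 * pi
    v <- interp2(img, center[1] + r * cos(ang), center[2] + r * sin(ang))
    vals[i] <- mean(v); cnt[i] <- n
  }
  structure(data.frame(radius_px = radii, radius_nm = radii * vx,
                       intensity = vals, n_samples = cnt),
            class = c("radial_profile", "data.frame"))
}

# Two-Gaussian fit of a 1D intensity profile: independent centers and
# amplitudes, one shared width, constant baseline.
.two_gauss_model <- function(p, x) {
  p[5] + p[3] * exp(-(x - p[1])^2 / (2 * p[6]^2)) +
    p[4] * exp(-(x - p[2])^2 / (2 * p[6]^2))
}

.fit_two_gauss <- function(x, y, init = NULL) {
  if (is.null(init)) {
    mid <- (min(x) + max(x)) / 2
    li <- which(x < mid); ri <- which(x >= mid)
    b0 <- min(y)
    c1 <- x[li][which.max(y[li])]
    c2 <- x[ri][which.max(y[ri])]
    a1 <- max(y[li]) - b0; a2 <- max(y[ri]) - b0
    s0 <- max((max(x) - min(x)) / 12, 1)
    init <- c(c1, c2, a1, a2, b0, s0)
  }
  lower <- c(min(x), min(x), 0, 0, -Inf, 0.3)
  upper <- c(max(x), max(x), Inf, Inf, Inf, (max(x) - min(x)))
  fit <- minpack.lm::nls.lm(
    par = pmin(pmax(init, lower), upper), lower = lower, upper = upper,
    fn = function(p) .two_gauss_model(p, x) - y,
    control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12))
  p <- fit$par
  sep <- abs(p[2] - p[1])
  if (sep <= 2 * p[6] || min(p[3], p[4]) <= 0)
    stop("diameter below resolution: profile has no resolvable peak pair")
  list(par = p, separation = sep, fitted = .two_gauss_model(p, x),
       residuals = .two_gauss_model(p, x) - y, x = x, y = y,
       deviance = fit$deviance)
}

# band profile through the center: `axis` = "x" gives intensity vs x
# averaged over `band` rows around the center y (and vice versa)
.band_profile <- function(img, center, axis = c("x", "y"), band = 3L) {
  axis <- match.arg(axis)
  hw <- (band - 1) / 2
  if (axis == "x") {
    xs <- 0:(ncol(img) - 1)
    off <- seq(-hw, hw, by = 1)
    v <- rowMeans(vapply(off, function(o)
      interp2(img, xs, rep(center[2] + o, length(xs))), numeric(length(xs))))
    list(coord = xs - center[1], value = v)
  } else {
    ys <- 0:(nrow(img) - 1)
    off <- seq(-hw, hw, by = 1)
    v <- rowMeans(vapply(off, function(o)
      interp2(img, rep(center[1] + o, length(ys)), ys), numeric(length(ys))))
    list(coord = ys - center[2], value = v)
  }
}

#' Ring diameter from an averaged map by two-Gaussian profile fits
#'
#' Extracts 3-pixel-wide intensity profiles through the vertical and
#' horizontal centers of the averaged ring image and fits each to two
#' Gaussians (independent centers and amplitudes, shared width, constant
#' baseline). Each component diameter is the distance between the fitted
#' centers. When the two components agree within `asym_tol` the average
#' of vertical and horizontal values is reported; otherwise the map is
#' flagged asymmetric and both components are reported separately.
#'
#' @param avg An [average_particles()] result (or [volume_image()]/matrix).
#' @param center `(x, y)` pixels; defaults to the image center.
#' @param z Projection rule passed to the 2D reduction.
#' @param band_width Averaged band width for the profiles, pixels.
#' @param asym_tol Relative vertical/horizontal disagreement above which
#'   the result is reported as asymmetric.
#' @return An object of class `"diameter_estimate"`: `diameter_nm`
#'   (`NA` when asymmetric), `vertical_nm`, `horizontal_nm`, `symmetric`,
#'   `se_nm` (`NA` until [monte_carlo_error()]), the two profile fits,
#'   and `voxel_nm`.
#' @export
diameter_from_average <- function(avg, center = NULL, z = "max",
                                  band_width = 3L, asym_tol = 0.05) {
  img <- .as_image2d(avg, z)
  vx <- .voxel_of(avg)[3]
  if (is.null(center)) center <- c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2)
  ph <- .band_profile(img, center, "x", band_width)
  pv <- .band_profile(img, center, "y", band_width)
  fh <- .fit_two_gauss(ph$coord, ph$value)
  fv <- .fit_two_gauss(pv$coord, pv$value)
  dh <- fh$separation * vx
  dv <- fv$separation * vx
  symmetric <- abs(dv - dh) / mean(c(dv, dh)) <= asym_tol
  structure(list(diameter_nm = if (symmetric) mean(c(dv, dh)) else NA_real_,
                 vertical_nm = dv, horizontal_nm = dh,
                 symmetric = symmetric, se_nm = NA_real_,
                 se_vertical_nm = NA_real_, se_horizontal_nm = NA_real_,
                 mc_distribution = NULL,
                 fits = list(horizontal = fh, vertical = fv),
                 voxel_nm = vx, asym_tol = asym_tol),
            class = "diameter_estimate")
}

#' @export
print.diameter_estimate <- function(x, ...) {
  if (x$symmetric) {
    cat(sprintf("diameter %.1f nm%s (symmetric; vertical %.1f, horizontal %.1f)\n",
                x$diameter_nm,
                if (is.na(x$se_nm)) "" else sprintf(" +/- %.2g nm (MC SD)", x$se_nm),
                x$vertical_nm, x$horizontal_nm))
  } else {
    cat(sprintf("asymmetric toroid: vertical %.1f%s nm, horizontal %.1f%s nm\n",
                x$vertical_nm,
                if (is.na(x$se_vertical_nm)) "" else sprintf(" +/- %.1f", x$se_vertical_nm),
                x$horizontal_nm,
                if (is.na(x$se_horizontal_nm)) "" else sprintf(" +/- %.1f", x$se_horizontal_nm)))
  }
  invisible(x)
}

#' Monte Carlo error of a ring diameter
#'
#' Residual-calibrated parametric bootstrap: replicate profiles are
#' synthesized as the fitted two-Gaussian model plus Gaussian noise at
#' the residual SD of the original fit, refit, and the SD of the
#' resulting diameter distribution is reported as the error (labelled as
#' an SD of the Monte Carlo distribution).
#'
#' @param est A [diameter_from_average()] result.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return `est` with `mc_distribution` (nm; combined for symmetric maps,
#'   columns `vertical`/`horizontal` otherwise), `se_nm`,
#'   `se_vertical_nm`, `se_horizontal_nm` filled in.
#' @export
monte_carlo_error <- function(est, n_reps = 200L, seed = 1L) {
  stopifnot(inherits(est, "diameter_estimate"))
  if (n_reps < 20L) warning("fewer than 20 Monte Carlo replicates; error estimate unstable")
  draw <- function(fit) {
    sd_r <- stats::sd(fit$residuals)
    y_star <- fit$fitted + stats::rnorm(length(fit$fitted), 0, sd_r)
    out <- tryCatch(.fit_two_gauss(fit$x, y_star, init = fit$par),
                    error = function(e) NULL)
    if (is.null(out)) NA_real_ else out$separation
  }
  mc <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i)
      c(v = draw(est$fits$vertical), h = draw(est$fits$horizontal)),
      numeric(2))
  })
  vmc <- mc[1, ] * est$voxel_nm
  hmc <- mc[2, ] * est$voxel_nm
  ok <- is.finite(vmc) & is.finite(hmc)
  vmc <- vmc[ok]; hmc <- hmc[ok]
  est$se_vertical_nm <- stats::sd(vmc)
  est$se_horizontal_nm <- stats::sd(hmc)
  if (est$symmetric) {
    est$mc_distribution <- (vmc + hmc) / 2
    est$se_nm <- stats::sd(est$mc_distribution)
  } else {
    est$mc_distribution <- cbind(vertical = vmc, horizontal = hmc)
    est$se_nm <- NA_real_
  }
  est
}

#' Normalize a diameter against a fiducial reference
#'
#' Rescales a sample diameter by `fiducial_reference / fiducial_d`,
#' compensating batch-to-batch variation of the fiducial channel; errors
#' are propagated in quadrature from the two relative errors.
#'
#' @param sample_d,fiducial_d [diameter_from_average()] results (after
#'   [monte_carlo_error()] if propagated errors are wanted); `fiducial_d`
#'   must be symmetric.
#' @param fiducial_reference Reference diameter of the fiducial, nm.
#' @return A rescaled `diameter_estimate`.
#' @export
normalize_diameters <- function(sample_d, fiducial_d, fiducial_reference) {
  stopifnot(inherits(sample_d, "diameter_estimate"),
            inherits(fiducial_d, "diameter_estimate"))
  fd <- fiducial_d$diameter_nm
  if (!isTRUE(fd > 0)) stop("fiducial diameter must be positive")
  k <- fiducial_reference / fd
  rel_f <- if (is.na(fiducial_d$se_nm)) 0 else fiducial_d$se_nm / fd
  scale_err <- function(val, se) {
    if (is.na(val)) return(c(NA_real_, NA_real_))
    rel_s <- if (is.na(se)) 0 else se / val
    new <- val * k
    c(new, if (is.na(se) && rel_f == 0) NA_real_ else new * sqrt(rel_s^2 + rel_f^2))
  }
  d <- scale_err(sample_d$diameter_nm, sample_d$se_nm)
  v <- scale_err(sample_d$vertical_nm, sample_d$se_vertical_nm)
  h <- scale_err(sample_d$horizontal_nm, sample_d$se_horizontal_nm)
  out <- sample_d
  out$diameter_nm <- d[1]; out$se_nm <- d[2]
  out$vertical_nm <- v[1]; out$se_vertical_nm <- v[2]
  out$horizontal_nm <- h[1]; out$se_horizontal_nm <- h[2]
  if (!is.null(out$mc_distribution)) out$mc_distribution <- out$mc_distribution * k
  out
}

#' Compare two Monte Carlo diameter distributions
#'
#' Two-sample two-tailed t-test (Welch) on the Monte Carlo-derived
#' diameter distributions.
#'
#' @param a,b Numeric vectors of diameter draws, or `diameter_estimate`s
#'   carrying `mc_distribution`.
#' @return A `htest` object (`statistic`, `p.value`, ...).
#' @export
compare_diameters <- function(a, b) {
  get_mc <- function(x) {
    if (inherits(x, "diameter_estimate")) {
      if (is.null(x$mc_distribution))
        stop("run monte_carlo_error() first")
      x <- x$mc_distribution
    }
    as.numeric(x)
  }
  a <- get_mc(a); b <- get_mc(b)
  if (length(a) < 20L || length(b) < 20L)
    warning("fewer than 20 draws per group; t-test unreliable")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("both distributions have zero variance")
  stats::t.test(a, b, alternative = "two.sided")
}

#' Annulus mask
#'
#' @param dim `(ny, nx)` of the target image.
#' @param center `(x, y)` pixels; defaults to the image center.
#' @param r_inner,r_outer Radii in pixels.
#' @return Logical `(ny, nx)` matrix.
#' @export
annulus_mask <- function(dim, center = NULL, r_inner, r_outer) {
  stopifnot(r_outer > r_inner, r_inner >= 0)
  if (is.null(center)) center <- c((dim[2] - 1) / 2, (dim[1] - 1) / 2)
  yy <- matrix(0:(dim[1] - 1), dim[1], dim[2])
  xx <- matrix(0:(dim[2] - 1), dim[1], dim[2], byrow = TRUE)
  rr <- sqrt((xx - center[1])^2 + (yy - center[2])^2)
  rr >= r_inner & rr <= r_outer
}

#' Sector (wedge) mask
#'
#' @inheritParams annulus_mask
#' @param r_range `(r_min, r_max)` pixels.
#' @param angle_range_deg `(from, to)` degrees, measured from +x toward
#'   +y; may wrap past 360.
#' @return Logical `(ny, nx)` matrix.
#' @export
sector_mask <- function(dim, center = NULL, r_range, angle_range_deg) {
  if (is.null(center)) center <- c((dim[2] - 1) / 2, (dim[1] - 1) / 2)
  yy <- matrix(0:(dim[1] - 1), dim[1], dim[2])
  xx <- matrix(0:(dim[2] - 1), dim[1], dim[2], byrow = TRUE)
  rr <- sqrt((xx - center[1])^2 + (yy - center[2])^2)
  ang <- (atan2(yy - center[2], xx - center[1]) * 180 / pi) %% 360
  a0 <- angle_range_deg[1] %% 360; a1 <- angle_range_deg[2] %% 360
  in_ang <- if (a0 <= a1) ang >= a0 & ang <= a1 else ang >= a0 | ang <= a1
  rr >= r_range[1] & rr <= r_range[2] & in_ang
}

#' Partition fluorescence between toroid and bridge regions
#'
#' Integrates background-subtracted intensity over disjoint ring-annulus
#' and bridge masks of the (sum-projected) image and reports each
#' region's fraction of their combined flux. The background is the mode
#' of pixel values outside both masks.
#'
#' @param x An [average_particles()] result, [volume_image()] or matrix,
#'   previously oriented so the bridge points in the masked direction.
#' @param ring_mask,bridge_mask Logical matrices matching the projected
#'   image; must be non-empty and disjoint.
#' @param z Projection rule (default `"sum"`).
#' @return Named numeric `c(fraction_toroid, fraction_bridge)`; the two
#'   sum to 1.
#' @export
toroid_bridge_fraction <- function(x, ring_mask, bridge_mask, z = "sum") {
  img <- .as_image2d(x, z)
  stopifnot(is.logical(ring_mask), is.logical(bridge_mask),
            all(dim(ring_mask) == dim(img)), all(dim(bridge_mask) == dim(img)))
  if (!any(ring_mask) || !any(bridge_mask))
    stop("mask spec invalid: ring and bridge masks must be non-empty")
  if (any(ring_mask & bridge_mask)) stop("ring and bridge masks overlap")
  outside <- !(ring_mask | bridge_mask)
  bg <- if (any(outside)) density_mode(img[outside]) else 0
  flux_r <- max(sum(img[ring_mask]) - bg * sum(ring_mask), 0)
  flux_b <- max(sum(img[bridge_mask]) - bg * sum(bridge_mask), 0)
  tot <- flux_r + flux_b
  if (tot <= 0) stop("no flux above background in either mask")
  c(fraction_toroid = flux_r / tot, fraction_bridge = flux_b / tot)
}
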