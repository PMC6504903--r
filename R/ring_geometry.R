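# Tilted-ring model and analytic plane-crossing solutions.
#
# A ring of radius r centered at (xc, yc, zc) is tilted from the image
# plane by theta and rotated about the microscope z axis by phi. Travel
# around the ring is parameterized by the angle rho:
#
#   x(rho) = xc - r cos(rho) sin(phi) + r sin(rho) cos(theta) cos(phi)
#   y(rho) = yc + r cos(rho) cos(phi) + r sin(rho) cos(theta) sin(phi)
#   z(rho) = zc - r sin(rho) sin(theta)
#
# All geometry is in 0-based voxel-center pixel units, axis order (x, y, z).

# plane definitions: constraint normal n (n . (p - guess) = 0) and the
# in-section lateral unit vector u (the section's positive half).
.plane_defs <- list(
  "xz"  = list(n = c(1, 0),                u = c(0, 1)),               # x = 0
  "yz"  = list(n = c(0, 1),                u = c(1, 0)),               # y = 0
  "45"  = list(n = c(1, -1) / sqrt(2),     u = c(1, 1) / sqrt(2)),     # x = y
  "135" = list(n = c(1, 1) / sqrt(2),      u = c(-1, 1) / sqrt(2))     # x = -y
)

plane_names <- function() names(.plane_defs)

#' Construct a tilted-ring pose
#'
#' A `ring_pose` holds the five geometric parameters of the ring model:
#' center `(xc, yc, zc)` in pixels, radius `r` in pixels, tilt `theta`
#' (radians, from the image plane, in `[0, pi/2)`) and rotation `phi`
#' (radians, about the z axis, wrapped into `[0, 2*pi)`).
#'
#' @param xc,yc,zc Ring center in 0-based pixel coordinates.
#' @param r Ring radius in pixels; must be positive.
#' @param theta Tilt angle in radians, `0 <= theta < pi/2`.
#' @param phi Rotation angle in radians; wrapped into `[0, 2*pi)`.
#' @return An object of class `"ring_pose"`.
#' @examples
#' ring_pose(32, 32, 16, r = 40, theta = 20 * pi / 180, phi = 1)
#' @export
ring_pose <- function(xc, yc, zc, r, theta = 0, phi = 0) {
  stopifnot(is.finite(xc), is.finite(yc), is.finite(zc), is.finite(r),
            is.finite(theta), is.finite(phi))
  if (r <= 0) stop("ring radius must be positive")
  if (theta < 0 || theta >= pi / 2) stop("tilt angle theta must lie in [0, pi/2)")
  structure(list(xc = xc, yc = yc, zc = zc, r = r,
                 theta = theta, phi = wrap_2pi(phi)),
            class = "ring_pose")
}

#' @export
print.ring_pose <- function(x, ...) {
  cat(sprintf(
    "ring_pose: center (%.3f, %.3f, %.3f) px, r = %.3f px, theta = %.2f deg, phi = %.2f deg\n",
    x$xc, x$yc, x$zc, x$r, x$theta * 180 / pi, x$phi * 180 / pi))
  invisible(x)
}

#' Evaluate the tilted-ring model
#'
#' Returns the 3D point reached after traveling angle `rho` around the
#' ring described by `pose`. Vectorized over `rho`.
#'
#' @param pose A [ring_pose()].
#' @param rho Travel angle(s) in radians.
#' @return A matrix with columns `x`, `y`, `z` (pixels), one row per `rho`.
#' @examples
#' p <- ring_pose(0, 0, 0, r = 1)
#' ring_point(p, pi / 2)  # (1, 0, 0)
#' @export
ring_point <- function(pose, rho) {
  stopifnot(inherits(pose, "ring_pose"))
  ct <- cos(pose$theta); st <- sin(pose$theta)
  cp <- cos(pose$phi);  sp <- sin(pose$phi)
  cr <- cos(rho); sr <- sin(rho)
  cbind(x = pose$xc - pose$r * cr * sp + pose$r * sr * ct * cp,
        y = pose$yc + pose$r * cr * cp + pose$r * sr * ct * sp,
        z = pose$zc - pose$r * sr * st)
}

# Coefficients of the plane-crossing condition
#   A cos(rho) + B sin(rho) + C = 0
# for a given plane through `guess`, plus the paper-style dimensionless
# intermediates a = A'/B', c = C'/B' where defined.
.crossing_coefs <- function(pose, plane, guess) {
  pd <- .plane_defs[[plane]]
  if (is.null(pd)) stop("unknown plane '", plane, "'; use one of ",
                        paste(plane_names(), collapse = ", "))
  n <- pd$n
  ct <- cos(pose$theta)
  cp <- cos(pose$phi); sp <- sin(pose$phi)
  d <- c(pose$xc - guess[1], pose$yc - guess[2])
  A <- pose$r * (-n[1] * sp + n[2] * cp)
  B <- pose$r * ct * (n[1] * cp + n[2] * sp)
  C <- sum(n * d)
  a <- if (abs(B) > 1e-12) -A / B else NA_real_
  cc <- if (abs(B) > 1e-12) C / B else NA_real_
  list(A = A, B = B, C = C, a = a, c = cc, n = n, u = pd$u)
}

# Stable ordering of a crossing pair: the crossing on the section's
# positive lateral half comes first; ties broken by increasing rho.
# This is what keeps the eight spots from being swapped between fits.
.order_crossings <- function(rho, pts, u, guess) {
  t_lat <- u[1] * (pts[, "x"] - guess[1]) + u[2] * (pts[, "y"] - guess[2])
  ord <- order(-round(t_lat, 9), rho)
  list(rho = rho[ord], points = pts[ord, , drop = FALSE], t = t_lat[ord])
}

#' Analytic plane crossings of a tilted ring
#'
#' Finds the two travel angles `rho` at which the ring crosses one of the
#' four cross-section planes through `center_guess`: `"xz"` (x = 0),
#' `"yz"` (y = 0), `"45"` (x = y) or `"135"` (x = -y), with coordinates
#' taken relative to `center_guess`. The crossing condition reduces to
#' `A cos(rho) + B sin(rho) + C = 0`, solved exactly with the
#' two-argument arctangent; both branches are returned in `[0, 2*pi)`,
#' ordered stably (the crossing on the section's positive half first).
#'
#' @param pose A [ring_pose()].
#' @param plane One of `"xz"`, `"yz"`, `"45"`, `"135"`.
#' @param center_guess Numeric length-3 `(x, y, z)`; the planes pass
#'   through this point.
#' @return A list with `rho` (numeric, length 2, or length 0 when the ring
#'   does not cross the plane), `points` (matrix of crossing coordinates),
#'   `a`, `c` (dimensionless intermediates, `NA` when the closed form is
#'   singular), and `status` (`"ok"`, `"no-crossing"`, `"fallback"`).
#' @examples
#' p <- ring_pose(0, 0, 0, r = 40)
#' plane_crossings(p, "xz", c(0, 0, 0))$rho  # pi/2 and 3*pi/2 for a flat ring
#' @export
plane_crossings <- function(pose, plane = plane_names(), center_guess) {
  stopifnot(inherits(pose, "ring_pose"), length(center_guess) == 3)
  plane <- match.arg(plane)
  co <- .crossing_coefs(pose, plane, center_guess)
  R0 <- sqrt(co$A^2 + co$B^2)
  if (R0 < 1e-8 * max(pose$r, 1)) {
    # singular closed form (e.g. cos(theta)*cos(phi)-type factor ~ 0):
    # delegate to the dense solver
    bf <- brute_force_crossings(pose, plane, center_guess)
    bf$a <- co$a; bf$c <- co$c
    bf$status <- if (length(bf$rho)) "fallback" else "no-crossing"
    return(bf)
  }
  disc <- R0^2 - co$C^2
  if (disc < 0) {
    return(list(rho = numeric(0), points = ring_point(pose, numeric(0)),
                a = co$a, c = co$c, status = "no-crossing"))
  }
  delta <- atan2(co$A, co$B)           # A cos + B sin = R0 sin(rho + delta)
  s0 <- asin(max(-1, min(1, -co$C / R0)))
  rho <- wrap_2pi(c(s0 - delta, pi - s0 - delta))
  pts <- ring_point(pose, rho)
  ord <- .order_crossings(rho, pts, co$u, center_guess)
  list(rho = ord$rho, points = ord$points, t = ord$t,
       a = co$a, c = co$c, status = "ok")
}

#' Brute-force plane crossings (independent oracle)
#'
#' Same contract as [plane_crossings()], implemented by dense sampling of
#' the ring model followed by sign-change bisection of the plane residual.
#' Slower but free of closed-form branch choices; used to validate the
#' analytic solver and as its fallback near coefficient singularities.
#'
#' @inheritParams plane_crossings
#' @param n_grid Number of initial samples of `rho` over `[0, 2*pi)`.
#' @param tol Bisection tolerance on `rho`, radians.
#' @return As [plane_crossings()].
#' @export
brute_force_crossings <- function(pose, plane = plane_names(), center_guess,
                                  n_grid = 32768L, tol = 1e-12) {
  stopifnot(inherits(pose, "ring_pose"), length(center_guess) == 3)
  plane <- match.arg(plane)
  pd <- .plane_defs[[plane]]
  n <- pd$n
  f <- function(rho) {
    p <- ring_point(pose, rho)
    n[1] * (p[, "x"] - center_guess[1]) + n[2] * (p[, "y"] - center_guess[2])
  }
  grid <- seq(0, 2 * pi, length.out = n_grid + 1L)
  fg <- f(grid)
  s <- sign(fg)
  s[s == 0] <- 1e-300  # exact zeros count as a crossing of either sign
  ix <- which(s[-length(s)] * s[-1] < 0 | fg[-length(fg)] == 0)
  roots <- numeric(0)
  for (i in ix) {
    lo <- grid[i]; hi <- grid[i + 1L]
    flo <- fg[i]
    if (flo == 0) { roots <- c(roots, lo); next }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (fm == 0) { lo <- mid; hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- wrap_2pi(roots)
  # collapse duplicates from the periodic seam
  if (length(roots) > 1L) {
    roots <- sort(roots)
    keep <- c(TRUE, diff(roots) > 1e-9)
    if (roots[1] + 2 * pi - roots[length(roots)] <= 1e-9) keep[1] <- FALSE
    roots <- roots[keep]
  }
  if (!length(roots)) {
    return(list(rho = numeric(0), points = ring_point(pose, numeric(0)),
                status = "no-crossing"))
  }
  pts <- ring_point(pose, roots)
  ord <- .order_crossings(roots, pts, pd$u, center_guess)
  list(rho = ord$rho, points = ord$points, t = ord$t, status = "ok")
}

#' All plane crossings of a ring through a guess center
#'
#' Convenience wrapper returning the crossings for all four section
#' planes (`xz`, `yz`, `45`, `135`) — the eight spot positions on which
#' the global cross-section fit operates.
#'
#' @inheritParams plane_crossings
#' @return Named list of [plane_crossings()] results, one per plane.
#' @export
ring_crossings <- function(pose, center_guess) {
  res <- lapply(plane_names(), function(p) plane_crossings(pose, p, center_guess))
  names(res) <- plane_names()
  res
}
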