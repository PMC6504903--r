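# Realignment of fitted particles (flatten, orient, randomize) and
# averaging into a single map.

#' Resample a volume so the fitted ring is flat and centered
#'
#' Applies the rigid rotation that undoes the fitted pose — first
#' `-phi` about z, then `-theta` about the in-plane axis — about the
#' fitted center, then recenters the ring at the middle voxel of an
#' odd-dimension cubic canvas. Trilinear resampling.
#'
#' @param volume A [volume_image()].
#' @param pose A fitted [ring_pose()].
#' @param out_dim Optional odd cube side in voxels; default
#'   `canvas_factor` times the fitted diameter, rounded up to odd.
#' @param canvas_factor Canvas size relative to the fitted diameter.
#' @return An object of class `"aligned_particle"`: `volume` (the
#'   resampled [volume_image()]), `source_pose`, `rotation_applied`
#'   (in-plane, radians), `brightness_scale`.
#' @export
flatten_transform <- function(volume, pose, out_dim = NULL, canvas_factor = 2.5) {
  stopifnot(inherits(volume, "volume_image"), inherits(pose, "ring_pose"))
  d <- dim(volume$data)
  rng <- ring_point(pose, seq(0, 2 * pi, length.out = 256))
  if (min(rng[, "x"]) < 0 || max(rng[, "x"]) > d[3] - 1 ||
      min(rng[, "y"]) < 0 || max(rng[, "y"]) > d[2] - 1 ||
      min(rng[, "z"]) < 0 || max(rng[, "z"]) > d[1] - 1)
    stop("fitted ring lies partially outside the resampling support")
  if (is.null(out_dim)) out_dim <- odd_dim(canvas_factor * 2 * pose$r)
  if (out_dim %% 2L == 0L) stop("output canvas must have odd dimensions")
  # output voxel -> source: invert flatten rotation F = Ry(-theta) Rz(-phi)
  Rinv <- rot_z(pose$phi) %*% rot_y(pose$theta)
  out <- affine_resample(volume$data, Rinv,
                         center_in = c(pose$xc, pose$yc, pose$zc),
                         out_dim = rep(out_dim, 3L))
  structure(list(volume = volume_image(pmax(out, 0), volume$voxel_size,
                                       volume$channel),
                 source_pose = pose, rotation_applied = 0,
                 brightness_scale = 1),
            class = "aligned_particle")
}

# in-plane (xy) rotation of an aligned particle's volume about its center
.rotate_inplane <- function(p, gamma) {
  v <- p$volume
  out <- affine_resample(v$data, rot_z(-gamma),
                         center_in = (dim(v$data)[c(3, 2, 1)] - 1) / 2,
                         out_dim = dim(v$data))
  p$volume <- volume_image(pmax(out, 0), v$voxel_size, v$channel)
  p$rotation_applied <- p$rotation_applied + gamma
  p
}

#' Orient an aligned particle by a secondary-channel reference
#'
#' Rotates in-plane so that the vector from the volume center to
#' `reference_point` points along +y (`"up"`) or +x (`"sideways"`) —
#' used when an asymmetric secondary distribution (e.g. a half-bridge)
#' must point in a reproducible direction before averaging.
#'
#' @param p An [flatten_transform()] result.
#' @param reference_point `(x, y)` in the aligned frame, relative to the
#'   volume center.
#' @param target `"up"` or `"sideways"`.
#' @return The rotated `aligned_particle`.
#' @export
orient_by_secondary <- function(p, reference_point, target = c("up", "sideways")) {
  stopifnot(inherits(p, "aligned_particle"), length(reference_point) == 2)
  target <- match.arg(target)
  if (sum(reference_point^2) < 1e-12)
    stop("reference point coincides with the center; orientation undefined")
  cur <- atan2(reference_point[2], reference_point[1])
  goal <- if (target == "up") pi / 2 else 0
  gamma <- goal - cur
  if (abs(gamma) < 1e-12) return(p)
  .rotate_inplane(p, gamma)
}

#' Randomly rotate an aligned particle in-plane
#'
#' Uniform rotation in `[0, 2*pi)` drawn with the given seed;
#' reproducible. Used to wash out accidental nonhomogeneous regions
#' before averaging when ring gaps carry no reproducible orientation.
#'
#' @param p An `aligned_particle`.
#' @param seed Integer seed.
#' @return The rotated `aligned_particle`.
#' @export
randomize_rotation <- function(p, seed) {
  stopifnot(inherits(p, "aligned_particle"))
  gamma <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  .rotate_inplane(p, gamma)
}

#' Average aligned particles into a single map
#'
#' Voxelwise mean of the aligned volumes. With
#' `normalize_outliers = TRUE`, any particle whose integrated intensity
#' exceeds 3x the median is first rescaled by the ratio of the median to
#' its own integrated intensity, so one much-brighter image cannot
#' dominate the average.
#'
#' @param particles List of `aligned_particle` (or a single one), all the
#'   same shape.
#' @param normalize_outliers Rescale over-bright particles?
#' @return An object of class `"average_map"`: `volume`
#'   (a [volume_image()]), `n`, `provenance` (data frame of per-particle
#'   rotation and brightness scale).
#' @export
average_particles <- function(particles, normalize_outliers = TRUE) {
  if (inherits(particles, "aligned_particle")) particles <- list(particles)
  stopifnot(length(particles) >= 1L)
  lapply(particles, function(p) stopifnot(inherits(p, "aligned_particle")))
  dims <- vapply(particles, function(p) paste(dim(p$volume$data), collapse = "x"), "")
  if (length(unique(dims)) != 1L) stop("aligned particles must share one shape")
  totals <- vapply(particles, function(p) sum(p$volume$data), 0)
  scales <- rep(1, length(particles))
  if (normalize_outliers && length(particles) > 1L) {
    # leave-one-out median: a much-brighter image is judged against the
    # OTHER images, and rescaled by its ratio to them
    for (i in seq_along(totals)) {
      med_i <- stats::median(totals[-i])
      if (med_i > 0 && totals[i] > 3 * med_i) scales[i] <- med_i / totals[i]
    }
  }
  acc <- array(0, dim = dim(particles[[1]]$volume$data))
  for (i in seq_along(particles)) acc <- acc + scales[i] * particles[[i]]$volume$data
  acc <- acc / length(particles)
  prov <- data.frame(particle = seq_along(particles),
                     integrated = totals, scale = scales,
                     rotation = vapply(particles, function(p) p$rotation_applied, 0))
  structure(list(volume = volume_image(acc, particles[[1]]$volume$voxel_size,
                                       particles[[1]]$volume$channel),
                 n = length(particles), provenance = prov),
            class = "average_map")
}

#' @export
print.average_map <- function(x, ...) {
  cat(sprintf("average_map of %d particle(s)\n", x$n))
  print(x$volume)
  invisible(x)
}
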