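# Ground-truth synthetic scenes: toroids with anisotropic PSF and noise,
# and acceptor-photobleaching FRET image pairs.

#' Describe a synthetic toroid scene
#'
#' A `scene_spec` is the ground-truth description from which
#' [simulate_toroid_volume()] renders a volume. Defaults emulate the
#' package's validation regime: a diploid-sized ring (160 nm) sampled at
#' 2 nm lateral voxels with the pixel-scale PSF used throughout the fit
#' validation suite (sigma 2 px lateral, 6 px axial).
#'
#' @param diameter_nm Ring diameter in nm (> 0).
#' @param theta_deg,phi_deg Tilt from the image plane and rotation about
#'   z, degrees.
#' @param center_offset_px Length-3 `(x, y, z)` offset of the ring center
#'   from the volume center, pixels.
#' @param voxel_size_nm `(dz, dy, dx)` in nm.
#' @param psf_sigma_nm `(lateral, axial)` Gaussian PSF sigmas in nm;
#'   axial must be >= lateral (the microscope's asymmetric resolution).
#' @param photons Total expected photon count of the particle
#'   (ring + bridge).
#' @param bridge_fraction Fraction of particle flux in the half-bridge
#'   blob, in `[0, 1)`.
#' @param bridge_angle_deg Travel angle around the ring at which the
#'   bridge sits.
#' @param bridge_offset_nm Distance of the bridge blob center beyond the
#'   ring radius, nm.
#' @param bridge_extent_nm Isotropic Gaussian sigma of the bridge blob, nm.
#' @param n_puncta Number of NPC-like background puncta.
#' @param puncta_flux Expected photons per punctum.
#' @param read_noise Gaussian read noise SD, counts.
#' @param poisson Apply Poisson noise to expected counts?
#' @param dim Optional `(nz, ny, nx)`; sized automatically when `NULL`.
#' @param seed Integer seed controlling all randomness of the scene.
#' @return An object of class `"scene_spec"`.
#' @export
scene_spec <- function(diameter_nm = 160, theta_deg = 20, phi_deg = 30,
                       center_offset_px = c(0, 0, 0),
                       voxel_size_nm = c(2, 2, 2),
                       psf_sigma_nm = c(4, 12),
                       photons = 2e6,
                       bridge_fraction = 0, bridge_angle_deg = 90,
                       bridge_offset_nm = 60, bridge_extent_nm = 20,
                       n_puncta = 0, puncta_flux = 2e4,
                       read_noise = 1, poisson = TRUE,
                       dim = NULL, seed = 1L) {
  stopifnot(diameter_nm > 0, bridge_fraction >= 0, bridge_fraction < 1,
            length(psf_sigma_nm) == 2, all(psf_sigma_nm >= 0))
  if (psf_sigma_nm[2] < psf_sigma_nm[1])
    stop("axial PSF sigma must be >= lateral sigma")
  if (theta_deg < 0 || theta_deg >= 90) stop("theta_deg must lie in [0, 90)")
  structure(list(diameter_nm = diameter_nm, theta_deg = theta_deg,
                 phi_deg = phi_deg, center_offset_px = center_offset_px,
                 voxel_size_nm = voxel_size_nm, psf_sigma_nm = psf_sigma_nm,
                 photons = photons, bridge_fraction = bridge_fraction,
                 bridge_angle_deg = bridge_angle_deg,
                 bridge_offset_nm = bridge_offset_nm,
                 bridge_extent_nm = bridge_extent_nm,
                 n_puncta = n_puncta, puncta_flux = puncta_flux,
                 read_noise = read_noise, poisson = poisson,
                 dim = dim, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Preset scene specifications
#'
#' Named presets mirroring the biological cases the pipeline targets:
#' `"diploid-ndc1"` (160 nm ring), `"haploid"` (100 nm), `"nbp1-like"`
#' (135 nm sample ring), `"fiducial"` (170 nm reference ring) and
#' `"mps3-like"` (ring plus half-bridge carrying 55% of the flux).
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [scene_spec()].
#' @return A [scene_spec()].
#' @export
scene_preset <- function(name = c("diploid-ndc1", "haploid", "nbp1-like",
                                  "fiducial", "mps3-like"),
                         seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(name,
    "diploid-ndc1" = list(diameter_nm = 160),
    "haploid"      = list(diameter_nm = 100),
    "nbp1-like"    = list(diameter_nm = 135),
    "fiducial"     = list(diameter_nm = 170),
    "mps3-like"    = list(diameter_nm = 167, bridge_fraction = 0.55,
                          theta_deg = 0, phi_deg = 0))
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(scene_spec, args)
}

# weighted trilinear splat of point samples into a (z, y, x) array
.splat <- function(arr, x, y, z, w) {
  d <- dim(arr); nz <- d[1]; ny <- d[2]; nx <- d[3]
  keep <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1 & z >= 0 & z <= nz - 1
  x <- x[keep]; y <- y[keep]; z <- z[keep]; w <- w[keep]
  if (!length(x)) return(arr)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2); z0 <- pmin(floor(z), nz - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(ix, iy, iz) iz + 1 + nz * (iy + ny * ix)
  ii <- c(idx(x0, y0, z0), idx(x0, y0, z0 + 1), idx(x0, y0 + 1, z0),
          idx(x0, y0 + 1, z0 + 1), idx(x0 + 1, y0, z0), idx(x0 + 1, y0, z0 + 1),
          idx(x0 + 1, y0 + 1, z0), idx(x0 + 1, y0 + 1, z0 + 1))
  ww <- c(w * (1 - fx) * (1 - fy) * (1 - fz), w * (1 - fx) * (1 - fy) * fz,
          w * (1 - fx) * fy * (1 - fz), w * (1 - fx) * fy * fz,
          w * fx * (1 - fy) * (1 - fz), w * fx * (1 - fy) * fz,
          w * fx * fy * (1 - fz), w * fx * fy * fz)
  acc <- rowsum(ww, ii)
  arr[as.integer(rownames(acc))] <- arr[as.integer(rownames(acc))] + acc[, 1]
  arr
}

# unit-sum discrete Gaussian along an axis, centered at 0-based c0
.axis_gauss <- function(n, c0, sigma) {
  g <- exp(-((0:(n - 1)) - c0)^2 / (2 * max(sigma, 1e-6)^2))
  s <- sum(g)
  if (s <= 0) g else g / s
}

#' Render a synthetic toroid volume with ground truth
#'
#' The ring is rendered as a uniform line emitter along the tilted-ring
#' model (64 sub-pixel samples per pixel of arc), optionally joined by a
#' half-bridge Gaussian blob and NPC-like background puncta, convolved
#' with the anisotropic Gaussian PSF, and degraded with Poisson noise and
#' Gaussian read noise. Deterministic per `spec$seed`.
#'
#' @param spec A [scene_spec()].
#' @return List with `volume` (a [volume_image()]) and `truth` (list with
#'   the exact `pose` as a [ring_pose()] in pixel units, component fluxes,
#'   and punctum positions).
#' @export
simulate_toroid_volume <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  vs <- spec$voxel_size_nm
  r_px <- spec$diameter_nm / 2 / vs[3]
  theta <- spec$theta_deg * pi / 180
  phi <- spec$phi_deg * pi / 180
  sig_lat_px <- spec$psf_sigma_nm[1] / vs[3]
  sig_ax_px <- spec$psf_sigma_nm[2] / vs[1]
  d <- spec$dim
  if (is.null(d)) {
    extra <- if (spec$bridge_fraction > 0)
      (spec$bridge_offset_nm + 3 * spec$bridge_extent_nm) / vs[3] else 0
    nlat <- odd_dim(2 * (1.8 * r_px + extra + 3 * sig_lat_px))
    nz <- odd_dim(2 * (r_px * sin(theta) + 3 * sig_ax_px + 3 +
                         abs(spec$center_offset_px[3])))
    d <- c(max(nz, 15L), nlat, nlat)
  }
  center <- c((d[3] - 1) / 2, (d[2] - 1) / 2, (d[1] - 1) / 2) + spec$center_offset_px
  pose <- ring_pose(center[1], center[2], center[3], r_px, theta, phi)
  # reject rings whose support leaves the volume
  rng <- ring_point(pose, seq(0, 2 * pi, length.out = 256))
  pad <- c(2 * sig_lat_px + 1, 2 * sig_lat_px + 1, 2 * sig_ax_px + 1)
  if (min(rng[, "x"]) < pad[1] - 1 || max(rng[, "x"]) > d[3] - pad[1] ||
      min(rng[, "y"]) < pad[2] - 1 || max(rng[, "y"]) > d[2] - pad[2] ||
      min(rng[, "z"]) < pad[3] - 1 || max(rng[, "z"]) > d[1] - pad[3])
    stop("ring (plus PSF support) exceeds volume bounds; enlarge dim")

  ring_flux <- spec$photons * (1 - spec$bridge_fraction)
  bridge_flux <- spec$photons * spec$bridge_fraction
  arr <- array(0, dim = d)
  n_samp <- max(256L, ceiling(64 * 2 * pi * r_px))
  rho <- (seq_len(n_samp) - 0.5) / n_samp * 2 * pi
  pts <- ring_point(pose, rho)
  arr <- .splat(arr, pts[, "x"], pts[, "y"], pts[, "z"],
                rep(ring_flux / n_samp, n_samp))

  if (bridge_flux > 0) {
    e1 <- c(-sin(phi), cos(phi), 0)
    e2 <- c(cos(theta) * cos(phi), cos(theta) * sin(phi), -sin(theta))
    beta <- spec$bridge_angle_deg * pi / 180
    bc <- center + (r_px + spec$bridge_offset_nm / vs[3]) *
      (cos(beta) * e1 + sin(beta) * e2)
    sb_lat <- spec$bridge_extent_nm / vs[3]
    sb_ax <- spec$bridge_extent_nm / vs[1]
    gz <- .axis_gauss(d[1], bc[3], sb_ax)
    gy <- .axis_gauss(d[2], bc[2], sb_lat)
    gx <- .axis_gauss(d[3], bc[1], sb_lat)
    arr <- arr + bridge_flux * outer(outer(gz, gy), gx)
  }

  puncta <- NULL
  noisy <- with_seed(spec$seed, {
    if (spec$n_puncta > 0) {
      px <- stats::runif(spec$n_puncta, 2, d[3] - 3)
      py <- stats::runif(spec$n_puncta, 2, d[2] - 3)
      pz <- stats::runif(spec$n_puncta, 2, d[1] - 3)
      puncta <- cbind(x = px, y = py, z = pz)
      arr <- .splat(arr, px, py, pz, rep(spec$puncta_flux, spec$n_puncta))
    }
    arr <- gauss_blur(arr, c(sig_ax_px, sig_lat_px, sig_lat_px))
    arr[arr < 0] <- 0
    if (spec$poisson) arr[] <- stats::rpois(length(arr), arr)
    if (spec$read_noise > 0)
      arr <- arr + stats::rnorm(length(arr), 0, spec$read_noise)
    arr[arr < 0] <- 0
    arr
  })
  list(volume = volume_image(noisy, vs, "simulated"),
       truth = list(pose = pose, ring_flux = ring_flux,
                    bridge_flux = bridge_flux,
                    bridge_center = if (bridge_flux > 0) bc else NULL,
                    puncta = puncta, spec = spec))
}

#' Predicted peak signal-to-noise ratio of a scene
#'
#' Renders the noise-free expected image and reports
#' `peak / sqrt(peak + read_noise^2)`, the shot-plus-read-noise SNR at
#' the brightest voxel.
#'
#' @param spec A [scene_spec()].
#' @return List with `peak` (expected counts) and `snr`.
#' @export
predicted_snr <- function(spec) {
  clean <- utils::modifyList(spec, list(poisson = FALSE, read_noise = 0))
  class(clean) <- "scene_spec"
  pk <- max(simulate_toroid_volume(clean)$volume$data)
  list(peak = pk, snr = pk / sqrt(pk + spec$read_noise^2))
}

#' Derive jittered seed annotations from ground truth
#'
#' Emulates approximate manual clicks: the four ring points at travel
#' angles 0, 90, 180 and 270 degrees, perturbed laterally by Gaussian
#' jitter.
#'
#' @param truth Ground truth from [simulate_toroid_volume()].
#' @param jitter_px SD of the perturbation, pixels.
#' @param seed Integer seed.
#' @return A [particle_seed()].
#' @export
make_seeds <- function(truth, jitter_px = 2, seed = 1L) {
  pts <- ring_point(truth$pose, c(0, pi / 2, pi, 3 * pi / 2))[, c("x", "y")]
  pts <- with_seed(seed, pts + matrix(stats::rnorm(8, 0, jitter_px), 4, 2))
  particle_seed("sim", "simulated", pts, z_hint = round(truth$pose$zc))
}

#' Default toroid/bridge partition masks for a simulated scene
#'
#' Builds the ring-annulus and bridge-sector masks used to partition
#' particle flux, from the scene's ground truth: an annulus of
#' `ring_halfwidth` pixels around the ring radius, and a sector centered
#' on the bridge azimuth extending from the annulus edge to the image
#' border.
#'
#' @param truth Ground truth from [simulate_toroid_volume()].
#' @param dim_yx `(ny, nx)` of the projected image.
#' @param ring_halfwidth Annulus half-width, pixels.
#' @param sector_halfangle Bridge sector half-angle, degrees.
#' @return List with logical matrices `ring` and `bridge`.
#' @export
truth_partition_masks <- function(truth, dim_yx, ring_halfwidth = 12,
                                  sector_halfangle = 75) {
  ctr <- c(truth$pose$xc, truth$pose$yc)
  r <- truth$pose$r
  ring <- annulus_mask(dim_yx, ctr, max(r - ring_halfwidth, 0), r + ring_halfwidth)
  if (is.null(truth$bridge_center))
    stop("scene has no bridge component")
  az <- atan2(truth$bridge_center[2] - ctr[2],
              truth$bridge_center[1] - ctr[1]) * 180 / pi
  rmax <- min(ctr[1], dim_yx[2] - 1 - ctr[1], ctr[2], dim_yx[1] - 1 - ctr[2])
  bridge <- sector_mask(dim_yx, ctr,
                        r_range = c(r + ring_halfwidth + 1e-6, rmax),
                        angle_range_deg = az + c(-sector_halfangle, sector_halfangle))
  list(ring = ring, bridge = bridge)
}

#' Simulate an acceptor-photobleaching FRET image pair
#'
#' Donor spots are placed on a jittered grid; after complete acceptor
#' photobleaching each donor intensity rises by `1/(1 - E)`, attenuated
#' multiplicatively by the donor-only bleach fraction `b` (donor
#' photobleaching during the acceptor bleach), i.e.
#' `post = pre * (1 - b) / (1 - E)`. Both frames carry flat background,
#' Poisson noise and Gaussian read noise; `shift_px` translates the post
#' frame to exercise registration.
#'
#' @param true_efficiency FRET efficiency `E` in `[0, 1)`.
#' @param n_spots Number of donor puncta.
#' @param donor_only_bleach Donor bleach fraction `b` in `[0, 1)`.
#' @param photons Expected integrated photons per spot pre-bleach.
#' @param psf_sigma_px Lateral Gaussian sigma of a spot, pixels.
#' @param background Flat background level, counts/pixel.
#' @param read_noise Gaussian read noise SD, counts.
#' @param poisson Apply Poisson noise?
#' @param shift_px Integer `(dx, dy)` translation of the post frame.
#' @param seed Integer seed.
#' @return List with `pre`, `post` (matrices indexed `[y, x]`), and
#'   `truth` (data frame of spot positions and fluxes plus parameters).
#' @export
simulate_fret_series <- function(true_efficiency, n_spots,
                                 donor_only_bleach = 0,
                                 photons = 4000, psf_sigma_px = 2,
                                 background = 10, read_noise = 1,
                                 poisson = TRUE, shift_px = c(0, 0),
                                 seed = 1L) {
  stopifnot(true_efficiency >= 0, true_efficiency < 1,
            donor_only_bleach >= 0, donor_only_bleach < 1, n_spots >= 1)
  spacing <- 16L
  ngrid <- ceiling(sqrt(n_spots))
  side <- ngrid * spacing + 2L * spacing
  with_seed(seed, {
    gx <- (rep(seq_len(ngrid), times = ngrid) - 0.5) * spacing + spacing
    gy <- (rep(seq_len(ngrid), each = ngrid) - 0.5) * spacing + spacing
    keep <- seq_len(n_spots)
    x <- gx[keep] + stats::runif(n_spots, -3, 3)
    y <- gy[keep] + stats::runif(n_spots, -3, 3)
    flux_pre <- photons * exp(stats::rnorm(n_spots, 0, 0.15))
    rise <- (1 - donor_only_bleach) / (1 - true_efficiency)
    render <- function(flux, dx, dy) {
      img <- matrix(background, side, side)
      for (i in seq_len(n_spots)) {
        gyv <- .axis_gauss(side, y[i] + dy, psf_sigma_px)
        gxv <- .axis_gauss(side, x[i] + dx, psf_sigma_px)
        img <- img + flux[i] * outer(gyv, gxv)
      }
      if (poisson) img[] <- stats::rpois(length(img), img)
      if (read_noise > 0) img <- img + stats::rnorm(length(img), 0, read_noise)
      img[img < 0] <- 0
      img
    }
    pre <- render(flux_pre, 0, 0)
    post <- render(flux_pre * rise, shift_px[1], shift_px[2])
    list(pre = pre, post = post,
         truth = list(spots = data.frame(x = x, y = y, flux_pre = flux_pre),
                      true_efficiency = true_efficiency,
                      donor_only_bleach = donor_only_bleach,
                      shift_px = shift_px))
  })
}
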