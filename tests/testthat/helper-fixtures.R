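# Shared fixture builders. Everything is generated in code at test time.

# a small, fast toroid scene (diameter in nm at 2 nm/px lateral voxels)
small_scene <- function(diameter_nm = 100, theta_deg = 15, phi_deg = 40,
                        seed = 1L, ...) {
  scene_spec(diameter_nm = diameter_nm, theta_deg = theta_deg,
             phi_deg = phi_deg, photons = 5e4 * diameter_nm / 4,
             seed = seed, ...)
}

# draw a valid random pose for property tests (caller controls the seed)
random_pose <- function(theta_max_deg = 44) {
  ring_pose(stats::runif(1, -6, 6), stats::runif(1, -6, 6),
            stats::runif(1, -3, 3), stats::runif(1, 20, 60),
            stats::runif(1, 0, theta_max_deg) * pi / 180,
            stats::runif(1, 0, 2 * pi))
}

# wrapped absolute angular difference in degrees
angdiff_deg <- function(a, b) {
  abs(((a - b + pi) %% (2 * pi)) - pi) * 180 / pi
}

# aligned particle wrapping a given (z, y, x) array, via an identity pose
as_aligned <- function(arr, voxel = c(2, 2, 2)) {
  d <- dim(arr)
  v <- volume_image(pmax(arr, 0), voxel, "fixture")
  pose <- ring_pose((d[3] - 1) / 2, (d[2] - 1) / 2, (d[1] - 1) / 2,
                    r = (min(d) - 1) / 4)
  flatten_transform(v, pose, out_dim = min(d) - (1 - min(d) %% 2))
}
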