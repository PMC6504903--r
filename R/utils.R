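# Internal numerical helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded operations are
#' reproducible without perturbing the caller's stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Round up to the nearest odd integer
#' @noRd
odd_dim <- function(x) {
  n <- ceiling(x)
  if (n %% 2L == 0L) n + 1L else as.integer(n)
}

#' Bilinear interpolation on a matrix
#'
#' `img` is indexed `img[iy, ix]` with 0-based voxel-center coordinates,
#' i.e. the value at (x = 0, y = 0) is `img[1, 1]`. Out-of-bounds samples
#' return `fill`.
#' @noRd
interp2 <- function(img, x, y, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- numeric(length(x))
  # gather the four corners with clamping, mask invalid afterwards
  inb <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1
  x0c <- pmin(pmax(x0, 0), nx - 1); x1c <- pmin(x0c + 1, nx - 1)
  y0c <- pmin(pmax(y0, 0), ny - 1); y1c <- pmin(y0c + 1, ny - 1)
  i00 <- y0c + 1 + ny * x0c
  i10 <- y1c + 1 + ny * x0c
  i01 <- y0c + 1 + ny * x1c
  i11 <- y1c + 1 + ny * x1c
  v <- (1 - fx) * ((1 - fy) * img[i00] + fy * img[i10]) +
    fx * ((1 - fy) * img[i01] + fy * img[i11])
  out[inb] <- v[inb]
  out[!inb] <- fill
  out
}

#' Separable Gaussian blur along one array dimension via FFT
#'
#' Circular convolution with a unit-sum Gaussian kernel; conserves the
#' integral exactly. `margin` gives the dimension index.
#' @noRd
fft_blur_dim <- function(arr, sigma, margin) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  n <- d[margin]
  # unit-sum periodic Gaussian kernel centered at index 1
  off <- c(0:(n %/% 2), -((n - (n %/% 2) - 1):1))
  k <- exp(-off^2 / (2 * sigma^2))
  k <- k / sum(k)
  kf <- stats::fft(k)
  perm <- c(margin, seq_along(d)[-margin])
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  mf <- stats::mvfft(m)
  res <- Re(stats::mvfft(mf * kf, inverse = TRUE)) / n
  a <- array(res, dim = d[perm])
  aperm(a, order(perm))
}

#' Anisotropic Gaussian blur of a 2D or 3D array
#'
#' `sigma` follows the array's dimension order; for volumes stored
#' (z, y, x) pass `c(sz, sy, sx)`.
#' @noRd
gauss_blur <- function(arr, sigma) {
  d <- dim(arr)
  stopifnot(length(sigma) == length(d))
  for (m in seq_along(d)) arr <- fft_blur_dim(arr, sigma[m], m)
  arr
}

#' Trilinear sampling of a (z, y, x) volume at arbitrary points
#'
#' Coordinates are 0-based voxel-center `(x, y, z)`; out-of-support
#' samples return `fill`.
#' @noRd
interp3 <- function(vol, x, y, z, fill = 0) {
  d <- dim(vol); nz <- d[1]; ny <- d[2]; nx <- d[3]
  inb <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1 & z >= 0 & z <= nz - 1
  x0 <- pmin(pmax(floor(x), 0), nx - 1); fx <- pmin(pmax(x - x0, 0), 1)
  y0 <- pmin(pmax(floor(y), 0), ny - 1); fy <- pmin(pmax(y - y0, 0), 1)
  z0 <- pmin(pmax(floor(z), 0), nz - 1); fz <- pmin(pmax(z - z0, 0), 1)
  x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1); z1 <- pmin(z0 + 1, nz - 1)
  idx <- function(ix, iy, iz) iz + 1 + nz * (iy + ny * ix)
  v <-
    (1 - fx) * ((1 - fy) * ((1 - fz) * vol[idx(x0, y0, z0)] + fz * vol[idx(x0, y0, z1)]) +
                  fy * ((1 - fz) * vol[idx(x0, y1, z0)] + fz * vol[idx(x0, y1, z1)])) +
    fx * ((1 - fy) * ((1 - fz) * vol[idx(x1, y0, z0)] + fz * vol[idx(x1, y0, z1)]) +
            fy * ((1 - fz) * vol[idx(x1, y1, z0)] + fz * vol[idx(x1, y1, z1)]))
  v[!inb] <- fill
  v
}

#' Rigid resampling of a (z, y, x) volume
#'
#' For every output voxel at 0-based coordinate `p_out`, samples the input
#' at `R %*% (p_out - center_out) + center_in` (coordinates ordered
#' (x, y, z)). Processed in z-slabs to bound memory.
#' @noRd
affine_resample <- function(vol, R, center_in, out_dim, center_out = (out_dim[c(3, 2, 1)] - 1) / 2,
                            fill = 0, slab = NULL) {
  nz <- out_dim[1]; ny <- out_dim[2]; nx <- out_dim[3]
  # slabs sized so coordinate temporaries are large single blocks the
  # allocator maps and returns directly, rather than arena fragments
  if (is.null(slab)) slab <- max(8L, as.integer(ceiling(6e6 / (ny * nx))))
  out <- array(fill, dim = c(nz, ny, nx))
  xs <- (0:(nx - 1)) - center_out[1]
  ys <- (0:(ny - 1)) - center_out[2]
  for (z0 in seq(0L, nz - 1L, by = slab)) {
    z1 <- min(z0 + slab - 1L, nz - 1L)
    zs <- (z0:z1) - center_out[3]
    nzz <- length(zs)
    # broadcast grids in (z, y, x) storage order
    gx <- rep(xs, each = nzz * ny)
    gy <- rep(rep(ys, each = nzz), times = nx)
    gz <- rep(zs, times = ny * nx)
    sx <- R[1, 1] * gx + R[1, 2] * gy + R[1, 3] * gz + center_in[1]
    sy <- R[2, 1] * gx + R[2, 2] * gy + R[2, 3] * gz + center_in[2]
    sz <- R[3, 1] * gx + R[3, 2] * gy + R[3, 3] * gz + center_in[3]
    out[(z0 + 1):(z1 + 1), , ] <- array(interp3(vol, sx, sy, sz, fill = fill),
                                        dim = c(nzz, ny, nx))
  }
  out
}

#' Rotation matrices acting on (x, y, z) column vectors
#' @noRd
rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @noRd
rot_y <- function(a) {
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Mode of a continuous sample via kernel density
#' @noRd
density_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || stats::sd(x) == 0) return(x[1])
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Wrap angles into [0, 2*pi)
#' @noRd
wrap_2pi <- function(a) {
  a <- a %% (2 * pi)
  a[a < 0] <- a[a < 0] + 2 * pi
  a
}
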