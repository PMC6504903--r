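# Acceptor-photobleaching FRET: spot detection, pre/post registration,
# donor-intensity quantification and relative efficiency.

#' Detection and quantification settings for FRET images
#'
#' @param blur_sigma Gaussian pre-blur sigma, pixels.
#' @param bg_radius Local-background tile radius, pixels.
#' @param bg_percentile Percentile used as the local background level.
#' @param peak_snr Maxima threshold in units of the image noise SD.
#' @param grow_frac Region-grow cutoff as a fraction of the local maximum.
#' @param max_region Maximum region size, pixels.
#' @param moved_threshold Residual punctum displacement (pixels) above
#'   which a punctum is flagged as moved and excluded.
#' @return Named list of settings.
#' @export
fret_control <- function(blur_sigma = 1, bg_radius = 16, bg_percentile = 0.25,
                         peak_snr = 5, grow_frac = 0.5, max_region = 200L,
                         moved_threshold = 2) {
  list(blur_sigma = blur_sigma, bg_radius = bg_radius,
       bg_percentile = bg_percentile, peak_snr = peak_snr,
       grow_frac = grow_frac, max_region = max_region,
       moved_threshold = moved_threshold)
}

# local-percentile background field: tile quantiles, bilinearly upsampled
.local_background <- function(img, radius, prob) {
  ny <- nrow(img); nx <- ncol(img)
  cy <- unique(pmin(seq(1L, ny, by = radius), ny))
  cx <- unique(pmin(seq(1L, nx, by = radius), nx))
  q <- matrix(0, length(cy), length(cx))
  for (i in seq_along(cy)) for (j in seq_along(cx)) {
    ys <- max(1L, cy[i] - radius):min(ny, cy[i] + radius)
    xs <- max(1L, cx[j] - radius):min(nx, cx[j] + radius)
    q[i, j] <- stats::quantile(img[ys, xs], prob, names = FALSE)
  }
  # map every pixel to tile coordinates and interpolate
  py <- stats::approx(cy - 1, seq_along(cy) - 1, xout = 0:(ny - 1), rule = 2)$y
  px <- stats::approx(cx - 1, seq_along(cx) - 1, xout = 0:(nx - 1), rule = 2)$y
  matrix(interp2(q, rep(px, each = ny), rep(py, times = nx)), ny, nx)
}

# 8-connected region grow from a maximum while intensity >= frac * peak
.region_grow <- function(img, y0, x0, frac, max_size) {
  ny <- nrow(img); nx <- ncol(img)
  peak <- img[y0, x0]
  thr <- frac * peak
  visited <- matrix(FALSE, ny, nx)
  queue <- matrix(c(y0, x0), ncol = 2)
  visited[y0, x0] <- TRUE
  region <- integer(0)
  while (nrow(queue) > 0 && length(region) < max_size) {
    cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    region <- c(region, (cur[2] - 1L) * ny + cur[1])
    ys <- pmax(1L, cur[1] - 1L):pmin(ny, cur[1] + 1L)
    xs <- pmax(1L, cur[2] - 1L):pmin(nx, cur[2] + 1L)
    for (yy in ys) for (xx in xs) {
      if (!visited[yy, xx] && img[yy, xx] >= thr) {
        visited[yy, xx] <- TRUE
        queue <- rbind(queue, c(yy, xx))
      }
    }
  }
  region
}

#' Detect fluorescent puncta in a 2D image
#'
#' Gaussian blur, local-percentile background subtraction, local-maximum
#' finding above a noise-scaled threshold, then adaptive 8-connected
#' region growing around each maximum.
#'
#' @param image Numeric matrix indexed `[y, x]`.
#' @param control A [fret_control()] list.
#' @return An object of class `"puncta"`: `table` (data frame with
#'   0-based `x`, `y`, `peak`, `size`), `regions` (list of linear pixel
#'   indices), `bgsub` (background-subtracted blurred image), `noise_sd`.
#' @export
detect_puncta <- function(image, control = fret_control()) {
  stopifnot(is.matrix(image))
  ny <- nrow(image); nx <- ncol(image)
  sm <- if (control$blur_sigma > 0)
    gauss_blur(array(image, dim(image)), rep(control$blur_sigma, 2)) else image
  sm <- matrix(sm, ny, nx)
  bg <- .local_background(sm, control$bg_radius, control$bg_percentile)
  w <- sm - bg
  noise_sd <- stats::mad(w)
  thr <- control$peak_snr * max(noise_sd, 1e-12)
  # strict local maxima over the 8-neighborhood
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- w
  ismax <- w > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ismax <- ismax & (w >= pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)])
  }
  idx <- which(ismax)
  ord <- order(w[idx], decreasing = TRUE)
  idx <- idx[ord]
  taken <- matrix(FALSE, ny, nx)
  regions <- list(); rows <- list()
  for (i in idx) {
    y0 <- (i - 1L) %% ny + 1L; x0 <- (i - 1L) %/% ny + 1L
    if (taken[y0, x0]) next
    reg <- .region_grow(w, y0, x0, control$grow_frac, control$max_region)
    reg <- reg[!taken[reg]]
    if (!length(reg)) next
    taken[reg] <- TRUE
    regions[[length(regions) + 1L]] <- reg
    rows[[length(rows) + 1L]] <- data.frame(x = x0 - 1L, y = y0 - 1L,
                                            peak = w[y0, x0],
                                            size = length(reg))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), peak = numeric(0), size = integer(0))
  structure(list(table = tab, regions = regions, bgsub = w,
                 noise_sd = noise_sd, control = control),
            class = "puncta")
}

#' Register a post-bleach image to its pre-bleach frame
#'
#' Global translational registration by FFT cross-correlation, then a
#' per-punctum residual displacement check: puncta whose local maximum
#' in the shifted post frame sits more than `moved_threshold` pixels
#' from its pre-bleach position are flagged as moved.
#'
#' @param pre,post Numeric matrices of identical shape.
#' @param puncta Optional [detect_puncta()] result from the pre frame.
#' @param control A [fret_control()] list.
#' @return List with `shift` (`(dx, dy)`, the content displacement of
#'   `post` relative to `pre`), `moved` (logical per punctum),
#'   `residual` (pixels per punctum).
#' @export
register_pre_post <- function(pre, post, puncta = NULL, control = fret_control()) {
  stopifnot(is.matrix(pre), is.matrix(post), all(dim(pre) == dim(post)))
  ny <- nrow(pre); nx <- ncol(pre)
  a <- pre - mean(pre); b <- post - mean(post)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  if (max(cc) - mean(cc) <= 1e-9 * max(abs(cc), 1e-300)) {
    warning("correlation peak ambiguous (flat images); assuming zero shift")
    shift <- c(0, 0)
  } else {
    pk <- which.max(cc)
    dy <- (pk - 1L) %% ny; dx <- (pk - 1L) %/% ny
    if (dy > ny / 2) dy <- dy - ny
    if (dx > nx / 2) dx <- dx - nx
    shift <- c(dx, dy)
  }
  moved <- logical(0); residual <- numeric(0)
  if (!is.null(puncta) && nrow(puncta$table) > 0) {
    wpost <- detect_puncta(post, control)$bgsub
    win <- max(3L, ceiling(control$moved_threshold) + 3L)
    residual <- vapply(seq_len(nrow(puncta$table)), function(i) {
      ex <- puncta$table$x[i] + shift[1]; ey <- puncta$table$y[i] + shift[2]
      ys <- max(1L, round(ey) + 1L - win):min(ny, round(ey) + 1L + win)
      xs <- max(1L, round(ex) + 1L - win):min(nx, round(ex) + 1L + win)
      sub <- wpost[ys, xs, drop = FALSE]
      pk <- which.max(sub)
      py <- ys[(pk - 1L) %% nrow(sub) + 1L] - 1L
      px <- xs[(pk - 1L) %/% nrow(sub) + 1L] - 1L
      sqrt((px - ex)^2 + (py - ey)^2)
    }, 0)
    moved <- residual > control$moved_threshold
  }
  list(shift = shift, moved = moved, residual = residual)
}

# translate an image by a (possibly fractional) shift, bilinear
.translate_image <- function(img, dx, dy) {
  ny <- nrow(img); nx <- ncol(img)
  xs <- rep(0:(nx - 1), each = ny) + dx
  ys <- rep(0:(ny - 1), times = nx) + dy
  matrix(interp2(img, xs, ys), ny, nx)
}

#' Measure donor puncta before and after acceptor bleaching
#'
#' Full measurement pipeline for one cell sample: detect puncta in the
#' pre-bleach donor image, register the post-bleach frame, and integrate
#' background-subtracted donor intensity over each grown region in both
#' frames. Moved puncta are flagged for exclusion.
#'
#' @param pre,post Donor-channel matrices.
#' @param control A [fret_control()] list.
#' @return Data frame with one row per punctum: `x`, `y`, `pre`, `post`
#'   (background-subtracted integrated counts, clamped at 0), `moved`.
#' @export
fret_measurements <- function(pre, post, control = fret_control()) {
  det <- detect_puncta(pre, control)
  reg <- register_pre_post(pre, post, det, control)
  # undo the global shift so pre-frame regions apply to the post frame
  post_aligned <- .translate_image(post, reg$shift[1], reg$shift[2])
  post_bg <- .local_background(post_aligned, control$bg_radius,
                               control$bg_percentile)
  pre_bg <- .local_background(pre, control$bg_radius, control$bg_percentile)
  pre_w <- pre - pre_bg
  post_w <- post_aligned - post_bg
  n <- nrow(det$table)
  pre_i <- post_i <- numeric(n)
  for (i in seq_len(n)) {
    reg_i <- det$regions[[i]]
    pre_i[i] <- max(sum(pre_w[reg_i]), 0)
    post_i[i] <- max(sum(post_w[reg_i]), 0)
  }
  data.frame(x = det$table$x, y = det$table$y,
             pre = pre_i, post = post_i,
             moved = if (n) reg$moved else logical(0))
}

#' Relative acceptor-photobleaching FRET efficiency
#'
#' Per punctum the raw efficiency is `(post - pre) / post` (the donor
#' dequenching convention). The relative efficiency is the mean raw
#' efficiency of the donor+acceptor pair sample minus that of the
#' donor-only control; its error is the quadrature sum of the two group
#' SEMs, and significance is a two-sided t-test of pair versus control.
#' Moved puncta and puncta with non-positive post intensity are excluded
#' (the latter with a message).
#'
#' @param pairs,controls Data frames as from [fret_measurements()]
#'   (columns `pre`, `post`, optional `moved`) for donor+acceptor and
#'   donor-only samples.
#' @return An object of class `"fret_result"`: `relative_efficiency`,
#'   `se`, `n_pair`, `n_control`, `mean_pair`, `mean_control`,
#'   `p_value`, `t_test`, and the per-punctum efficiency vectors.
#' @export
fret_efficiency <- function(pairs, controls) {
  raw_e <- function(df, label) {
    if (is.null(df$moved)) df$moved <- FALSE
    df <- df[!df$moved, , drop = FALSE]
    bad <- df$post <= 0
    if (any(bad)) {
      message(sum(bad), " ", label, " punctum/puncta excluded (post-bleach intensity <= 0)")
      df <- df[!bad, , drop = FALSE]
    }
    if (nrow(df) < 1L) stop("no usable puncta in ", label, " sample")
    (df$post - df$pre) / df$post
  }
  ep <- raw_e(pairs, "pair")
  ec <- raw_e(controls, "control")
  rel <- mean(ep) - mean(ec)
  se <- sqrt(stats::var(ep) / length(ep) + stats::var(ec) / length(ec))
  tt <- stats::t.test(ep, ec, alternative = "two.sided")
  structure(list(relative_efficiency = rel, se = se,
                 n_pair = length(ep), n_control = length(ec),
                 mean_pair = mean(ep), mean_control = mean(ec),
                 p_value = tt$p.value, t_test = tt,
                 raw_pair = ep, raw_control = ec),
            class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf(
    "relative FRET efficiency %.1f +/- %.1f%% (pair n = %d, control n = %d; p = %.3g)\n",
    100 * x$relative_efficiency, 100 * x$se, x$n_pair, x$n_control, x$p_value))
  invisible(x)
}
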