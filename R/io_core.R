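# Image volumes, on-disk stacks, particle seed annotations and config.

#' Construct a 3D image volume with physical voxel metadata
#'
#' The central image container: a real-valued 3D array indexed
#' `(z, y, x)` with voxel sizes in nanometers. Lateral sampling must be
#' isotropic (`dy == dx`). Coordinates throughout the package are
#' 0-based voxel-center pixel units.
#'
#' @param data Numeric 3D array, `(z, y, x)` order; finite, non-negative.
#' @param voxel_size Numeric length-3 `(dz, dy, dx)` in nm; all positive,
#'   `dy == dx`.
#' @param channel Channel name.
#' @return An object of class `"volume_image"` with fields `data`,
#'   `voxel_size`, `channel`.
#' @examples
#' v <- volume_image(array(0, c(8, 16, 16)), c(125, 40, 40), "YFP")
#' dim(v$data)
#' @export
volume_image <- function(data, voxel_size, channel = "unknown") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array ordered (z, y, x)")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be three positive values (dz, dy, dx) in nm")
  if (abs(voxel_size[2] - voxel_size[3]) > 1e-9 * voxel_size[2])
    stop("lateral sampling must be isotropic (dy == dx)")
  if (any(!is.finite(data))) stop("volume data must be finite")
  if (any(data < 0)) stop("volume data must be non-negative")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 channel = as.character(channel)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_image '%s': %d x %d x %d (z, y, x), voxel (%.4g, %.4g, %.4g) nm\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], total %.6g\n",
              min(x$data), max(x$data), sum(x$data)))
  invisible(x)
}

# The tiff package stores 32-bit samples quantized to k/(2^32 - 1); the
# integer k survives the write/read cycle exactly up to 24 bits, so a
# power-of-two quantization step per channel giving 24-bit dynamic range
# makes the roundtrip exact for integer-valued (photon-count) data.
.TIFF_DENOM <- 2^32 - 1

.quant_step <- function(max_val) {
  if (max_val <= 0) return(1)
  2^max(ceiling(log2(max_val)) - 24, -1022)
}

.sidecar_path <- function(path) paste0(path, ".meta.json")

#' Write image volumes to a multi-page TIFF stack
#'
#' Pages are ordered z-major with channels interleaved (channel fastest).
#' Samples are stored as 32-bit TIFF with a per-channel power-of-two
#' quantization step giving 24-bit dynamic range; integer-valued data
#' (photon counts up to 2^24) survive the roundtrip bit-exactly,
#' arbitrary reals are stored with relative quantization below 2^-24.
#' Voxel size, channel names, layout and quantization steps are recorded
#' in a JSON sidecar `<path>.meta.json`.
#'
#' @param volumes A [volume_image()] or list of them, all the same shape.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(volumes, path) {
  if (inherits(volumes, "volume_image")) volumes <- list(volumes)
  stopifnot(length(volumes) >= 1L)
  lapply(volumes, function(v) stopifnot(inherits(v, "volume_image")))
  dims <- lapply(volumes, function(v) dim(v$data))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all volumes must have identical shapes")
  vs <- volumes[[1]]$voxel_size
  for (v in volumes) {
    if (max(abs(v$voxel_size - vs)) > 1e-9) stop("all volumes must share voxel_size")
  }
  d <- dims[[1]]
  steps <- vapply(volumes, function(v) .quant_step(max(v$data)), 0)
  pages <- vector("list", d[1] * length(volumes))
  k <- 1L
  for (z in seq_len(d[1])) {
    for (ci in seq_along(volumes)) {
      sl <- volumes[[ci]]$data[z, , ]
      pages[[k]] <- round(sl / steps[ci]) / .TIFF_DENOM
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "deflate", reduce = FALSE)
  meta <- list(axes = "zyx, channel-interleaved",
               n_z = d[1], n_y = d[2], n_x = d[3],
               voxel_size_nm = vs,
               channels = vapply(volumes, function(v) v$channel, ""),
               quant_step = steps)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack into image volumes
#'
#' Reads stacks written by [write_stack()] (using the JSON sidecar for
#' voxel size, channel names and layout), or plain single-channel TIFF
#' z-stacks from other sources when `voxel_size` and layout are supplied
#' via `config`.
#'
#' @param path TIFF file path.
#' @param channel_map Optional named integer vector mapping channel names
#'   to 1-based channel indices; defaults to the channels recorded in the
#'   sidecar. All requested channels must exist.
#' @param config Optional list overriding metadata absent from the file:
#'   `voxel_size` (length-3 nm), `n_channels` (default 1), `channels`
#'   (names).
#' @return A list of [volume_image()], one per requested channel.
#' @export
read_stack <- function(path, channel_map = NULL, config = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(.sidecar_path(path))) {
    meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  }
  voxel <- config$voxel_size %||% meta$voxel_size_nm
  if (is.null(voxel))
    stop("no voxel-size metadata found for ", path,
         " and no config override given; supply config$voxel_size = c(dz, dy, dx) nm")
  channels <- meta$channels %||% config$channels %||%
    paste0("ch", seq_len(config$n_channels %||% 1L))
  nc <- length(channels)
  if (length(pages) %% nc != 0L)
    stop("page count ", length(pages), " is not a multiple of channel count ", nc)
  nz <- length(pages) %/% nc
  steps <- meta$quant_step %||% rep(NA_real_, nc)
  if (is.null(channel_map)) {
    channel_map <- stats::setNames(seq_len(nc), channels)
  }
  bad <- union(setdiff(names(channel_map), channels),
               names(channel_map)[channel_map < 1 | channel_map > nc])
  if (length(bad))
    stop("requested channel(s) ", paste(bad, collapse = ", "),
         " not in stack; available channels: ", paste(channels, collapse = ", "))
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  out <- vector("list", length(channel_map))
  for (i in seq_along(channel_map)) {
    ci <- channel_map[i]
    arr <- array(0, dim = c(nz, ny, nx))
    for (z in seq_len(nz)) {
      sl <- pages[[(z - 1L) * nc + ci]]
      if (!is.na(steps[ci])) sl <- round(sl * .TIFF_DENOM) * steps[ci]
      arr[z, , ] <- sl
    }
    arr[arr < 0] <- 0
    out[[i]] <- volume_image(arr, voxel, names(channel_map)[i])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a particle seed annotation
#'
#' Four approximate click points at the 0, 90, 180 and 270 degree ring
#' crossings, in 0-based pixel coordinates, plus an optional z slice hint.
#'
#' @param particle_id Identifier.
#' @param channel Channel the seeds refer to.
#' @param points 4x2 matrix of `(x, y)` pixel coordinates, rows ordered
#'   0, 90, 180, 270 degrees.
#' @param z_hint Optional 0-based slice index.
#' @return An object of class `"particle_seed"`.
#' @export
particle_seed <- function(particle_id, channel, points, z_hint = NA_real_) {
  points <- as.matrix(points)
  if (!all(dim(points) == c(4L, 2L))) stop("seed points must be a 4x2 (x, y) matrix")
  if (any(!is.finite(points))) stop("seed points must be finite")
  colnames(points) <- c("x", "y")
  structure(list(particle_id = as.character(particle_id),
                 channel = as.character(channel),
                 points = points, z_hint = z_hint),
            class = "particle_seed")
}

#' Read particle seeds from CSV
#'
#' One row per particle with columns `particle_id`, `channel`,
#' `x0,y0,x90,y90,x180,y180,x270,y270` and optional `z_hint` — a
#' scriptable stand-in for interactive point placement.
#'
#' @param path CSV file path.
#' @return List of [particle_seed()].
#' @export
read_seeds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("particle_id", "channel", "x0", "y0", "x90", "y90",
            "x180", "y180", "x270", "y270")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("seed CSV missing column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    pts <- matrix(as.numeric(df[i, c("x0", "y0", "x90", "y90",
                                     "x180", "y180", "x270", "y270")]),
                  ncol = 2, byrow = TRUE)
    particle_seed(df$particle_id[i], df$channel[i], pts,
                  if ("z_hint" %in% names(df)) df$z_hint[i] else NA_real_)
  })
}

#' Write particle seeds to CSV
#' @param seeds List of [particle_seed()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_seeds <- function(seeds, path) {
  if (inherits(seeds, "particle_seed")) seeds <- list(seeds)
  rows <- lapply(seeds, function(s) {
    data.frame(particle_id = s$particle_id, channel = s$channel,
               x0 = s$points[1, 1], y0 = s$points[1, 2],
               x90 = s$points[2, 1], y90 = s$points[2, 2],
               x180 = s$points[3, 1], y180 = s$points[3, 2],
               x270 = s$points[4, 1], y270 = s$points[4, 2],
               z_hint = s$z_hint)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Validate seeds against a volume
#' @noRd
check_seed_bounds <- function(seed, volume) {
  d <- dim(volume$data)
  p <- seed$points
  if (any(p[, 1] < 0 | p[, 1] > d[3] - 1 | p[, 2] < 0 | p[, 2] > d[2] - 1))
    stop("seed points for particle '", seed$particle_id, "' fall outside image bounds")
  invisible(TRUE)
}

#' Read a YAML analysis configuration
#'
#' Configuration carries voxel sizes, channel maps and fit settings for
#' the command-line interface; any subset may be present.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  yaml::read_yaml(path)
}
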