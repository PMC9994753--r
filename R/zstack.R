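#' Construct a z-stack volume
#'
#' A `zstack` is the universal volume container of the package: a 4D numeric
#' array with axis order `(z, y, x, c)` — TIFF pages are z-slices — together
#' with a declared value range and optional physical voxel size.
#'
#' @param data 4D numeric array, axis order `(z, y, x, c)`, channel axis
#'   last with 1 (grayscale) or 3 (RGB) channels.
#' @param value_range one of `"raw"` (arbitrary finite values), `"unit"`
#'   (values in `[0, 1]`) or `"unit_signed"` (values in `[-1, 1]`, the GAN
#'   convention).
#' @param voxel_size numeric length-3 `(z, y, x)` physical voxel size in
#'   micrometres. Defaults to a 0.5 µm confocal step in z and 0.1 µm
#'   laterally; metadata only, never used in computation.
#' @return an object of class `zstack`.
#' @export
zstack <- function(data, value_range = c("raw", "unit", "unit_signed"),
                   voxel_size = c(0.5, 0.1, 0.1)) {
  value_range <- match.arg(value_range)
  obj <- structure(list(data = data, value_range = value_range,
                        voxel_size = voxel_size),
                   class = "zstack")
  validate_zstack(obj)
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<zstack> %d x %d x %d x %d (z,y,x,c), range=%s [%.3g, %.3g]\n",
              d[1], d[2], d[3], d[4], x$value_range,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Validate a z-stack
#'
#' Enforces the axis-order contract `(z, y, x, c)`: rank exactly 4, channel
#' count 1 or 3, all values finite, and values inside the declared range
#' when the range is not `"raw"`.
#'
#' @param x a `zstack`.
#' @return `x`, invisibly-checked.
#' @export
validate_zstack <- function(x) {
  if (!inherits(x, "zstack")) stop("not a zstack object")
  d <- dim(x$data)
  if (is.null(d) || length(d) != 4L)
    stop("zstack data must be a rank-4 array (z, y, x, c)")
  if (!d[4] %in% c(1L, 3L))
    stop("channel axis must be last with 1 or 3 channels, got ", d[4])
  if (!all(is.finite(x$data)))
    stop("zstack contains non-finite values")
  rng <- range(x$data)
  if (x$value_range == "unit" && (rng[1] < 0 || rng[2] > 1))
    stop("values outside declared unit range [0, 1]")
  if (x$value_range == "unit_signed" && (rng[1] < -1 || rng[2] > 1))
    stop("values outside declared unit_signed range [-1, 1]")
  x
}

#' Rescale a volume to the signed unit range [-1, 1]
#'
#' Affine map of the volume's global minimum and maximum onto `[-1, 1]`,
#' the accepted input/output convention for GAN generators with a tanh
#' output.  A constant volume maps to all `-1` (background) by convention,
#' so a blank stack looks like background to the networks.  Normalisation
#' is per-volume; no dataset-level statistics are used.
#'
#' @param volume a `zstack` with `value_range` `"raw"` or `"unit"`. A
#'   `unit_signed` volume is returned unchanged (idempotence).
#' @return a `zstack` with `value_range = "unit_signed"`.
#' @export
normalize_to_signed_unit <- function(volume) {
  validate_zstack(volume)
  if (volume$value_range == "unit_signed") return(volume)
  lo <- min(volume$data)
  hi <- max(volume$data)
  if (hi - lo <= 0) {
    data <- array(-1, dim(volume$data))
  } else {
    data <- 2 * (volume$data - lo) / (hi - lo) - 1
    # guard rounding at the extremes
    data[data > 1] <- 1
    data[data < -1] <- -1
  }
  zstack(data, "unit_signed", volume$voxel_size)
}

#' Triplicate a single-channel volume to three channels
#'
#' The networks consume 3-channel volumes; single-channel TMRE stacks are
#' triplicated upstream.  Values are unchanged.
#'
#' @param volume a `zstack` with exactly one channel.
#' @return a `zstack` with `c = 3`, all three channels equal.
#' @export
replicate_channels <- function(volume) {
  validate_zstack(volume)
  d <- dim(volume$data)
  if (d[4] != 1L) stop("replicate_channels requires a single-channel volume")
  data <- array(volume$data, c(d[1:3], 3L))
  zstack(data, volume$value_range, volume$voxel_size)
}
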