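#' Multi-channel calibrated image stack
#'
#' An `image_stack` bundles a 4D voxel grid with its physical calibration.
#' The logical axis order is (channel, z, y, x); in memory the voxels are held
#' as an R array of dimension `c(y, x, z, channel)` so that a single plane
#' `v[, , z, c]` is an ordinary `y x x` matrix (column-major R storage mirrors
#' the row-major (channel, z, y, x) layout used by most TIFF tooling).
#' Use [get_plane()] / [get_channel()] rather than indexing directly.
#'
#' @param voxels numeric array, either `y x x` (single plane, single channel),
#'   `y x x x z`, or `y x x x z x channel`.
#' @param pixel_size_um in-plane pixel size in micrometres (isotropic in x/y).
#' @param z_step_um spacing between z-planes in micrometres.
#' @param channel_names character vector naming the channels, e.g.
#'   `c("MBP", "NFH")`; must be unique and match the channel count.
#' @param bit_depth nominal camera bit depth; integer intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @return An object of class `image_stack`.
#' @examples
#' s <- image_stack(array(0, c(8, 8, 2, 1)), 0.25, 1, "MBP")
#' dim_stack(s)
#' @export
image_stack <- function(voxels, pixel_size_um, z_step_um, channel_names,
                        bit_depth = 16L) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L, 1L)
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    stop("voxels must have 2 to 4 dimensions (y, x[, z[, channel]])")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  if (!is.numeric(z_step_um) || z_step_um <= 0)
    stop("z_step_um must be > 0")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(voxels)[4L])
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", dim(voxels)[4L], ")")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (any(voxels < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  vmax <- 2^bit_depth - 1
  if (max(voxels, na.rm = TRUE) > vmax)
    stop("intensities exceed 2^bit_depth - 1 = ", vmax)
  structure(
    list(voxels = voxels, pixel_size_um = pixel_size_um,
         z_step_um = z_step_um, channel_names = channel_names,
         bit_depth = as.integer(bit_depth)),
    class = "image_stack")
}

#' @describeIn image_stack Stack dimensions as a named vector
#'   (channel, z, y, x).
#' @param x,stack an `image_stack`.
#' @export
dim_stack <- function(stack) {
  d <- dim(stack$voxels)
  c(channel = d[4L], z = d[3L], y = d[1L], x = d[2L])
}

#' @describeIn image_stack Extract one z-plane of one channel as a matrix.
#' @param channel channel name or index.
#' @param z z-plane index (1-based).
#' @export
get_plane <- function(stack, channel, z) {
  ci <- resolve_channel(stack, channel)
  stack$voxels[, , z, ci]
}

#' @describeIn image_stack Extract a whole channel as a `y x x x z` array.
#' @export
get_channel <- function(stack, channel) {
  ci <- resolve_channel(stack, channel)
  stack$voxels[, , , ci, drop = FALSE][, , , 1L]
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    ci <- match(channel, stack$channel_names)
    if (is.na(ci))
      stop("channel '", channel, "' not present; stack has: ",
           paste(stack$channel_names, collapse = ", "))
    ci
  } else {
    ci <- as.integer(channel)
    if (ci < 1L || ci > length(stack$channel_names))
      stop("channel index out of range")
    ci
  }
}

#' Voxel volume in cubic micrometres
#' @param stack an `image_stack`.
#' @export
voxel_volume_um3 <- function(stack) {
  stack$pixel_size_um^2 * stack$z_step_um
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim_stack(x)
  cat(sprintf(
    "image_stack: %d channel(s) [%s], %d z-plane(s), %d x %d px\n",
    d["channel"], paste(x$channel_names, collapse = ", "), d["z"],
    d["y"], d["x"]))
  cat(sprintf("  calibration: %.4g um/px, %.4g um z-step, %d-bit\n",
              x$pixel_size_um, x$z_step_um, x$bit_depth))
  invisible(x)
}
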