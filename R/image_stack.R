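# ImageStack: a single-cell multi-channel 3-D intensity array with voxel
# geometry and channel-role metadata. Voxels are stored as a 4-D numeric
# array with dim (n_z, n_y, n_x, n_channels); slice z = 1 is ALWAYS the
# slice nearest the coverslip.

#' Construct an ImageStack
#'
#' Bundles a multi-channel 3-D intensity array with its voxel sizes and a map
#' from channel roles (`er`, `tubulin`, `actin`, ...) to channel indices.
#' By convention slice index 1 is the slice nearest the coverslip; readers
#' are responsible for flipping source data that is stored top-first.
#'
#' @param voxels numeric array, dim `(n_z, n_y, n_x)` or
#'   `(n_z, n_y, n_x, n_channels)`; all intensities must be non-negative
#' @param voxel_size numeric length-3 vector `(dz, dy, dx)` in micrometres
#' @param channel_roles named integer vector mapping role names to channel
#'   indices, e.g. `c(er = 1, tubulin = 2, actin = 3)`
#' @return an object of class `ImageStack`
#' @export
image_stack <- function(voxels, voxel_size, channel_roles = c(other = 1L)) {
  if (!is.array(voxels) || !(length(dim(voxels)) %in% c(3L, 4L))) {
    stop("`voxels` must be a 3-D or 4-D array")
  }
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  storage.mode(voxels) <- "double"
  if (anyNA(voxels) || min(voxels) < 0) {
    stop("intensities must be finite and non-negative")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 positive numbers (dz, dy, dx) in micrometres")
  }
  names(voxel_size) <- c("dz", "dy", "dx")
  n_ch <- dim(voxels)[4L]
  idx <- as.integer(channel_roles)
  if (is.null(names(channel_roles)) || any(!nzchar(names(channel_roles)))) {
    stop("`channel_roles` must be a named vector of channel indices")
  }
  if (anyNA(idx) || any(idx < 1L) || any(idx > n_ch)) {
    stop(sprintf("channel role index out of range 1..%d", n_ch))
  }
  if (anyDuplicated(idx)) stop("channel role indices must be distinct")
  names(idx) <- names(channel_roles)
  structure(
    list(voxels = voxels, voxel_size = voxel_size, channel_roles = idx),
    class = "ImageStack"
  )
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "ImageStack: %d slice(s) x %d x %d px, %d channel(s)\n", d[1], d[2], d[3], d[4]
  ))
  cat(sprintf(
    "  voxel size (um): dz=%g dy=%g dx=%g\n",
    x$voxel_size["dz"], x$voxel_size["dy"], x$voxel_size["dx"]
  ))
  cat(
    "  roles:",
    paste(sprintf("%s=%d", names(x$channel_roles), x$channel_roles), collapse = " "),
    "\n"
  )
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$voxels)

#' Extract one channel of an ImageStack as a 3-D array
#'
#' @param stack an `ImageStack`
#' @param role a role name present in `stack$channel_roles`
#' @return numeric array with dim `(n_z, n_y, n_x)`
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!role %in% names(stack$channel_roles)) {
    stop(sprintf(
      "channel role '%s' not present (available: %s)",
      role, paste(names(stack$channel_roles), collapse = ", ")
    ))
  }
  ch <- stack$channel_roles[[role]]
  out <- stack$voxels[, , , ch]
  dim(out) <- dim(stack$voxels)[1:3]
  out
}

#' Voxel volume in cubic micrometres
#' @param stack an `ImageStack`
#' @return scalar, `dz * dy * dx`
#' @export
voxel_volume <- function(stack) {
  prod(stack$voxel_size)
}

#' Reverse the slice order of a stack
#'
#' Used when the source file stores the coverslip-distal slice first; after
#' flipping, slice 1 is the coverslip-proximal slice.
#'
#' @param stack an `ImageStack`
#' @return the stack with z order reversed
#' @export
flip_z <- function(stack) {
  nz <- dim(stack$voxels)[1L]
  stack$voxels <- stack$voxels[nz:1, , , , drop = FALSE]
  stack
}
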