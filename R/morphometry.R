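# ER morphometry: area at the synapse plane, actin spreading area, their
# ratio, and 3-D volume by connected components (the "3D Objects Counter"
# style measurement).

#' ER area at the synapse plane
#'
#' Otsu-thresholds the ER channel *within the cell mask* over the first
#' `ceiling(synapse_fraction * n_z)` slices, projects the thresholded voxels
#' to XY (binary OR over the slab) and reports pixel count times pixel area.
#' The threshold is computed on in-mask intensities, so the measure is
#' invariant to a global intensity gain.
#'
#' @param stack an [image_stack()]
#' @param seg a `CellSegmentation`
#' @param channel_role channel to measure (default "er")
#' @param synapse_fraction fraction of slices defining the synapse slab
#' @return area in square micrometres (0, with a warning, if no ER signal
#'   passes the threshold at the synapse - legitimate for unspread cells)
#' @export
er_area_at_synapse <- function(stack, seg, channel_role = "er",
                               synapse_fraction = 0.10) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$voxels)
  n_syn <- n_synapse_slices(d[1], synapse_fraction)
  ch <- get_channel(stack, channel_role)
  vals <- ch[seg$cell_mask]
  if (length(vals) == 0) stop("cell mask is empty")
  if (max(vals) <= min(vals)) {
    warning("no contrast in channel: synapse-plane area is 0")
    return(0)
  }
  thr <- otsu_threshold(vals)
  fg <- (ch > thr) & seg$cell_mask
  fg[-seq_len(n_syn), , ] <- FALSE
  proj <- apply(fg, c(2, 3), any)
  n_px <- sum(proj)
  if (n_px == 0) {
    warning("no signal above threshold at the synapse plane: area is 0")
    return(0)
  }
  n_px * stack$voxel_size[["dy"]] * stack$voxel_size[["dx"]]
}

#' Footprint area of a 2-D mask in square micrometres
#'
#' @param footprint logical matrix (e.g. from [actin_footprint()])
#' @param voxel_size `(dz, dy, dx)` in micrometres
#' @return area in square micrometres
#' @export
footprint_area_um2 <- function(footprint, voxel_size) {
  sum(footprint) * voxel_size[["dy"]] * voxel_size[["dx"]]
}

#' ER-to-actin spreading ratio
#'
#' ER area at the synapse plane divided by the actin-delimited spreading
#' area of the cell.
#'
#' @param er_area_um2 ER area at the synapse plane, square micrometres
#' @param actin_area_um2 actin footprint area, square micrometres
#' @return dimensionless ratio
#' @export
spreading_ratio <- function(er_area_um2, actin_area_um2) {
  stopifnot(er_area_um2 >= 0)
  if (actin_area_um2 <= 0) stop("actin area must be positive")
  er_area_um2 / actin_area_um2
}

#' ER volume by 3-D connected components
#'
#' Otsu-thresholds the channel within the cell mask, labels 3-D connected
#' components with 26-connectivity (the Fiji 3D Objects Counter convention),
#' discards components smaller than `min_object_voxels`, and reports the
#' summed volume of the retained components.
#'
#' @param stack an [image_stack()]
#' @param seg a `CellSegmentation`
#' @param channel_role channel to measure (default "er")
#' @param min_object_voxels smallest component retained, in voxels (speckle
#'   rejection; default 5)
#' @return a `MorphometryResult` list: `er_volume_um3`, `n_objects`,
#'   `object_voxels`, `min_object_voxels`
#' @export
er_volume <- function(stack, seg, channel_role = "er", min_object_voxels = 5L) {
  stopifnot(inherits(stack, "ImageStack"), min_object_voxels >= 1L)
  ch <- get_channel(stack, channel_role)
  vals <- ch[seg$cell_mask]
  if (length(vals) == 0) stop("cell mask is empty")
  if (max(vals) <= min(vals)) {
    return(structure(
      list(er_volume_um3 = 0, n_objects = 0L, object_voxels = integer(0),
           min_object_voxels = as.integer(min_object_voxels)),
      class = "MorphometryResult"
    ))
  }
  thr <- otsu_threshold(vals)
  fg <- (ch > thr) & seg$cell_mask
  lab <- label_components(fg, connectivity = 26L)
  n <- max(lab)
  sizes <- if (n > 0L) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  kept <- sizes[sizes >= min_object_voxels]
  structure(
    list(
      er_volume_um3 = sum(kept) * voxel_volume(stack),
      n_objects = length(kept),
      object_voxels = kept,
      min_object_voxels = as.integer(min_object_voxels)
    ),
    class = "MorphometryResult"
  )
}

#' @export
print.MorphometryResult <- function(x, ...) {
  cat(sprintf(
    "MorphometryResult: %d object(s) >= %d voxels, volume %.3f um^3\n",
    x$n_objects, x$min_object_voxels, x$er_volume_um3
  ))
  invisible(x)
}
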