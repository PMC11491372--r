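# Cell mask, actin spreading footprint, and MTOC detection. All downstream
# quantification consumes the CellSegmentation produced here.

#' Segment the single cell in a stack
#'
#' Global Otsu threshold on the Gaussian-smoothed designated channel, box
#' closing, 3-D hole filling, then retention of the largest connected
#' component. The original macro-based analysis relied on a manually drawn
#' cell ROI; automatic segmentation keeps the pipeline unattended, and a
#' pre-computed mask can be supplied via `mask` to reproduce hand-drawn ROIs
#' exactly.
#'
#' @param stack an [image_stack()]
#' @param channel_role channel to segment on (default "actin", the membrane-
#'   proximal stain)
#' @param smooth_sigma pre-threshold smoothing `(sigma_z, sigma_y, sigma_x)`
#'   in voxels; default 0.5 slice in Z, 1 px in XY
#' @param mask optional user-supplied logical array overriding segmentation
#' @return a `CellSegmentation` list with `cell_mask`, `provenance`
#' @export
segment_cell <- function(stack, channel_role = "actin",
                         smooth_sigma = c(0.5, 1, 1), mask = NULL) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!is.null(mask)) {
    stopifnot(is.array(mask), identical(dim(mask), dim(stack$voxels)[1:3]))
    lc <- largest_component(mask != 0)
    seg <- list(cell_mask = lc$mask,
                provenance = list(method = "user mask"))
    class(seg) <- "CellSegmentation"
    return(seg)
  }
  ch <- get_channel(stack, channel_role)
  if (max(ch) <= min(ch)) stop("empty mask: channel is flat or blank")
  sm <- gauss_smooth(ch, smooth_sigma)
  thr <- otsu_threshold(as.numeric(sm))
  m <- sm > thr
  if (!any(m)) stop("empty mask after thresholding")
  m <- binary_closing(m, radius = c(1L, 2L, 2L))
  m <- fill_holes(m)
  lc <- largest_component(m, connectivity = 26L)
  if (lc$n_components > 1L) {
    warning(sprintf(
      "%d components after thresholding; keeping the largest", lc$n_components
    ))
  }
  m <- lc$mask
  if (mean(m) > 0.5) stop("threshold failure: mask covers >50% of the stack")
  seg <- list(
    cell_mask = m,
    provenance = list(method = "otsu", channel = channel_role,
                      smooth_sigma = smooth_sigma, threshold = thr)
  )
  class(seg) <- "CellSegmentation"
  seg
}

#' @export
print.CellSegmentation <- function(x, ...) {
  cat(sprintf("CellSegmentation: %d voxels in cell mask (%s)\n",
              sum(x$cell_mask), x$provenance$method))
  if (!is.null(x$mtoc_position)) {
    cat("  MTOC (z,y,x):", paste(x$mtoc_position, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Actin-delimited spreading footprint at the synapse plane
#'
#' Thresholds the actin channel within the bottom `n_synapse_slices` slices,
#' projects to XY, fills holes (cortical actin is a ring; the footprint is its
#' filled interior) and keeps the largest component. The result is clipped to
#' the XY projection of the cell mask.
#'
#' @param stack an [image_stack()]
#' @param seg a `CellSegmentation`
#' @param n_slices number of coverslip-proximal slices to use; default the
#'   synapse slab `ceiling(0.1 * n_z)`
#' @return 2-D logical footprint mask `(n_y, n_x)`
#' @export
actin_footprint <- function(stack, seg, n_slices = NULL) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$voxels)
  if (is.null(n_slices)) n_slices <- n_synapse_slices(d[1])
  stopifnot(n_slices >= 1, n_slices <= d[1])
  act <- get_channel(stack, "actin")
  slab <- act[seq_len(n_slices), , , drop = FALSE]
  thr <- otsu_threshold(as.numeric(slab))
  proj <- apply(slab > thr, c(2, 3), any)
  proj <- fill_holes_2d(proj)
  lc <- largest_component(as_3d(proj))
  fp <- as_2d(lc$mask)
  cell_proj <- apply(seg$cell_mask, c(2, 3), any)
  fp <- fp & cell_proj
  if (!any(fp)) stop("empty actin footprint")
  fp
}

#' Detect the MTOC as the brightest tubulin focus
#'
#' Position of the maximum of the Gaussian-smoothed tubulin channel restricted
#' to the cell mask. Ties are broken deterministically by the lowest `(z, y,
#' x)` index (column-major scan order over `(z, y, x)` guarantees this).
#'
#' @param stack an [image_stack()]
#' @param seg a `CellSegmentation`
#' @param smooth_sigma smoothing sigmas in voxels
#' @return named integer vector `(z, y, x)`, 1-based voxel coordinate
#' @export
detect_mtoc <- function(stack, seg, smooth_sigma = c(1, 1.5, 1.5)) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!"tubulin" %in% names(stack$channel_roles)) {
    stop("tubulin channel absent")
  }
  if (!any(seg$cell_mask)) stop("cell mask is empty")
  tub <- gauss_smooth(get_channel(stack, "tubulin"), smooth_sigma)
  vals <- tub[seg$cell_mask]
  if (max(vals) - min(vals) < 1e-9 * max(abs(vals), 1)) {
    warning("tubulin channel has no contrast inside the mask")
  }
  tub[!seg$cell_mask] <- -Inf
  # which.max on the flat array returns the first (lowest z, then y, then x)
  idx <- which.max(tub)
  d <- dim(tub)
  z <- (idx - 1) %% d[1] + 1
  y <- ((idx - 1) %/% d[1]) %% d[2] + 1
  x <- (idx - 1) %/% (d[1] * d[2]) + 1
  c(z = as.integer(z), y = as.integer(y), x = as.integer(x))
}

#' Run the full segmentation stage for one stack
#'
#' Cell mask, actin footprint (when an actin channel is present), MTOC (when
#' a tubulin channel is present), and the optional bead annotation.
#'
#' @param stack an [image_stack()]
#' @param channel_role channel used for the cell mask
#' @param bead_position optional `(z, y, x)` voxel coordinate of the bead
#'   (beads are unlabeled latex in the experiments and are annotated, not
#'   detected)
#' @return a `CellSegmentation` with `cell_mask`, `footprint_mask`,
#'   `mtoc_position`, `bead_position`
#' @export
segment_all <- function(stack, channel_role = "actin", bead_position = NULL) {
  seg <- segment_cell(stack, channel_role)
  # bead conjugates have no coverslip, so no spreading footprint
  if ("actin" %in% names(stack$channel_roles) && is.null(bead_position)) {
    seg$footprint_mask <- actin_footprint(stack, seg)
  }
  if ("tubulin" %in% names(stack$channel_roles)) {
    seg$mtoc_position <- detect_mtoc(stack, seg)
  }
  seg$bead_position <- bead_position
  seg
}
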