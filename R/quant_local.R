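# Local statistics: masked-ROI Pearson colocalization at the synapse plane,
# MTOC-proximal mean density, and line-scan intensity profiles.

#' Pearson colocalization at the synapse plane
#'
#' Plain (non-thresholded) Pearson correlation of two channels over the ROI
#' formed by the cell mask restricted to the first
#' `ceiling(synapse_fraction * n_z)` slices:
#' `r = sum((a - mean(a)) * (b - mean(b))) / sqrt(sum((a - mean(a))^2) *
#' sum((b - mean(b))^2))`.
#'
#' @param stack an [image_stack()]
#' @param seg a `CellSegmentation`
#' @param role_a,role_b channel roles to correlate (default er vs tubulin)
#' @param synapse_fraction fraction of slices defining the ROI slab
#' @return a `ColocResult` list: `pearson_r`, `n_voxels`, `roi_description`
#' @export
pearson_synapse <- function(stack, seg, role_a = "er", role_b = "tubulin",
                            synapse_fraction = 0.10) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$voxels)
  n_syn <- n_synapse_slices(d[1], synapse_fraction)
  roi <- seg$cell_mask
  roi[-seq_len(n_syn), , ] <- FALSE
  n <- sum(roi)
  if (n < 2) stop("ROI has fewer than 2 voxels")
  a <- get_channel(stack, role_a)[roi]
  b <- get_channel(stack, role_b)[roi]
  da <- a - mean(a)
  db <- b - mean(b)
  ssa <- sum(da^2); ssb <- sum(db^2)
  if (ssa == 0 || ssb == 0) {
    stop("zero variance in a channel within the ROI: Pearson r undefined")
  }
  structure(
    list(
      pearson_r = sum(da * db) / sqrt(ssa * ssb),
      n_voxels = n,
      roi_description = sprintf(
        "cell mask in first %d of %d slices (%s vs %s)", n_syn, d[1], role_a, role_b
      )
    ),
    class = "ColocResult"
  )
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("ColocResult: r = %.4f over %d voxels (%s)\n",
              x$pearson_r, x$n_voxels, x$roi_description))
  invisible(x)
}

#' Mean fluorescence in a circle around the MTOC
#'
#' Uses the Z-slice where the MTOC was found plus the slices directly before
#' and after it (an out-of-range neighbor at the stack boundary is dropped
#' with a warning). In each slice, pixels whose centers fall within the XY
#' circle of the given physical diameter centered at the MTOC are included;
#' the mean is taken over the pooled voxels of the (up to) three slices, not
#' intersected with the cell mask - the circle as drawn in the original Fiji
#' analysis. Preset diameters: 4 um for the A20 cell line, 2 um for primary
#' B cells.
#'
#' @param stack an [image_stack()]
#' @param seg a `CellSegmentation` with a known `mtoc_position`
#' @param channel_role channel whose density is measured (default "er")
#' @param diameter_um circle diameter in micrometres, or a preset name
#'   ("A20" = 4, "primary" = 2)
#' @return an `MtocDensityResult` list: `mean_fluorescence`, `diameter_um`,
#'   `slices_used`, `n_voxels`
#' @export
mtoc_density <- function(stack, seg, channel_role = "er", diameter_um = "A20") {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(diameter_um)) {
    diameter_um <- switch(diameter_um, A20 = 4, primary = 2,
                          stop(sprintf("unknown preset '%s'", diameter_um)))
  }
  stopifnot(diameter_um > 0)
  mtoc <- seg$mtoc_position
  if (is.null(mtoc)) stop("MTOC position unknown; run detect_mtoc first")
  d <- dim(stack$voxels)
  zs <- (mtoc[["z"]] - 1L):(mtoc[["z"]] + 1L)
  in_range <- zs >= 1L & zs <= d[1]
  if (!all(in_range)) {
    warning("MTOC at the stack boundary: using 2 slices instead of 3")
    zs <- zs[in_range]
  }
  vs <- stack$voxel_size
  dy <- (seq_len(d[2]) - mtoc[["y"]]) * vs[["dy"]]
  dx <- (seq_len(d[3]) - mtoc[["x"]]) * vs[["dx"]]
  disc <- outer(dy^2, dx^2, `+`) <= (diameter_um / 2)^2
  if (!any(disc)) stop("MTOC circle lies entirely outside the image")
  ch <- get_channel(stack, channel_role)
  vals <- unlist(lapply(zs, function(z) {
    sl <- ch[z, , ]
    dim(sl) <- d[2:3]
    sl[disc]
  }))
  structure(
    list(
      mean_fluorescence = mean(vals),
      diameter_um = diameter_um,
      slices_used = as.integer(zs),
      n_voxels = length(vals)
    ),
    class = "MtocDensityResult"
  )
}

#' @export
print.MtocDensityResult <- function(x, ...) {
  cat(sprintf(
    "MtocDensityResult: mean = %.3f in %.1f um circle, slices %s (%d voxels)\n",
    x$mean_fluorescence, x$diameter_um,
    paste(x$slices_used, collapse = ","), x$n_voxels
  ))
  invisible(x)
}

#' Line-scan intensity profile across a slice
#'
#' Samples the channel at unit-pixel spacing along the segment from `p0` to
#' `p1` in the given slice, using bilinear interpolation; the profile has
#' `floor(|p1 - p0|) + 1` samples.
#'
#' @param stack an [image_stack()]
#' @param channel_role channel to sample
#' @param p0,p1 numeric `(y, x)` endpoints in pixel coordinates (1-based)
#' @param z slice index
#' @return data.frame with `position_px`, `position_um`, `intensity`
#' @export
line_scan <- function(stack, channel_role, p0, p1, z) {
  stopifnot(inherits(stack, "ImageStack"), length(p0) == 2L, length(p1) == 2L)
  d <- dim(stack$voxels)
  stopifnot(z >= 1, z <= d[1])
  if (any(p0 < 1) || any(p1 < 1) || p0[1] > d[2] || p1[1] > d[2] ||
      p0[2] > d[3] || p1[2] > d[3]) {
    stop("line endpoints outside slice bounds")
  }
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length line")
  n <- floor(len) + 1L
  t <- if (n == 1L) 0 else seq(0, 1, length.out = n)
  ys <- p0[1] + t * (p1[1] - p0[1])
  xs <- p0[2] + t * (p1[2] - p0[2])
  sl <- get_channel(stack, channel_role)[z, , ]
  dim(sl) <- d[2:3]
  y0 <- pmin(pmax(floor(ys), 1L), d[2] - 1L)
  x0 <- pmin(pmax(floor(xs), 1L), d[3] - 1L)
  fy <- ys - y0
  fx <- xs - x0
  v <- sl[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    sl[cbind(y0 + 1L, x0)] * fy * (1 - fx) +
    sl[cbind(y0, x0 + 1L)] * (1 - fy) * fx +
    sl[cbind(y0 + 1L, x0 + 1L)] * fy * fx
  pos_px <- t * len
  data.frame(
    position_px = pos_px,
    position_um = pos_px * stack$voxel_size[["dy"]],
    intensity = v
  )
}
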