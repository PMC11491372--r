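# Low-level 3-D image operations backed by compiled code. Arrays are
# (z, y, x); masks are logical arrays of the same shape.

#' Separable Gaussian smoothing of a 3-D array
#'
#' @param arr numeric array `(n_z, n_y, n_x)`
#' @param sigma length-3 numeric `(sigma_z, sigma_y, sigma_x)` in voxels; a
#'   sigma of 0 disables smoothing along that axis
#' @return smoothed array of the same shape
#' @export
gauss_smooth <- function(arr, sigma) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L, length(sigma) == 3L)
  cpp_gauss3d(as.numeric(arr), as.integer(dim(arr)),
              sigma[1], sigma[2], sigma[3])
}

#' Otsu's threshold of intensities
#'
#' Computes the classical between-class-variance-maximising threshold on a
#' 256-bin histogram of the supplied intensities. Returns a value such that
#' `x > threshold` is foreground.
#'
#' @param x numeric vector of intensities (e.g. voxels inside a mask)
#' @param n_bins number of histogram bins
#' @return scalar threshold
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite intensities supplied")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  h <- tabulate(
    pmin(n_bins, 1L + as.integer((x - lo) / (hi - lo) * n_bins)),
    nbins = n_bins
  )
  p <- h / sum(h)
  midpoints <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  w0 <- cumsum(p)
  mu <- cumsum(p * midpoints)
  mu_total <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_total * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)
  lo + k / n_bins * (hi - lo)
}

#' Label connected components of a 3-D mask
#'
#' @param mask logical array `(n_z, n_y, n_x)`
#' @param connectivity 6 (faces) or 26 (faces, edges, corners)
#' @return integer array of labels, 0 = background, components numbered in
#'   scan order
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L,
            connectivity %in% c(6L, 26L))
  cpp_label3d(as.logical(mask), as.integer(dim(mask)), as.integer(connectivity))
}

#' Fill enclosed cavities of a 3-D mask
#'
#' Background voxels not 6-connected to the array border become foreground.
#'
#' @param mask logical array `(n_z, n_y, n_x)`
#' @return logical array with holes filled
#' @export
fill_holes <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  cpp_fill_holes3d(as.logical(mask), as.integer(dim(mask)))
}

#' Binary closing (dilation then erosion) with a box structuring element
#'
#' @param mask logical array `(n_z, n_y, n_x)`
#' @param radius per-axis radii `(rz, ry, rx)` in voxels
#' @return closed mask
#' @export
binary_closing <- function(mask, radius = c(1L, 2L, 2L)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, length(radius) == 3L)
  d <- as.integer(dim(mask))
  r <- as.integer(radius)
  m <- cpp_morph3d(as.logical(mask), d, r, TRUE)
  cpp_morph3d(m, d, r, FALSE)
}

#' Keep only the largest connected component of a mask
#'
#' @param mask logical array `(n_z, n_y, n_x)`
#' @param connectivity 6 or 26
#' @return list with `mask` (largest component) and `n_components` found
#' @export
largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0L) return(list(mask = mask & FALSE, n_components = 0L))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which.max(sizes)
  out <- lab == keep
  dim(out) <- dim(mask)
  list(mask = out, n_components = n)
}

# 2-D helpers reuse the 3-D kernels by adding a singleton z axis.
as_3d <- function(m2d) {
  array(m2d, dim = c(1L, dim(m2d)))
}
as_2d <- function(m3d) {
  out <- m3d[1, , ]
  dim(out) <- dim(m3d)[2:3]
  out
}

#' Fill holes of a 2-D mask
#' @param mask logical matrix
#' @return logical matrix
#' @export
fill_holes_2d <- function(mask) {
  # pad with all-TRUE slices so the z faces contribute no background seeds
  m3 <- array(TRUE, dim = c(3L, dim(mask)))
  m3[2, , ] <- mask
  out <- fill_holes(m3)[2, , ]
  dim(out) <- dim(mask)
  out
}
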