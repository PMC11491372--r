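# Reading/writing image stacks with explicit voxel geometry and channel
# roles, and the per-cell metric table (QuantRecord) CSV layer.

METRIC_COLUMNS <- c(
  "is_fraction_pct", "polarity_index", "pearson_r", "mtoc_density",
  "er_area_um2", "actin_area_um2", "spreading_ratio", "er_volume_um3",
  "whole_cell_fluorescence"
)

stack_description <- function(stack) {
  d <- dim(stack$voxels)
  jsonlite::toJSON(list(
    software = "isquant",
    n_z = d[1], n_y = d[2], n_x = d[3], n_channels = d[4],
    page_order = "channel_fastest",
    z_orientation = "coverslip_first",
    voxel_size_um = as.numeric(stack$voxel_size),
    channel_roles = as.list(stack$channel_roles)
  ), auto_unbox = TRUE, digits = NA)
}

parse_description <- function(desc) {
  if (is.null(desc)) return(NULL)
  if (grepl("\"software\"\\s*:\\s*\"isquant\"", desc)) {
    meta <- jsonlite::fromJSON(desc)
    return(list(
      source = "isquant",
      n_channels = as.integer(meta$n_channels),
      voxel_size = as.numeric(meta$voxel_size_um),
      channel_roles = unlist(meta$channel_roles)
    ))
  }
  if (grepl("<OME|OME-XML|PhysicalSize", desc)) {
    grab <- function(attr) {
      m <- regmatches(desc, regexpr(sprintf('%s="[0-9.eE+-]+"', attr), desc))
      if (length(m) == 0) return(NA_real_)
      as.numeric(sub('.*="([0-9.eE+-]+)".*', "\\1", m))
    }
    vs <- c(grab("PhysicalSizeZ"), grab("PhysicalSizeY"), grab("PhysicalSizeX"))
    nc <- grab("SizeC")
    return(list(
      source = "ome",
      n_channels = if (is.finite(nc)) as.integer(nc) else NULL,
      voxel_size = if (all(is.finite(vs))) vs else NULL,
      channel_roles = NULL
    ))
  }
  NULL
}

#' Read a multi-channel 3-D stack from a TIFF file
#'
#' Pages are interpreted as a Z x channel stack in channel-fastest order (the
#' ImageJ hyperstack XYCZT convention). Voxel sizes and channel layout are
#' taken from the embedded metadata (isquant JSON or OME-XML ImageDescription)
#' when present; arguments override metadata with a warning, since acquisition
#' metadata is often wrong in practice. After reading, slice 1 is always the
#' slice nearest the coverslip: pass `z_flip = TRUE` for source files stored
#' coverslip-last.
#'
#' @param path TIFF file path
#' @param channel_roles named integer vector mapping roles to channel indices;
#'   default taken from metadata, else `c(other = 1)` per channel count
#' @param z_flip if `TRUE`, reverse the slice order on read
#' @param n_channels number of channels (needed for plain TIFFs without
#'   metadata when > 1)
#' @param voxel_size `(dz, dy, dx)` in micrometres; required if the file
#'   carries no usable metadata
#' @return an [image_stack()]
#' @export
read_stack <- function(path, channel_roles = NULL, z_flip = FALSE,
                       n_channels = NULL, voxel_size = NULL) {
  tif <- read_tiff(path)
  meta <- parse_description(tif$description)

  nc <- n_channels
  if (!is.null(meta$n_channels)) {
    if (is.null(nc)) {
      nc <- meta$n_channels
    } else if (nc != meta$n_channels) {
      warning(sprintf(
        "n_channels=%d overrides metadata value %d", nc, meta$n_channels
      ))
    }
  }
  if (is.null(nc)) nc <- 1L

  vs <- voxel_size
  if (!is.null(meta$voxel_size)) {
    if (is.null(vs)) {
      vs <- meta$voxel_size
    } else if (any(abs(as.numeric(vs) - meta$voxel_size) > 1e-12)) {
      warning("supplied voxel_size overrides file metadata")
    }
  }
  if (is.null(vs)) {
    stop("voxel_size not found in metadata and not supplied")
  }

  roles <- channel_roles
  if (is.null(roles)) roles <- meta$channel_roles
  if (is.null(roles)) {
    roles <- stats::setNames(seq_len(nc), if (nc == 1L) "other" else paste0("ch", seq_len(nc)))
  }

  n_pages <- length(tif$pages)
  if (n_pages %% nc != 0L) {
    stop(sprintf("%d pages not divisible by %d channels", n_pages, nc))
  }
  nz <- n_pages %/% nc
  ny <- nrow(tif$pages[[1]]); nx <- ncol(tif$pages[[1]])
  vox <- array(0, dim = c(nz, ny, nx, nc))
  for (z in seq_len(nz)) {
    for (c in seq_len(nc)) {
      vox[z, , , c] <- tif$pages[[(z - 1L) * nc + c]]
    }
  }
  stack <- image_stack(vox, vs, roles)
  if (isTRUE(z_flip)) flip_z(stack) else stack
}

#' Write an ImageStack to a multi-page TIFF
#'
#' Pages are written channel-fastest with an isquant JSON ImageDescription
#' carrying voxel sizes and channel roles, so [read_stack()] round-trips the
#' stack without extra arguments. With `dtype = "auto"`, integer-valued data
#' within 16-bit range is stored as uint16, anything else as float64 (both
#' round-trip bit-identically).
#'
#' @param stack an [image_stack()]
#' @param path output path
#' @param dtype "auto", "uint8", "uint16", "float32" or "float64"
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path, dtype = "auto") {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$voxels)
  if (identical(dtype, "auto")) {
    v <- stack$voxels
    dtype <- if (max(v) <= 65535 && all(v == round(v))) "uint16" else "float64"
  }
  pages <- vector("list", d[1] * d[4])
  for (z in seq_len(d[1])) {
    for (c in seq_len(d[4])) {
      pages[[(z - 1L) * d[4] + c]] <- matrix(stack$voxels[z, , , c], d[2], d[3])
    }
  }
  write_tiff(pages, path, dtype = dtype,
             description = stack_description(stack))
}

#' Construct a per-cell metric record (QuantRecord)
#'
#' One row of all per-cell quantities destined for the results CSV. Metrics
#' not computed for a cell are explicitly absent (`NA`), never zero-filled.
#'
#' @param cell_id character cell identifier
#' @param condition character condition label
#' @param timepoint_min numeric time point in minutes (may be `NA`)
#' @param metrics named list of scalar metrics; recognised names are
#'   `r paste(METRIC_COLUMNS, collapse = ", ")`, extra names are kept
#' @return a `QuantRecord` (named list)
#' @export
quant_record <- function(cell_id, condition = NA_character_,
                         timepoint_min = NA_real_, metrics = list()) {
  stopifnot(is.list(metrics))
  if (length(metrics) && is.null(names(metrics))) stop("metrics must be named")
  chk_range <- function(name, lo, hi) {
    v <- metrics[[name]]
    if (!is.null(v) && !is.na(v) && (v < lo || v > hi)) {
      stop(sprintf("%s = %g outside [%g, %g]", name, v, lo, hi))
    }
  }
  chk_range("is_fraction_pct", 0, 100)
  chk_range("polarity_index", -1, 1)
  chk_range("pearson_r", -1, 1)
  for (nm in c("er_area_um2", "actin_area_um2", "spreading_ratio",
               "er_volume_um3", "mtoc_density", "whole_cell_fluorescence")) {
    chk_range(nm, 0, Inf)
  }
  structure(
    list(cell_id = as.character(cell_id), condition = as.character(condition),
         timepoint_min = as.numeric(timepoint_min), metrics = metrics),
    class = "QuantRecord"
  )
}

records_to_df <- function(records) {
  extra <- sort(unique(unlist(lapply(records, function(r) {
    setdiff(names(r$metrics), METRIC_COLUMNS)
  }))))
  cols <- c(METRIC_COLUMNS, extra)
  rows <- lapply(records, function(r) {
    vals <- lapply(cols, function(cn) {
      v <- r$metrics[[cn]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    })
    names(vals) <- cols
    data.frame(cell_id = r$cell_id, condition = r$condition,
               timepoint_min = r$timepoint_min, vals,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    df <- data.frame(matrix(nrow = 0, ncol = 3 + length(cols)))
    names(df) <- c("cell_id", "condition", "timepoint_min", cols)
    return(df)
  }
  do.call(rbind, rows)
}

#' Write QuantRecords to CSV
#'
#' One row per cell, stable column order (identity columns, then the standard
#' metric columns, then any extras alphabetically); missing metrics are
#' written as empty fields.
#'
#' @param records list of [quant_record()] objects (or a data.frame already
#'   in table form)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_records <- function(records, path) {
  df <- if (is.data.frame(records)) records else records_to_df(records)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a QuantRecord CSV back into a data.frame
#'
#' @param path CSV path written by [write_records()]
#' @return data.frame with empty fields as `NA`
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
}
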