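# Synthetic 3-D confocal stacks of B cells with measured ground truth.
#
# Every SceneTruth field is *measured* on the noise-free stack by direct
# per-voxel summation, never copied from the request: recovery tests then
# exercise the quantification pipeline rather than the generator's
# calibration. Geometry emulates an A20-like B cell spread on a coverslip
# (hemispheroid, ~20 slices at 0.14 um z-step) or a sphere conjugated to an
# antigen-coated bead.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Default parameters for the coverslip-spread synthetic cell
#'
#' Geometry mirrors a spread A20 B cell imaged at 0.14 um z-steps: a
#' hemispheroid resting on the coverslip with a cortical actin shell and
#' synaptic actin layer, an ER network painted on a blobby sub-volume of the
#' cytoplasm, and a tubulin aster radiating from a bright MTOC punctum.
#'
#' @param ... overrides for any default (see source for the full list)
#' @return named list of parameters
#' @export
coverslip_params <- function(...) {
  p <- list(
    n_z = 20L, n_y = 72L, n_x = 72L,
    voxel_size = c(dz = 0.14, dy = 0.2, dx = 0.2),
    cell_radius_um = 5.0,        # lateral radius = actin-delimited spreading
    cell_height_um = 2.2,        # axial semi-axis of the hemispheroid
    bottom_fraction = 0.30,      # target share of ER signal in the synapse slab
    synapse_fraction = 0.10,
    er_volume_um3 = 12,          # painted ER support volume
    texture_sigma_um = 0.5,      # correlation length of the ER texture
    er_total_counts = 2.8e5,     # noise-free whole-cell ER fluorescence
    er_tubulin_coupling = 0,     # weight steering the ER support onto microtubules
    biological_cv = 0.12,        # per-cell lognormal CV on ER volume and total
    mtoc_lateral_um = 1.2,       # MTOC offset from the cell axis
    mtoc_z_um = 0.6,             # MTOC height above the coverslip
    mtoc_pool = 0.3,             # perinuclear ER pool gain at the MTOC
    pool_sigma_um = 0.8,
    tubulin_peak = 180, actin_peak = 180,
    actin_shell_frac = 0.18,     # cortical shell thickness (fraction of radius)
    actin_bottom_um = 0.25,      # synaptic actin layer thickness
    psf_sigma_um = NULL,         # optional (sigma_xy, sigma_z) PSF blur
    poisson_noise = TRUE,
    read_noise_sd = 2
  )
  utils::modifyList(p, list(...))
}

# voxel-centre coordinate grids in micrometres; z = 0 at the coverslip plane
coord_grids <- function(p) {
  vs <- p$voxel_size
  z <- (seq_len(p$n_z) - 1) * vs[["dz"]]
  y <- (seq_len(p$n_y) - (p$n_y + 1) / 2) * vs[["dy"]]
  x <- (seq_len(p$n_x) - (p$n_x + 1) / 2) * vs[["dx"]]
  d <- c(p$n_z, p$n_y, p$n_x)
  list(
    z = array(rep(z, times = d[2] * d[3]), dim = d),
    y = array(rep(rep(y, each = d[1]), times = d[3]), dim = d),
    x = array(rep(x, each = d[1] * d[2]), dim = d)
  )
}

smooth_noise_field <- function(dim, sigma_vox) {
  f <- array(stats::rnorm(prod(dim)), dim = dim)
  f <- gauss_smooth(f, sigma_vox)
  rng <- range(f)
  (f - rng[1]) / (rng[2] - rng[1])
}

# optional PSF: isotropic in XY, wider in Z, applied to the clean signal
# before noise; off by default (the metrics are intensity-sum statistics
# largely insensitive to modest blur)
apply_psf <- function(clean, p) {
  s <- p$psf_sigma_um
  if (is.null(s)) return(clean)
  vs <- p$voxel_size
  if (length(s) == 1L) s <- c(s, 2 * s)
  gauss_smooth(clean, c(s[2] / vs[["dz"]], s[1] / vs[["dy"]], s[1] / vs[["dx"]]))
}

apply_noise <- function(clean, p) {
  clean <- apply_psf(clean, p)
  if (!isTRUE(p$poisson_noise) && p$read_noise_sd == 0) return(clean)
  v <- as.numeric(clean)
  if (isTRUE(p$poisson_noise)) v <- stats::rpois(length(v), v)
  if (p$read_noise_sd > 0) v <- v + stats::rnorm(length(v), 0, p$read_noise_sd)
  out <- pmax(0, round(v))
  dim(out) <- dim(clean)
  out
}

tubulin_pattern <- function(g, cell, mtoc_um, p) {
  dz <- g$z - mtoc_um[1]; dy <- g$y - mtoc_um[2]; dx <- g$x - mtoc_um[3]
  r2 <- dz^2 + dy^2 + dx^2
  phi <- atan2(dy, dx)
  n_rays <- 12L
  phis <- stats::runif(n_rays, -pi, pi)
  spokes <- 0
  for (ph in phis) spokes <- spokes + exp(30 * (cos(phi - ph) - 1))
  aster <- spokes / (1 + sqrt(r2) / 1.5) * exp(-abs(dz) / 1.2)
  punctum <- exp(-r2 / (2 * 0.25^2))
  rays <- (0.03 + aster) * cell
  pat <- (0.03 + 0.25 * aster + punctum) * cell
  list(total = pat / max(pat), rays = rays / max(rays))
}

actin_pattern <- function(g, u, cell, p) {
  shell <- cell & (u >= 1 - p$actin_shell_frac)
  plate <- cell & (g$z <= p$actin_bottom_um)
  pat <- 0.10 * cell
  pat[shell | plate] <- 1
  pat
}

mtoc_voxel <- function(mtoc_um, p) {
  vs <- p$voxel_size
  c(
    z = round(mtoc_um[1] / vs[["dz"]]) + 1L,
    y = round(mtoc_um[2] / vs[["dy"]] + (p$n_y + 1) / 2),
    x = round(mtoc_um[3] / vs[["dx"]] + (p$n_x + 1) / 2)
  )
}

# share of total intensity in the first n_syn slices, by direct summation
slab_share <- function(arr, n_syn) {
  tot <- sum(arr)
  sum(arr[seq_len(n_syn), , ]) / tot
}

masked_pearson <- function(a, b, mask) {
  av <- a[mask]; bv <- b[mask]
  stats::cor(av, bv)
}

#' Generate a synthetic coverslip-spread B cell with known ground truth
#'
#' Returns a 3-channel (er, tubulin, actin) stack plus a `SceneTruth` list in
#' which every field is re-measured on the noise-free stack. The axial
#' placement of the ER support is calibrated (by root finding on a z-decay
#' rate) so that the noise-free fraction of ER signal in the synapse slab
#' (first `ceiling(synapse_fraction * n_z)` slices) matches
#' `params$bottom_fraction` to within 1%; generation fails loudly if the
#' requested fraction is unachievable for the geometry.
#'
#' @param params a [coverslip_params()] list
#' @param seed integer RNG seed; (params, seed) fully determines the output
#' @return list with elements `stack` (an [image_stack()]) and `truth`
#'   (SceneTruth: `true_bottom_fraction`, `true_coupling`, `true_pearson_r`,
#'   `mtoc_position`, `true_object_volume_um3`, `whole_cell_total`, `seed`,
#'   plus a `masks` sublist with the painted supports for oracle tests)
#' @export
generate_coverslip_cell <- function(params = coverslip_params(), seed = 1L) {
  p <- params
  stopifnot(p$cell_radius_um > 0, p$cell_height_um > 0, p$read_noise_sd >= 0)
  vs <- p$voxel_size
  margin_xy <- 2 * max(vs[["dy"]], vs[["dx"]])
  if (p$cell_radius_um + margin_xy > (min(p$n_y, p$n_x) - 1) / 2 * vs[["dy"]] ||
      p$cell_height_um + 2 * vs[["dz"]] > p$n_z * vs[["dz"]]) {
    stop("cell larger than stack (needs a 2-voxel margin)")
  }
  if (p$bottom_fraction <= 0 || p$bottom_fraction >= 1) {
    stop("bottom_fraction must be in (0, 1)")
  }

  with_seed(seed, {
    g <- coord_grids(p)
    u <- sqrt((g$x / p$cell_radius_um)^2 + (g$y / p$cell_radius_um)^2 +
                (g$z / p$cell_height_um)^2)
    cell <- u <= 1
    n_syn <- n_synapse_slices(p$n_z, p$synapse_fraction)
    vox_vol <- prod(vs)

    # per-cell biological variability (real cells differ in organelle size
    # and expression level; without it between-condition tests see only
    # technical noise)
    cv <- p$biological_cv
    jitter <- function() stats::rlnorm(1, meanlog = -cv^2 / 2, sdlog = cv)
    er_volume_um3 <- p$er_volume_um3 * jitter()
    er_total_counts <- p$er_total_counts * jitter()

    sigma_vox <- p$texture_sigma_um / c(vs[["dz"]], vs[["dy"]], vs[["dx"]])
    tex <- smooth_noise_field(dim(cell), sigma_vox)
    mtoc_um <- c(p$mtoc_z_um, p$mtoc_lateral_um, 0)
    tub_pat <- tubulin_pattern(g, cell, mtoc_um, p)
    tub <- tub_pat$total

    n_support <- round(er_volume_um3 / vox_vol)
    cell_idx <- which(cell)
    if (n_support > length(cell_idx)) stop("er_volume_um3 exceeds the cell volume")
    z_cell <- g$z[cell_idx]

    # support placement score: ER texture, attraction onto the microtubule
    # ray lattice (coupling), attraction to the MTOC region (perinuclear
    # pool), and the axial term lambda that is calibrated to the requested
    # synapse-slab fraction
    cpl <- p$er_tubulin_coupling
    pool_g <- exp(
      -((g$z - mtoc_um[1])^2 + (g$y - mtoc_um[2])^2 + (g$x - mtoc_um[3])^2) /
        (2 * p$pool_sigma_um^2)
    )
    static_score <- (1 - cpl) * log(0.05 + 0.95 * tex[cell_idx]) +
      cpl * log(0.05 + 0.95 * tub_pat$rays[cell_idx]) +
      3 * p$mtoc_pool * pool_g[cell_idx]
    pool_factor <- 1 + p$mtoc_pool * pool_g

    er_for_lambda <- function(lambda) {
      score <- static_score - lambda * z_cell
      keep <- cell_idx[order(score, decreasing = TRUE)[seq_len(n_support)]]
      support <- array(FALSE, dim = dim(cell))
      support[keep] <- TRUE
      er <- (0.4 + 0.6 * tex) * pool_factor * support
      er <- er / sum(er) * er_total_counts
      list(er = er, support = support)
    }
    frac_at <- function(lambda) slab_share(er_for_lambda(lambda)$er, n_syn)

    lo <- -60; hi <- 60
    f_lo <- frac_at(lo); f_hi <- frac_at(hi)
    if (p$bottom_fraction < f_lo || p$bottom_fraction > f_hi) {
      stop(sprintf(
        "requested bottom fraction %.3f unachievable (attainable range %.3f..%.3f)",
        p$bottom_fraction, f_lo, f_hi
      ))
    }
    root <- stats::uniroot(function(l) frac_at(l) - p$bottom_fraction,
                           c(lo, hi), tol = 1e-4)
    er_parts <- er_for_lambda(root$root)
    er_clean <- er_parts$er
    support <- er_parts$support
    realized <- slab_share(er_clean, n_syn)
    if (abs(realized - p$bottom_fraction) > 0.01) {
      stop(sprintf(
        "axial calibration failed: realized %.4f vs requested %.4f",
        realized, p$bottom_fraction
      ))
    }

    tub_clean <- tub * p$tubulin_peak
    act_clean <- actin_pattern(g, u, cell, p) * p$actin_peak

    d <- c(dim(cell), 3L)
    vox <- array(0, dim = d)
    vox[, , , 1] <- apply_noise(er_clean, p)
    vox[, , , 2] <- apply_noise(tub_clean, p)
    vox[, , , 3] <- apply_noise(act_clean, p)
    stack <- image_stack(vox, vs, c(er = 1L, tubulin = 2L, actin = 3L))

    truth <- list(
      true_bottom_fraction = realized,
      true_coupling = p$er_tubulin_coupling,
      true_pearson_r = masked_pearson(er_clean, tub_clean, cell),
      mtoc_position = mtoc_voxel(mtoc_um, p),
      bead_position = NULL,
      true_object_volume_um3 = sum(support) * vox_vol,
      whole_cell_total = sum(er_clean),
      n_synapse_slices = n_syn,
      seed = seed,
      masks = list(
        cell_support = cell,
        er_support = support,
        noise_free = list(er = er_clean, tubulin = tub_clean, actin = act_clean)
      )
    )
    list(stack = stack, truth = truth)
  })
}

#' Default parameters for the bead-conjugate synthetic cell
#'
#' A spherical B cell touching an antigen-coated bead; the ER intensity is
#' tilted along the cell-bead axis to emulate organelle polarization toward
#' the synapse.
#'
#' @param ... overrides for any default
#' @return named list of parameters
#' @export
conjugate_params <- function(...) {
  p <- list(
    n_z = 40L, n_y = 56L, n_x = 56L,
    voxel_size = c(dz = 0.25, dy = 0.2, dx = 0.2),
    cell_radius_um = 3.2,
    bead_radius_um = 1.5,
    bead_direction = c(0, 0, 1),   # unit (z, y, x); default along +x
    polarization = 0,              # target normalized centroid displacement
    er_volume_um3 = 8,             # painted ER support volume (compact enough
                                   # that strong polarization is attainable)
    texture_strength = 0.5,
    texture_sigma_um = 0.5,
    er_peak = 200,
    tubulin_peak = 180, actin_peak = 180,
    actin_shell_frac = 0.18,
    psf_sigma_um = NULL,
    poisson_noise = TRUE,
    read_noise_sd = 2
  )
  utils::modifyList(p, list(...))
}

#' Generate a synthetic B cell-bead conjugate with known polarization
#'
#' The ER mass is displaced along the cell-bead axis; the displacement gain is
#' calibrated so that the noise-free fluorescence-centroid offset, projected
#' on the axis and normalized by the cell radius, equals `polarization`. The
#' recorded truth is always the realized noise-free value.
#'
#' @param params a [conjugate_params()] list
#' @param polarization target polarity in `[-1, 1]`; overrides
#'   `params$polarization`
#' @param seed integer RNG seed
#' @return list with `stack` and `truth` (`true_polarization`,
#'   `bead_position`, `mtoc_position`, `cell_center`, masks)
#' @export
generate_bead_conjugate <- function(params = conjugate_params(),
                                    polarization = params$polarization,
                                    seed = 1L) {
  p <- params
  if (abs(polarization) > 1) stop("polarization out of range [-1, 1]")
  vs <- p$voxel_size
  r <- p$cell_radius_um
  u_hat <- p$bead_direction / sqrt(sum(p$bead_direction^2))

  with_seed(seed, {
    g <- coord_grids(p)
    center_um <- c((p$n_z - 1) / 2 * vs[["dz"]], 0, 0)
    dzc <- g$z - center_um[1]; dyc <- g$y - center_um[2]; dxc <- g$x - center_um[3]
    rho <- sqrt(dzc^2 + dyc^2 + dxc^2)
    cell <- rho <= r
    if (center_um[1] - r < 2 * vs[["dz"]] ||
        r + 2 * max(vs) > (min(p$n_y, p$n_x) - 1) / 2 * vs[["dy"]]) {
      stop("cell larger than stack (needs a 2-voxel margin)")
    }
    bead_um <- center_um + (r + p$bead_radius_um) * u_hat
    if (p$bead_radius_um >= r) stop("bead overlaps the cell center")

    proj <- (dzc * u_hat[1] + dyc * u_hat[2] + dxc * u_hat[3]) / r
    sigma_vox <- p$texture_sigma_um / c(vs[["dz"]], vs[["dy"]], vs[["dx"]])
    tex <- smooth_noise_field(dim(cell), sigma_vox)
    ts <- p$texture_strength
    base <- ((1 - ts) + ts * (0.34 + 0.66 * tex)) * cell

    # the ER support (top-N voxels of a texture score tilted along the
    # cell-bead axis) is displaced toward the bead, and the intensity within
    # it is tilted by the same rate; the rate k is calibrated so the realized
    # normalized centroid offset equals the requested polarization
    n_support <- round(p$er_volume_um3 / prod(vs))
    cell_idx <- which(cell)
    if (n_support > length(cell_idx)) stop("er_volume_um3 exceeds the cell volume")
    # with texture off, place the support radially (innermost voxels) so a
    # zero-polarization cell is genuinely symmetric
    log_tex <- if (ts > 0) log(0.05 + 0.95 * tex[cell_idx]) else -rho[cell_idx] / r
    proj_cell <- proj[cell_idx]

    er_for_k <- function(k) {
      score <- log_tex + k * proj_cell
      keep <- cell_idx[order(score, decreasing = TRUE)[seq_len(n_support)]]
      support <- array(FALSE, dim = dim(cell))
      support[keep] <- TRUE
      # intensity tilt is capped: displacement is carried by support
      # placement, keeping the painted ER bright relative to the noise floor
      # (a strong intensity tilt would make most of the organelle too dim to
      # outweigh the clamped read-noise background in the centroid)
      k_i <- sign(k) * min(abs(k), 2)
      er <- base * exp(k_i * proj) * support
      list(er = er / max(er) * p$er_peak, support = support)
    }
    centroid_for <- function(k) {
      w <- er_for_k(k)$er
      fz <- sum(w * g$z) / sum(w); fy <- sum(w * g$y) / sum(w)
      fx <- sum(w * g$x) / sum(w)
      ((fz - center_um[1]) * u_hat[1] + (fy - center_um[2]) * u_hat[2] +
          (fx - center_um[3]) * u_hat[3]) / r
    }
    c_lo <- centroid_for(-100); c_hi <- centroid_for(100)
    if (polarization < c_lo || polarization > c_hi) {
      stop(sprintf(
        "requested polarization %.3f unachievable (attainable range %.3f..%.3f)",
        polarization, c_lo, c_hi
      ))
    }
    root <- stats::uniroot(function(k) centroid_for(k) - polarization,
                           c(-100, 100), tol = 1e-6)
    k <- root$root
    er_parts <- er_for_k(k)
    er_clean <- er_parts$er
    realized <- centroid_for(k)

    mtoc_um <- center_um + 0.7 * r * u_hat
    tub_clean <- tubulin_pattern(g, cell, mtoc_um, p)$total * p$tubulin_peak
    shell <- cell & (rho >= (1 - p$actin_shell_frac) * r)
    act <- 0.10 * cell
    act[shell] <- 1
    act_clean <- act * p$actin_peak

    d <- c(dim(cell), 3L)
    vox <- array(0, dim = d)
    vox[, , , 1] <- apply_noise(er_clean, p)
    vox[, , , 2] <- apply_noise(tub_clean, p)
    vox[, , , 3] <- apply_noise(act_clean, p)
    stack <- image_stack(vox, vs, c(er = 1L, tubulin = 2L, actin = 3L))

    bead_vox <- c(
      z = round(bead_um[1] / vs[["dz"]]) + 1L,
      y = round(bead_um[2] / vs[["dy"]] + (p$n_y + 1) / 2),
      x = round(bead_um[3] / vs[["dx"]] + (p$n_x + 1) / 2)
    )
    truth <- list(
      true_polarization = realized,
      bead_position = bead_vox,
      bead_position_um = bead_um,
      cell_center_um = center_um,
      cell_radius_um = r,
      mtoc_position = mtoc_voxel(mtoc_um, p),
      true_object_volume_um3 = sum(er_parts$support) * prod(vs),
      whole_cell_total = sum(er_clean),
      seed = seed,
      masks = list(cell_support = cell, er_support = er_parts$support,
                   noise_free = list(er = er_clean, tubulin = tub_clean,
                                     actin = act_clean))
    )
    list(stack = stack, truth = truth)
  })
}

#' Generate a channel pair with a controlled degree of colocalization
#'
#' Inside the cell body the ER channel is a convex mixture of the (scaled)
#' tubulin pattern and an independent smooth random pattern:
#' `er = coupling * tubulin_pattern + (1 - coupling) * independent`, before
#' noise. The recorded truth is the noise-free Pearson correlation of the two
#' channels inside the cell mask, measured by direct summation.
#'
#' @param params a [coverslip_params()] list (geometry and noise are reused)
#' @param coupling mixing coefficient in `[0, 1]`
#' @param seed integer RNG seed
#' @return list with `stack` and `truth` (`true_coupling`, `true_pearson_r`,
#'   `mtoc_position`, masks)
#' @export
generate_coupled_channels <- function(params = coverslip_params(),
                                      coupling = 0.5, seed = 1L) {
  p <- params
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  vs <- p$voxel_size

  with_seed(seed, {
    g <- coord_grids(p)
    u <- sqrt((g$x / p$cell_radius_um)^2 + (g$y / p$cell_radius_um)^2 +
                (g$z / p$cell_height_um)^2)
    cell <- u <= 1
    mtoc_um <- c(p$mtoc_z_um, p$mtoc_lateral_um, 0)
    sigma_vox <- p$texture_sigma_um / c(vs[["dz"]], vs[["dy"]], vs[["dx"]])

    pat_a <- tubulin_pattern(g, cell, mtoc_um, p)$total
    pat_a <- pat_a / mean(pat_a[cell])
    indep <- (0.05 + 0.95 * smooth_noise_field(dim(cell), sigma_vox)) * cell
    indep <- indep / mean(indep[cell])

    er_clean <- (coupling * pat_a + (1 - coupling) * indep) * cell
    er_clean <- er_clean / max(er_clean) * 200
    tub_clean <- pat_a / max(pat_a) * p$tubulin_peak * cell
    act_clean <- actin_pattern(g, u, cell, p) * p$actin_peak

    d <- c(dim(cell), 3L)
    vox <- array(0, dim = d)
    vox[, , , 1] <- apply_noise(er_clean, p)
    vox[, , , 2] <- apply_noise(tub_clean, p)
    vox[, , , 3] <- apply_noise(act_clean, p)
    stack <- image_stack(vox, vs, c(er = 1L, tubulin = 2L, actin = 3L))

    truth <- list(
      true_coupling = coupling,
      true_pearson_r = masked_pearson(er_clean, tub_clean, cell),
      mtoc_position = mtoc_voxel(mtoc_um, p),
      seed = seed,
      masks = list(cell_support = cell,
                   noise_free = list(er = er_clean, tubulin = tub_clean,
                                     actin = act_clean))
    )
    list(stack = stack, truth = truth)
  })
}

#' Write a SceneTruth sidecar as JSON
#'
#' Array-valued fields (masks, noise-free channels) are dropped; scalar and
#' coordinate fields are kept.
#'
#' @param truth a SceneTruth list
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_scene_truth <- function(truth, path) {
  truth$masks <- NULL
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
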