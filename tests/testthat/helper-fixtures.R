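# Shared fixtures and independent oracles. Oracles here are deliberately
# written as direct, brute-force computations so they stay independent of
# the package's implementation paths.

# a constant-intensity cuboid stack with a matching all-TRUE cuboid mask
cuboid_stack <- function(nz = 20, ny = 10, nx = 10, value = 1,
                         voxel_size = c(0.14, 0.2, 0.2), n_ch = 1) {
  vox <- array(value, dim = c(nz, ny, nx, n_ch))
  roles <- if (n_ch == 1) c(er = 1L) else c(er = 1L, tubulin = 2L, actin = 3L)[seq_len(n_ch)]
  image_stack(vox, voxel_size, roles)
}

full_mask_seg <- function(stack) {
  seg <- list(cell_mask = array(TRUE, dim = dim(stack$voxels)[1:3]))
  class(seg) <- "CellSegmentation"
  seg
}

mask_seg <- function(mask, mtoc = NULL, bead = NULL) {
  seg <- list(cell_mask = mask, mtoc_position = mtoc, bead_position = bead)
  class(seg) <- "CellSegmentation"
  seg
}

# brute-force MTOC-circle oracle: loop every pixel of every candidate slice
# and test the disc inequality (dy*Dy)^2 + (dx*Dx)^2 <= (d/2)^2
mtoc_density_oracle <- function(stack, mtoc, channel_role, diameter_um) {
  ch <- get_channel(stack, channel_role)
  d <- dim(ch)
  vs <- stack$voxel_size
  zs <- intersect((mtoc[["z"]] - 1L):(mtoc[["z"]] + 1L), seq_len(d[1]))
  vals <- numeric(length(zs) * d[2] * d[3])
  n <- 0L
  for (z in zs) {
    for (y in seq_len(d[2])) {
      for (x in seq_len(d[3])) {
        dy <- (y - mtoc[["y"]]) * vs[["dy"]]
        dx <- (x - mtoc[["x"]]) * vs[["dx"]]
        if (dy^2 + dx^2 <= (diameter_um / 2)^2) {
          n <- n + 1L
          vals[n] <- ch[z, y, x]
        }
      }
    }
  }
  list(mean = mean(vals[seq_len(n)]), n = n)
}

# direct-formula Pearson on extracted voxel vectors (independent of
# pearson_synapse): relies on stats::cor
pearson_oracle <- function(stack, mask, role_a, role_b, n_syn) {
  roi <- mask
  roi[-seq_len(n_syn), , ] <- FALSE
  stats::cor(get_channel(stack, role_a)[roi], get_channel(stack, role_b)[roi])
}

# one-way ANOVA and Tukey HSD from first principles (sums of squares and
# ptukey), independent of stats::aov / stats::TukeyHSD
anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_between <- sum(ns * (means - gm)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- k - 1
  df2 <- n - k
  ms_within <- ss_within / df2
  F <- (ss_between / df1) / ms_within
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(levels(groups), 2)
  tukey <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(ms_within / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(means[[j]] - means[[i]]) / se
    stats::ptukey(q, k, df2, lower.tail = FALSE)
  })
  names(tukey) <- paste(pairs[2, ], pairs[1, ], sep = "-")
  list(F = F, p = p, tukey = tukey)
}

local_tmp <- function(ext = ".tif", envir = parent.frame()) {
  path <- tempfile(fileext = ext)
  withr::defer(unlink(path), envir = envir)
  path
}
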