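# The generator's realized-truth contract: every SceneTruth field must be
# reproducible from the noise-free stack by independent per-voxel summation.

test_that("identical params and seed give bit-identical stacks", {
  a <- generate_coverslip_cell(coverslip_params(), seed = 17)
  b <- generate_coverslip_cell(coverslip_params(), seed = 17)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$true_bottom_fraction, b$truth$true_bottom_fraction)
  c1 <- generate_bead_conjugate(conjugate_params(), 0.4, seed = 5)
  c2 <- generate_bead_conjugate(conjugate_params(), 0.4, seed = 5)
  expect_identical(c1$stack$voxels, c2$stack$voxels)
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(3)
  set.seed(99); invisible(generate_coverslip_cell(seed = 3)); x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("realized bottom fraction is measured truth and tracks the request", {
  for (bf in c(0.2, 0.6)) {
    gen <- generate_coverslip_cell(coverslip_params(bottom_fraction = bf), seed = 3)
    truth <- gen$truth
    # independent brute-force voxel sum on the noise-free ER channel
    er <- truth$masks$noise_free$er
    n_syn <- truth$n_synapse_slices
    frac <- sum(er[seq_len(n_syn), , ]) / sum(er)
    expect_equal(truth$true_bottom_fraction, frac, tolerance = 1e-12)
    expect_lt(abs(frac - bf), 0.01)
  }
})

test_that("noise-free slab mass strictly increases with requested bottom fraction", {
  fracs <- vapply(c(0.15, 0.35, 0.55, 0.75), function(bf) {
    generate_coverslip_cell(coverslip_params(bottom_fraction = bf),
                            seed = 11)$truth$true_bottom_fraction
  }, 1.0)
  expect_true(all(diff(fracs) > 0))
})

test_that("unachievable bottom fractions fail loudly", {
  expect_error(generate_coverslip_cell(coverslip_params(bottom_fraction = 0)),
               "bottom_fraction")
  expect_error(generate_coverslip_cell(coverslip_params(bottom_fraction = 1)),
               "bottom_fraction")
  expect_error(
    generate_coverslip_cell(coverslip_params(cell_radius_um = 20)),
    "larger than stack"
  )
})

test_that("conjugate truth equals the centroid-projection oracle and flips sign", {
  gen <- generate_bead_conjugate(conjugate_params(), polarization = 0.8, seed = 21)
  tr <- gen$truth
  # independent oracle: direct voxel summation of the noise-free centroid
  er <- tr$masks$noise_free$er
  d <- dim(er)
  vs <- gen$stack$voxel_size
  z <- (seq_len(d[1]) - 1) * vs[["dz"]]
  y <- (seq_len(d[2]) - (d[2] + 1) / 2) * vs[["dy"]]
  x <- (seq_len(d[3]) - (d[3] + 1) / 2) * vs[["dx"]]
  tot <- sum(er)
  fz <- sum(apply(er, 1, sum) * z) / tot
  fy <- sum(apply(er, 2, sum) * y) / tot
  fx <- sum(apply(er, 3, sum) * x) / tot
  u_hat <- c(0, 0, 1)
  ctr <- tr$cell_center_um
  oracle <- sum((c(fz, fy, fx) - ctr) * u_hat) / tr$cell_radius_um
  expect_equal(tr$true_polarization, oracle, tolerance = 1e-10)
  expect_lt(abs(tr$true_polarization - 0.8), 0.01)

  # mirrored bead direction with the same seed flips the truth exactly
  mirror <- generate_bead_conjugate(
    conjugate_params(bead_direction = c(0, 0, -1)), polarization = -0.8, seed = 21
  )
  expect_equal(mirror$truth$true_polarization, -tr$true_polarization,
               tolerance = 5e-3)
})

test_that("zero-polarization symmetric cell has centroid at the cell center", {
  gen <- generate_bead_conjugate(
    conjugate_params(texture_strength = 0, poisson_noise = FALSE, read_noise_sd = 0),
    polarization = 0, seed = 2
  )
  expect_lt(abs(gen$truth$true_polarization), 1e-3)
})

test_that("polarization requests outside the attainable range error", {
  expect_error(generate_bead_conjugate(conjugate_params(), polarization = 1.2),
               "out of range")
  expect_error(generate_bead_conjugate(conjugate_params(), polarization = 0.99),
               "unachievable")
  expect_error(
    generate_bead_conjugate(conjugate_params(bead_radius_um = 4)),
    "bead overlaps"
  )
})

test_that("coupled-channel truth is the measured noise-free Pearson r", {
  # coupling 1, zero noise: ER is an exact rescaling of tubulin, r = 1
  gen1 <- generate_coupled_channels(
    coverslip_params(poisson_noise = FALSE, read_noise_sd = 0), coupling = 1, seed = 4
  )
  expect_equal(gen1$truth$true_pearson_r, 1, tolerance = 1e-12)
  mask <- gen1$truth$masks$cell_support
  expect_equal(
    stats::cor(gen1$stack$voxels[, , , 1][mask], gen1$stack$voxels[, , , 2][mask]),
    1, tolerance = 1e-12
  )
  # coupling 0, zero noise: independent patterns, near-zero r, measured not assumed
  gen0 <- generate_coupled_channels(
    coverslip_params(poisson_noise = FALSE, read_noise_sd = 0), coupling = 0, seed = 4
  )
  nf <- gen0$truth$masks$noise_free
  direct <- stats::cor(nf$er[mask], nf$tubulin[mask])
  expect_equal(gen0$truth$true_pearson_r, direct, tolerance = 1e-12)
  expect_lt(abs(gen0$truth$true_pearson_r), 0.35)
  # noise-free truth strictly increases with coupling
  r_mid <- generate_coupled_channels(coverslip_params(), coupling = 0.5,
                                     seed = 4)$truth$true_pearson_r
  expect_gt(r_mid, gen0$truth$true_pearson_r)
  expect_lt(r_mid, gen1$truth$true_pearson_r)
  expect_error(generate_coupled_channels(coupling = 1.5), "coupling")
})

test_that("SceneTruth sidecar drops arrays and round-trips scalars", {
  gen <- generate_coverslip_cell(seed = 8)
  path <- local_tmp(".json")
  write_scene_truth(gen$truth, path)
  side <- jsonlite::fromJSON(path)
  expect_null(side$masks)
  expect_equal(side$true_bottom_fraction, gen$truth$true_bottom_fraction)
  expect_equal(side$true_object_volume_um3, gen$truth$true_object_volume_um3)
  expect_equal(unlist(side$mtoc_position), unname(gen$truth$mtoc_position))
})
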