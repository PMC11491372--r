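test_that("uniform cuboid gives flat percentages and the exact IS fraction", {
  stk <- cuboid_stack(20, 10, 10, value = 1)
  seg <- full_mask_seg(stk)
  zp <- zscan_profile(stk, seg, "er")
  expect_equal(zp$pct_per_slice, rep(5, 20), tolerance = 1e-12)
  expect_equal(zp$n_synapse_slices, 2L)
  expect_equal(zp$is_fraction_pct, 10, tolerance = 1e-12)
  expect_equal(sum(zp$pct_per_slice), 100, tolerance = 1e-6)
})

test_that("all signal in the synapse slab gives IS fraction 100", {
  vox <- array(0, dim = c(20, 10, 10, 1))
  vox[1:2, , , 1] <- 7
  stk <- image_stack(vox, c(0.14, 0.2, 0.2), c(er = 1L))
  zp <- zscan_profile(stk, full_mask_seg(stk), "er")
  expect_equal(zp$is_fraction_pct, 100, tolerance = 1e-12)
})

test_that("n_synapse_slices is ceil(0.1 n_z), never zero", {
  expect_equal(n_synapse_slices(20), 2L)
  expect_equal(n_synapse_slices(21), 3L)
  expect_equal(n_synapse_slices(9), 1L)
  expect_equal(n_synapse_slices(5), 1L)
})

test_that("percentages always sum to 100 and scale invariance holds", {
  gen <- generate_coverslip_cell(seed = 31)
  seg <- segment_all(gen$stack)
  zp <- zscan_profile(gen$stack, seg, "er")
  expect_equal(sum(zp$pct_per_slice), 100, tolerance = 1e-6)
  expect_true(all(zp$pct_per_slice >= 0))
  scaled <- gen$stack
  scaled$voxels <- scaled$voxels * 3.7
  zp2 <- zscan_profile(scaled, seg, "er")
  expect_equal(zp2$pct_per_slice, zp$pct_per_slice, tolerance = 1e-12)
  expect_equal(zp2$is_fraction_pct, zp$is_fraction_pct, tolerance = 1e-12)
})

test_that("zero whole-cell fluorescence is an explicit error, never NaN", {
  stk <- cuboid_stack(10, 6, 6, value = 0)
  expect_error(zscan_profile(stk, full_mask_seg(stk), "er"), "zero whole-cell")
})

test_that("whole-cell fluorescence equals the Z-scan row sum and is linear", {
  stk <- cuboid_stack(10, 10, 10, value = 1)
  seg <- full_mask_seg(stk)
  expect_equal(whole_cell_fluorescence(stk, seg, "er"), 1000)
  gen <- generate_coverslip_cell(seed = 13)
  seg <- segment_all(gen$stack)
  zp <- zscan_profile(gen$stack, seg, "er")
  tot <- whole_cell_fluorescence(gen$stack, seg, "er")
  expect_identical(tot, sum(zp$raw_per_slice))
  doubled <- gen$stack
  doubled$voxels <- doubled$voxels * 2
  expect_equal(whole_cell_fluorescence(doubled, seg, "er"), 2 * tot)
})

test_that("polarity index: symmetry, extremes and scale invariance", {
  # spherically symmetric intensity about the mask centroid -> PI ~ 0
  d <- c(21, 21, 21)
  ctr <- c(11, 11, 11)
  g <- expand.grid(z = 1:21, y = 1:21, x = 1:21)
  rho <- sqrt((g$z - 11)^2 + (g$y - 11)^2 + (g$x - 11)^2)
  mask <- array(rho <= 9, dim = d)
  vox <- array(0, dim = c(d, 1))
  vox[, , , 1] <- array(exp(-(rho / 5)^2), dim = d) * mask
  stk <- image_stack(vox, c(0.2, 0.2, 0.2), c(er = 1L))
  seg <- mask_seg(mask)
  bead <- c(z = 11, y = 11, x = 21)
  expect_lt(abs(polarity_index(stk, seg, "er", bead)), 0.02)

  # all fluorescence at the bead-facing boundary -> PI near +1
  vox2 <- array(0, dim = c(d, 1))
  vox2[11, 11, 20, 1] <- 100
  stk2 <- image_stack(vox2, c(0.2, 0.2, 0.2), c(er = 1L))
  expect_gte(polarity_index(stk2, seg, "er", bead), 0.9)

  # positive rescaling leaves the index unchanged
  gen <- generate_bead_conjugate(conjugate_params(), 0.4, seed = 3)
  segc <- segment_all(gen$stack, bead_position = gen$truth$bead_position)
  p1 <- polarity_index(gen$stack, segc, "er", gen$truth$bead_position)
  sc <- gen$stack; sc$voxels <- sc$voxels * 11
  expect_equal(polarity_index(sc, segc, "er", gen$truth$bead_position), p1,
               tolerance = 1e-12)
})

test_that("reflecting the fluorescence through the centroid plane negates the index", {
  gen <- generate_bead_conjugate(conjugate_params(), 0.5, seed = 14)
  bead <- gen$truth$bead_position  # bead on the +x axis
  seg <- segment_all(gen$stack, bead_position = bead)
  p_fwd <- polarity_index(gen$stack, seg, "er", bead)
  # mirror the whole stack in x; the mask mirrors too, the bead stays put
  mir <- gen$stack
  nx <- dim(mir$voxels)[3]
  mir$voxels <- mir$voxels[, , nx:1, , drop = FALSE]
  seg_m <- segment_all(mir, bead_position = bead)
  p_mir <- polarity_index(mir, seg_m, "er", bead)
  expect_equal(p_mir, -p_fwd, tolerance = 0.01)
})

test_that("polarity errors: missing bead, degenerate axis, zero signal", {
  stk <- cuboid_stack(10, 10, 10, value = 1)
  seg <- full_mask_seg(stk)
  expect_error(polarity_index(stk, seg, "er", NULL), "bead_position")
  ctr <- c(z = 5, y = 5, x = 5)
  expect_error(polarity_index(stk, seg, "er", c(z = 5.5, y = 5.5, x = 5.5)),
               "axis undefined")
  zero <- cuboid_stack(10, 10, 10, value = 0)
  expect_error(polarity_index(zero, seg, "er", c(z = 1, y = 1, x = 1)),
               "zero fluorescence")
})
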