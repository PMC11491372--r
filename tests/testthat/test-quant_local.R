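test_that("Pearson is exact on affine and anti-correlated channels", {
  gen <- generate_coverslip_cell(seed = 19)
  seg <- segment_all(gen$stack)
  a <- get_channel(gen$stack, "er")
  d <- dim(gen$stack$voxels)
  mk <- function(b) {
    vox <- array(0, dim = c(d[1:3], 2))
    vox[, , , 1] <- a
    vox[, , , 2] <- b
    image_stack(vox, gen$stack$voxel_size, c(er = 1L, tubulin = 2L))
  }
  r_affine <- pearson_synapse(mk(3 * a + 7), seg)$pearson_r
  expect_equal(r_affine, 1, tolerance = 1e-12)
  r_anti <- pearson_synapse(mk(-a + max(a)), seg)$pearson_r
  expect_equal(r_anti, -1, tolerance = 1e-12)
})

test_that("Pearson matches the direct-formula oracle and is affine invariant", {
  for (s in c(2, 5)) {
    gen <- generate_coupled_channels(coupling = 0.6, seed = s)
    seg <- segment_all(gen$stack)
    res <- pearson_synapse(gen$stack, seg)
    oracle <- pearson_oracle(gen$stack, seg$cell_mask, "er", "tubulin",
                             n_synapse_slices(dim(gen$stack$voxels)[1]))
    expect_equal(res$pearson_r, oracle, tolerance = 1e-10)
    expect_gte(res$n_voxels, 2)
    # independent positive-gain rescaling of either channel
    sc <- gen$stack
    sc$voxels[, , , 1] <- sc$voxels[, , , 1] * 5 + 3
    sc$voxels[, , , 2] <- sc$voxels[, , , 2] * 0.25 + 11
    expect_equal(pearson_synapse(sc, seg)$pearson_r, res$pearson_r,
                 tolerance = 1e-12)
  }
})

test_that("zero-variance channels are an explicit error", {
  vox <- array(1, dim = c(10, 8, 8, 2))
  vox[, , , 2] <- seq_len(10 * 8 * 8)
  stk <- image_stack(vox, c(0.2, 0.2, 0.2), c(er = 1L, tubulin = 2L))
  expect_error(pearson_synapse(stk, full_mask_seg(stk)), "zero variance")
})

test_that("MTOC density equals the brute-force disc oracle voxel for voxel", {
  gen <- generate_coverslip_cell(seed = 23)
  seg <- segment_all(gen$stack)
  for (dia in c(4, 2)) {
    res <- mtoc_density(gen$stack, seg, "er", dia)
    oracle <- mtoc_density_oracle(gen$stack, seg$mtoc_position, "er", dia)
    expect_identical(res$n_voxels, oracle$n)
    expect_equal(res$mean_fluorescence, oracle$mean, tolerance = 1e-12)
  }
  # named presets resolve to the published diameters
  expect_equal(mtoc_density(gen$stack, seg, "er", "A20")$diameter_um, 4)
  expect_equal(mtoc_density(gen$stack, seg, "er", "primary")$diameter_um, 2)
})

test_that("uniform intensity returns the constant for any diameter and position", {
  stk <- cuboid_stack(12, 20, 20, value = 37, voxel_size = c(0.2, 0.2, 0.2))
  seg <- mask_seg(array(TRUE, dim = c(12, 20, 20)), mtoc = c(z = 6, y = 10, x = 10))
  for (dia in c(0.5, 2, 4)) {
    expect_identical(mtoc_density(stk, seg, "er", dia)$mean_fluorescence, 37)
  }
})

test_that("a perinuclear ER pool raises the MTOC-proximal density", {
  lo <- generate_coverslip_cell(coverslip_params(mtoc_pool = 0.05), seed = 3)
  hi <- generate_coverslip_cell(coverslip_params(mtoc_pool = 0.9), seed = 3)
  d_lo <- mtoc_density(lo$stack, segment_all(lo$stack), "er")$mean_fluorescence
  d_hi <- mtoc_density(hi$stack, segment_all(hi$stack), "er")$mean_fluorescence
  expect_gt(d_hi, d_lo)
})

test_that("MTOC at the stack boundary drops the missing neighbor slice", {
  stk <- cuboid_stack(6, 10, 10, value = 5, voxel_size = c(0.2, 0.2, 0.2))
  seg <- mask_seg(array(TRUE, dim = c(6, 10, 10)), mtoc = c(z = 1, y = 5, x = 5))
  expect_warning(res <- mtoc_density(stk, seg, "er", 1), "2 slices")
  expect_equal(res$slices_used, c(1L, 2L))
})

test_that("with a huge diameter the density converges to the 3-slice mean", {
  gen <- generate_coverslip_cell(seed = 29)
  seg <- segment_all(gen$stack)
  res <- mtoc_density(gen$stack, seg, "er", diameter_um = 1e4)
  er <- get_channel(gen$stack, "er")
  zs <- res$slices_used
  expect_equal(res$mean_fluorescence, mean(er[zs, , ]), tolerance = 1e-12)
})

test_that("line scans are flat on constants, peak at the punctum, and reverse", {
  stk <- cuboid_stack(6, 30, 30, value = 11, voxel_size = c(0.2, 0.2, 0.2))
  prof <- line_scan(stk, "er", p0 = c(15, 2), p1 = c(15, 28), z = 3)
  expect_equal(nrow(prof), floor(26) + 1)
  expect_true(all(abs(prof$intensity - 11) < 1e-12))

  gen <- generate_coverslip_cell(seed = 37)
  mtoc <- gen$truth$mtoc_position
  d <- dim(gen$stack$voxels)
  prof2 <- line_scan(gen$stack, "tubulin", p0 = c(mtoc[["y"]], 2),
                     p1 = c(mtoc[["y"]], d[3] - 1), z = mtoc[["z"]])
  peak_x <- 2 + prof2$position_px[which.max(prof2$intensity)]
  expect_lte(abs(peak_x - mtoc[["x"]]), 1)

  rev_prof <- line_scan(gen$stack, "tubulin", p0 = c(mtoc[["y"]], d[3] - 1),
                        p1 = c(mtoc[["y"]], 2), z = mtoc[["z"]])
  expect_equal(rev_prof$intensity, rev(prof2$intensity), tolerance = 1e-12)

  expect_error(line_scan(stk, "er", c(5, 5), c(5, 5), z = 2), "zero-length")
  expect_error(line_scan(stk, "er", c(0, 5), c(5, 5), z = 2), "outside")
})
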