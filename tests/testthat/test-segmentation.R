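test_that("segmentation recovers the painted cell body (Jaccard >= 0.9)", {
  gen <- generate_coverslip_cell(coverslip_params(poisson_noise = FALSE,
                                                  read_noise_sd = 0), seed = 12)
  seg <- segment_cell(gen$stack, "actin")
  truth <- gen$truth$masks$cell_support
  jac <- sum(seg$cell_mask & truth) / sum(seg$cell_mask | truth)
  expect_gte(jac, 0.9)
  # deterministic for fixed input
  seg2 <- segment_cell(gen$stack, "actin")
  expect_identical(seg$cell_mask, seg2$cell_mask)
})

test_that("blank and two-cell images are handled per contract", {
  blank <- image_stack(array(0, dim = c(6, 10, 10, 1)), c(0.2, 0.2, 0.2),
                       c(actin = 1L))
  expect_error(segment_cell(blank, "actin"), "empty mask|flat or blank")

  # two well-separated blobs: keep only the larger, with a warning
  vox <- array(0, dim = c(8, 40, 40, 1))
  vox[2:7, 4:16, 4:16, 1] <- 100    # 13x13 blob
  vox[2:7, 25:31, 25:31, 1] <- 100  # 7x7 blob
  two <- image_stack(vox, c(0.2, 0.2, 0.2), c(actin = 1L))
  expect_warning(seg <- segment_cell(two, "actin", smooth_sigma = c(0, 0, 0)),
                 "keeping the largest")
  lab <- label_components(seg$cell_mask)
  expect_equal(max(lab), 1L)
  expect_true(all(which(seg$cell_mask, arr.ind = TRUE)[, 2] <= 18))
})

test_that("actin footprint matches the analytic disc area and nests in the cell", {
  gen <- generate_coverslip_cell(coverslip_params(poisson_noise = FALSE,
                                                  read_noise_sd = 0), seed = 9)
  seg <- segment_cell(gen$stack, "actin")
  fp <- actin_footprint(gen$stack, seg)
  area <- footprint_area_um2(fp, gen$stack$voxel_size)
  r <- coverslip_params()$cell_radius_um
  expect_lt(abs(area - pi * r^2) / (pi * r^2), 0.10)
  # footprint is a subset of the XY projection of the cell mask
  proj <- apply(seg$cell_mask, c(2, 3), any)
  expect_true(all(proj[fp]))
})

test_that("spreading increases the footprint area", {
  small <- generate_coverslip_cell(coverslip_params(cell_radius_um = 3.5), seed = 2)
  large <- generate_coverslip_cell(coverslip_params(cell_radius_um = 5.5), seed = 2)
  a_small <- footprint_area_um2(
    actin_footprint(small$stack, segment_cell(small$stack, "actin")),
    small$stack$voxel_size
  )
  a_large <- footprint_area_um2(
    actin_footprint(large$stack, segment_cell(large$stack, "actin")),
    large$stack$voxel_size
  )
  expect_gt(a_large, a_small)
})

test_that("MTOC detection lands within 2 voxels of the simulated punctum", {
  for (s in c(1, 7)) {
    gen <- generate_coverslip_cell(seed = s)
    seg <- segment_cell(gen$stack, "actin")
    mtoc <- detect_mtoc(gen$stack, seg)
    expect_lte(sqrt(sum((as.numeric(mtoc) - as.numeric(gen$truth$mtoc_position))^2)), 2)
  }
})

test_that("MTOC ties break deterministically toward the lowest (z, y, x)", {
  vox <- array(0, dim = c(8, 12, 12, 2))
  vox[, , , 1] <- 50                               # actin fill for the mask
  vox[3, 4, 4, 2] <- 100
  vox[6, 9, 9, 2] <- 100                           # identical second punctum
  stk <- image_stack(vox, c(0.2, 0.2, 0.2), c(actin = 1L, tubulin = 2L))
  seg <- mask_seg(array(TRUE, dim = c(8, 12, 12)))
  mtoc <- detect_mtoc(stk, seg, smooth_sigma = c(0, 0, 0))
  expect_equal(unname(mtoc), c(3, 4, 4))
  expect_identical(mtoc, detect_mtoc(stk, seg, smooth_sigma = c(0, 0, 0)))
})

test_that("flat tubulin inside the mask warns and errors are explicit", {
  vox <- array(0, dim = c(6, 10, 10, 2))
  vox[, , , 1] <- 10
  vox[, , , 2] <- 7
  stk <- image_stack(vox, c(0.2, 0.2, 0.2), c(actin = 1L, tubulin = 2L))
  seg <- mask_seg(array(TRUE, dim = c(6, 10, 10)))
  expect_warning(mtoc <- detect_mtoc(stk, seg, smooth_sigma = c(0, 0, 0)),
                 "no contrast")
  expect_equal(unname(mtoc), c(1, 1, 1))
  stk_no_tub <- image_stack(vox[, , , 1, drop = FALSE], c(0.2, 0.2, 0.2),
                            c(actin = 1L))
  expect_error(detect_mtoc(stk_no_tub, seg), "tubulin channel absent")
})

test_that("user-supplied masks bypass thresholding", {
  gen <- generate_coverslip_cell(seed = 4)
  manual <- gen$truth$masks$cell_support
  seg <- segment_cell(gen$stack, mask = manual)
  expect_identical(seg$cell_mask, manual)
  expect_equal(seg$provenance$method, "user mask")
})

test_that("dilating the true cell never shrinks the estimated mask volume", {
  vols <- vapply(c(4.0, 4.6, 5.2), function(r) {
    gen <- generate_coverslip_cell(coverslip_params(cell_radius_um = r), seed = 6)
    sum(segment_cell(gen$stack, "actin")$cell_mask)
  }, 1.0)
  expect_true(all(diff(vols) > 0))
})
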