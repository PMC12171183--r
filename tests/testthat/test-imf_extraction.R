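test_that("cross-kernel erosion matches manual expectations", {
  sq5 <- matrix(TRUE, 5, 5)
  e2 <- erode_slice_roi(sq5, 2)
  expect_equal(sum(e2), 1)
  expect_true(e2[3, 3])
  expect_identical(erode_slice_roi(sq5, 0), sq5)
  expect_false(any(erode_slice_roi(matrix(TRUE, 3, 3), 2)))
  # one erosion of a cross-shaped region keeps only its centre
  cross <- matrix(FALSE, 5, 5); cross[3, ] <- TRUE; cross[, 3] <- TRUE
  e1 <- erode_slice_roi(cross, 1)
  expect_equal(which(e1), which(matrix(seq_len(25), 5, 5) == 13))
})

test_that("slice median follows R's midpoint convention and skips NaN", {
  roi <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  ff <- matrix(c(0.02, 0.03, 0.10, 0.9), 2, 2)
  expect_equal(slice_ff_median(ff, roi), 0.03)
  ff2 <- matrix(c(0.02, 0.04, NaN, 0.9), 2, 2)
  expect_equal(slice_ff_median(ff2, roi), 0.03)   # even-count midpoint
  expect_equal(slice_ff_median(matrix(0.05, 2, 2), matrix(TRUE, 2, 2)), 0.05)
  expect_error(slice_ff_median(ff, matrix(FALSE, 2, 2)), "empty")
  expect_error(slice_ff_median(matrix(NaN, 2, 2), matrix(TRUE, 2, 2)), "NaN")
})

test_that("uniform slice grows to the entire ROI", {
  ff <- matrix(0.04, 20, 20)
  roi <- matrix(FALSE, 20, 20); roi[5:15, 5:15] <- TRUE
  reg <- grow_muscle_region(ff, roi, 0.04, r = 3)
  expect_identical(reg & roi, roi)
})

test_that("radius governs jumps across fat bands (pocket fixture)", {
  fx <- make_pocket_slice()
  med <- slice_ff_median(fx$ff, fx$roi)
  expect_equal(med, 0.03)
  reg20 <- grow_muscle_region(fx$ff, fx$roi, med, r = 20)
  reg5 <- grow_muscle_region(fx$ff, fx$roi, med, r = 5)
  pocket <- fx$roi; pocket[, 1:35] <- FALSE       # right of the band
  expect_true(all(reg20[pocket]))                  # r=20 jumps the band
  expect_false(any(reg5[pocket]))                  # r=5 cannot
  expect_false(any(reg20[, 26:35]))                # band itself never muscle
  # both match the literal fixed-point oracle
  dev <- abs(fx$ff - med); seed <- which(dev == min(dev), arr.ind = TRUE)
  seed <- seed[order(seed[, 1], seed[, 2]), , drop = FALSE][1, ]
  expect_identical(reg20, brute_grow(fx$ff, fx$roi, med, 20, seed))
  expect_identical(reg5, brute_grow(fx$ff, fx$roi, med, 5, seed))
})

test_that("seed choice within the reachable component does not matter", {
  set.seed(99)
  for (i in 1:5) {
    ff <- matrix(runif(400, 0, 0.08), 20, 20)
    roi <- matrix(TRUE, 20, 20)
    med <- slice_ff_median(ff, roi)
    reg <- grow_muscle_region(ff, roi, med, r = 4)
    elig <- which(roi & abs(ff - med) <= med & reg)
    alt <- sample(elig, 1)
    rc <- arrayInd(alt, dim(ff))
    reg2 <- brute_grow(ff, roi, med, 4, c(rc[1], rc[2]))
    expect_identical(reg, reg2)
  }
})

test_that("IMF slice mask is the ROI complement of the grown region", {
  roi <- matrix(FALSE, 10, 10); roi[2:9, 2:9] <- TRUE
  expect_false(any(imf_mask_from_growth(roi, roi)))
  expect_identical(imf_mask_from_growth(roi, matrix(FALSE, 10, 10)), roi)
  part <- roi; part[2:9, 2:5] <- FALSE
  expect_equal(sum(imf_mask_from_growth(roi, part)), 8 * 4)
  expect_error(imf_mask_from_growth(matrix(FALSE, 10, 10), roi), "contained")
})

test_that("small-cluster filter removes components below the threshold", {
  m <- array(FALSE, c(10, 10, 4))
  m[2:4, 2, 2] <- TRUE                    # 3-voxel component
  m[7:9, 7, 2] <- TRUE; m[7:8, 7, 3] <- TRUE   # 5-voxel component
  f <- filter_small_clusters(m, 4, 26)
  expect_equal(sum(f$mask), 5)
  expect_equal(f$removed, 1L)
  expect_identical(filter_small_clusters(m, 1, 26)$mask, m)
  # connectivity semantics for diagonal-touching voxels
  d <- array(FALSE, c(5, 5, 5)); d[2, 2, 2] <- TRUE; d[3, 3, 3] <- TRUE
  expect_equal(filter_small_clusters(d, 4, 6)$removed, 2L)
  expect_equal(filter_small_clusters(d, 4, 26)$removed, 1L)
  expect_false(any(filter_small_clusters(d, 4, 26)$mask))
})

test_that("surviving voxels never increase with min_cluster_voxels", {
  set.seed(3)
  m <- array(runif(12 * 12 * 8) < 0.15, c(12, 12, 8))
  counts <- vapply(1:8, function(k) sum(filter_small_clusters(m, k, 26)$mask),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-slice partition: muscle region and IMF pixels tile the ROI", {
  ph <- generate_phantom(phantom_preset("young", seed = 2))
  res <- extract_imf(ph$ff, ph$mask)
  ax <- res$slice_axis
  for (k in which(res$per_slice$analyzed)[c(3, 10, 20)]) {
    roi <- res$eroded_roi[, , k]
    musc <- res$muscle_region[, , k]
    # pre-filter IMF pixels = roi \ muscle region
    imf_pre <- roi & !musc
    expect_false(any(musc & imf_pre))
    expect_identical(musc | imf_pre, roi)
    # filtered mask is a subset of the pre-filter pixels
    expect_true(all(imf_pre[res$imf_mask[, , k]]))
  }
  expect_false(any(res$imf_mask & res$muscle_region))
})

test_that("uniform low-FF phantom yields an empty IMF mask", {
  sp <- phantom_spec(n_branches = 0L, n_noise_singletons = 0L, seed = 4)
  ph <- generate_phantom(sp)
  expect_false(any(ph$truth))
  res <- extract_imf(ph$ff, ph$mask)
  expect_false(any(res$imf_mask))
})

test_that("extraction is deterministic and respects the slice axis", {
  ph <- generate_phantom(phantom_preset("young", seed = 5))
  r1 <- extract_imf(ph$ff, ph$mask)
  r2 <- extract_imf(ph$ff, ph$mask)
  expect_identical(r1$imf_mask, r2$imf_mask)
  # permuted volume with slice_axis = 1 gives the permuted result
  ffp <- ff_volume(aperm(ph$ff$data, c(3, 1, 2)), ph$ff$spacing[c(3, 1, 2)],
                   slice_axis = 1L)
  mkp <- muscle_mask(aperm(ph$mask$data, c(3, 1, 2)), ph$ff$spacing[c(3, 1, 2)],
                     slice_axis = 1L)
  r3 <- extract_imf(ffp, mkp)
  expect_identical(aperm(r1$imf_mask, c(3, 1, 2)), r3$imf_mask)
})
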