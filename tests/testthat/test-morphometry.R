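flat_ph <- generate_knee_phantom(small_phantom(gap_mm = 5, delta_mm = 0.4))
flat_roi <- roi(flat_ph$truth$roi_slices)

test_that("slice minimum gap matches parallel flat surfaces exactly", {
  d <- slice_min_gap(flat_ph$unloaded, flat_ph$truth$roi_slices[1], flat_roi)
  expect_lte(abs(d - 5), flat_ph$unloaded$spacing[2] / 2 + 1e-9)
  expect_equal(d, flat_ph$truth$per_slice_gap_unloaded_mm[
    flat_ph$truth$roi_slices[1]])
})

test_that("a missing surface yields absent, an invalid index errors", {
  v <- flat_ph$unloaded
  femur_only <- v$data
  femur_only[femur_only == knee_labels()[["tibia"]]] <- 0L
  vf <- label_volume(femur_only, v$spacing)
  expect_true(is.na(slice_min_gap(vf, 1)))
  expect_error(slice_min_gap(v, 999), "invalid slice index")
  expect_error(slice_min_gap(v, 0), "invalid slice index")
})

test_that("slice minimum equals the exhaustive boundary-pair oracle", {
  for (radius in c(25, 40, Inf)) {
    ph <- generate_knee_phantom(small_phantom(
      gap_mm = 5.5, delta_mm = 0.3, condyle_radius = radius,
      spacing = c(2, 0.4, 0.5), shape = c(6L, 64L, 64L)))
    for (s in seq_len(n_slices(ph$unloaded))) {
      got <- slice_min_gap(ph$unloaded, s)
      want <- oracle_slice_min_gap(ph$unloaded$data[s, , ],
                                   ph$unloaded$spacing[2:3])
      if (is.na(want)) expect_true(is.na(got))
      else expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("mBGFT averages contributing slices and skips absent ones", {
  v <- flat_ph$unloaded
  dat <- v$data
  dat[2, , ] <- 0L                            # remove both surfaces in slice 2
  v2 <- label_volume(dat, v$spacing)
  g <- measure_mbgft(v2, roi(c(1, dim(dat)[1])))
  expect_true(is.na(g$per_slice_mm[["2"]]))
  expect_equal(g$n_slices, dim(dat)[1] - 1L)
  expect_equal(g$mbgft_mm, mean(g$per_slice_mm, na.rm = TRUE))

  dat[] <- 0L
  empty <- label_volume(dat, v$spacing)
  expect_error(measure_mbgft(empty, roi(c(1, 2))), "empty measurement")
})

test_that("whole-voxel translation of both masks leaves mBGFT unchanged", {
  v <- flat_ph$unloaded
  g0 <- measure_mbgft(v, flat_roi)$mbgft_mm
  shifted <- array(0L, dim(v$data))
  shifted[, , 3:dim(v$data)[3]] <- v$data[, , 1:(dim(v$data)[3] - 2)]
  shifted[, 4:dim(v$data)[2], ] <- shifted[, 1:(dim(v$data)[2] - 3), ]
  g1 <- measure_mbgft(label_volume(shifted, v$spacing), flat_roi)$mbgft_mm
  expect_equal(g1, g0, tolerance = 1e-12)
})

test_that("doubling the physical spacing doubles all reported distances", {
  v <- flat_ph$unloaded
  g1 <- measure_mbgft(v, flat_roi)
  v2 <- label_volume(v$data, v$spacing * 2)
  g2 <- measure_mbgft(v2, flat_roi)
  expect_equal(g2$per_slice_mm, 2 * g1$per_slice_mm)
  expect_equal(g2$mbgft_mm, 2 * g1$mbgft_mm)
})

test_that("strain follows its defining identities", {
  s <- compute_strain(5.92, 4.98)
  expect_equal(s$delta_mbgft_mm, 0.94)
  expect_equal(s$strain, 0.15878, tolerance = 5e-4)
  expect_equal(s$pct_delta_mbgft, 100 * s$strain)
  expect_equal(compute_strain(4.4, 4.4)$strain, 0)
  expect_warning(sw <- compute_strain(5, 5.3), "widened")
  expect_equal(sw$delta_mbgft_mm, -0.3)
  expect_error(compute_strain(0, 4), "positive")
  expect_error(compute_strain(-2, 4), "positive")
})

test_that("gap measurements feed strain end to end on a phantom", {
  gu <- measure_mbgft(flat_ph$unloaded, flat_roi)
  gl <- measure_mbgft(flat_ph$loaded, flat_roi)
  s <- compute_strain(gu, gl)
  expect_equal(s$delta_mbgft_mm, flat_ph$truth$delta_mbgft_true_mm,
               tolerance = 1e-9)
  expect_equal(s$strain, flat_ph$truth$strain_true, tolerance = 1e-9)
})
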