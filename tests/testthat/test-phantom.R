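test_that("zero load reduction gives bit-identical volumes", {
  ph <- generate_knee_phantom(small_phantom(delta_mm = 0))
  expect_identical(ph$unloaded$data, ph$loaded$data)
  expect_equal(ph$truth$delta_mbgft_true_mm, 0)
  expect_equal(ph$truth$strain_true, 0)
})

test_that("phantom generation is deterministic", {
  p <- small_phantom(condyle_radius = 25, delta_mm = 0.4)
  a <- generate_knee_phantom(p)
  b <- generate_knee_phantom(p)
  expect_identical(a$unloaded$data, b$unloaded$data)
  expect_identical(a$loaded$data, b$loaded$data)
  expect_identical(a$truth, b$truth)
})

test_that("flat-surface phantom realizes the requested gap within half a voxel", {
  for (g0 in c(5, 5.99, 7.31)) {
    ph <- generate_knee_phantom(small_phantom(gap_mm = g0, delta_mm = 0.4))
    expect_lte(abs(ph$truth$mbgft_true_unloaded_mm - g0),
               ph$unloaded$spacing[2] / 2 + 1e-9)
    # flat surfaces: every RoI slice sees the same quantized gap
    gu <- ph$truth$per_slice_gap_unloaded_mm[ph$truth$contributing_slices]
    expect_true(all(gu == gu[1]))
  }
})

test_that("a Subject-1-like flat phantom reproduces the printed strain", {
  # printed gaps 0.50 / 7.31 give strain 0.0684; fine grid so that the
  # quantized truth stays close
  p <- phantom_params(shape = c(6L, 256L, 120L), spacing = c(2, 0.1, 0.25),
                      condyle_radius = Inf, plateau_extent = 24,
                      cartilage_thickness = 2, meniscus_height = 1,
                      bone_height = 8, gap_mm = 7.31, delta_mm = 0.5)
  ph <- generate_knee_phantom(p)
  expect_equal(ph$truth$delta_quantized_mm, 0.5)
  expect_lt(abs(ph$truth$strain_true - 0.0684), 0.002)
})

test_that("curved condyle varies the per-slice gap and matches the voxel oracle", {
  p <- small_phantom(gap_mm = 6, delta_mm = 0.4, condyle_radius = 25,
                     shape = c(10L, 96L, 96L))
  ph <- generate_knee_phantom(p)
  keep <- ph$truth$contributing_slices
  gu <- ph$truth$per_slice_gap_unloaded_mm[keep]
  expect_gt(max(gu) - min(gu), ph$unloaded$spacing[2])  # gap varies
  # exhaustive boundary-pair oracle on the emitted volume agrees with
  # the analytic truth on every contributing slice
  od <- oracle_mbgft(ph$unloaded)
  expect_equal(od[keep], unname(gu), tolerance = 1e-12)
  expect_lte(abs(mean(od[keep]) - ph$truth$mbgft_true_unloaded_mm),
             ph$unloaded$spacing[2] / 2)
})

test_that("loaded volume is a rigid axial femur translation", {
  p <- small_phantom(gap_mm = 5, delta_mm = 0.8, spacing = c(2, 0.4, 0.4))
  ph <- generate_knee_phantom(p)
  dq <- ph$truth$delta_quantized_mm
  expect_equal(dq, round(0.8 / 0.4) * 0.4)
  rows_shift <- as.integer(round(dq / 0.4))
  fem <- knee_labels()[["femur"]]
  u <- ph$unloaded$data; l <- ph$loaded$data
  nr <- dim(u)[2]
  shifted <- array(0L, dim(u))
  shifted[, (rows_shift + 1):nr, ] <- u[, 1:(nr - rows_shift), ]
  expect_identical(l == fem, shifted == fem)
  # tibia side untouched
  tib <- knee_labels()[["tibia"]]
  expect_identical(u == tib, l == tib)
})

test_that("invalid phantom parameters are rejected", {
  expect_error(small_phantom(gap_mm = 5, delta_mm = 5), "delta_mm")
  expect_error(small_phantom(gap_mm = 2.4, delta_mm = 0.5), "cartilage")
  expect_error(phantom_params(shape = c(4, 16, 16), spacing = c(2, 0.4, 0.4),
                              plateau_extent = 24, gap_mm = 5,
                              delta_mm = 0.5),
               "too small")
})

test_that("phantom volumes survive a NIfTI round trip with truth sidecar", {
  ph <- generate_knee_phantom(small_phantom(shape = c(4L, 64L, 64L)))
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  back <- read_label_volume(file.path(dir, "unloaded.nii.gz"))
  expect_identical(back$data, ph$unloaded$data)
  expect_equal(back$spacing, ph$unloaded$spacing, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$strain_true, ph$truth$strain_true, tolerance = 1e-12)
})

test_that("synthetic sweep tables follow the generating power law", {
  # exact at zero noise, including the unit-stiffness anchor
  sp <- sweep_noise_spec(a_gen = 0.2196, b_gen = -0.8495, noise_sd = 0,
                         grid = c(1, 2, 3, 5, 10, 15, 20, 25, 30, 50))
  tab <- generate_sweep_table(sp)
  expect_equal(tab$strain[tab$stiffness_mpa == 1], 0.2196)
  expect_true(all(diff(tab$strain) < 0))
  expect_equal(tab$strain, 0.2196 * tab$stiffness_mpa^-0.8495)

  # seeded noise is reproducible and leaves the session RNG alone
  spn <- sweep_noise_spec(0.22, -0.85, noise_sd = 0.01, seed = 42L)
  set.seed(1); before <- runif(1)
  t1 <- generate_sweep_table(spn)
  t2 <- generate_sweep_table(spn)
  expect_identical(t1, t2)
  set.seed(1); expect_identical(runif(1), before)
})

test_that("noisy sweeps are recovered by the fit within 3 standard errors", {
  spn <- sweep_noise_spec(0.2279, -0.8315, noise_sd = 0.01, seed = 7L)
  fit <- fit_power_law(generate_sweep_table(spn))
  expect_lt(abs(fit$a - 0.2279), 3 * fit$se[["a"]])
  expect_lt(abs(fit$b - -0.8315), 3 * fit$se[["b"]])
})

test_that("sweep-spec invariants are enforced", {
  expect_error(sweep_noise_spec(-1, -0.8))
  expect_error(sweep_noise_spec(0.2, 0.8))
  expect_error(sweep_noise_spec(0.2, -0.8, grid = c(5, 3, 1)))
})
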