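test_that("reference cohort stores the six sessions verbatim", {
  ref <- reference_sessions()
  expect_equal(nrow(ref), 6L)
  expect_setequal(unique(ref$subject),
                  c("Subject 1", "Subject 2", "Subject 3"))

  s3r <- ref[ref$session == "Subject 3 repeat", ]
  expect_equal(s3r$mbgft_unloaded_mm, 6.54)
  expect_equal(s3r$mbgft_loaded_mm, 5.88)
  expect_equal(s3r$delta_mbgft_mm, 0.67)

  s2r <- ref[ref$session == "Subject 2 repeat", ]
  expect_equal(s2r$coef_a, 0.3334)
  expect_equal(s2r$coef_b, -0.8036)
  expect_equal(s2r$force_n, 340)

  # full-table checksum: any silent edit of a printed value fails here
  expect_equal(sum(ref$mbgft_unloaded_mm), 35.98)
  expect_equal(sum(ref$mbgft_model_mm), 36.00)
  expect_equal(sum(ref$delta_mbgft_mm), 3.73)
  expect_equal(sum(ref$strain), 0.63064)
  expect_equal(sum(ref$coef_a), 1.3176)
  expect_equal(sum(ref$coef_b), -5.0972)
  expect_equal(sum(ref$ccs_mpa), 14.4232)
  expect_equal(sum(ref$force_n), 2180)
})

test_that("the conflicting printed row labels are kept and flagged", {
  ref <- reference_sessions()
  # the second row of the stiffness table is printed "Subject2 repeat"
  # although its gap values belong to Subject 1's repeat scan, and its
  # mBGFT differs between the two printed tables (5.64 vs 5.66)
  row2 <- ref[2, ]
  expect_equal(row2$session, "Subject 1 repeat")
  expect_equal(row2$printed_label_model, "Subject2 repeat")
  expect_true(row2$label_conflict)
  expect_equal(row2$mbgft_unloaded_mm, 5.64)
  expect_equal(row2$mbgft_model_mm, 5.66)
  expect_equal(sum(ref$label_conflict), 1L)
})

test_that("cohort constants carry both printed summary variants", {
  cc <- reference_constants()
  expect_equal(cc$generalized_a, 0.2196)
  expect_equal(cc$generalized_b, -0.8495)
  expect_equal(cc$ccs_mean_mpa, 2.4039)
  expect_equal(cc$ccs_sd_mpa, 0.172)
  # the discussion section prints a different cohort summary; both are
  # kept, downstream checks target the recomputable table value
  expect_equal(cc$ccs_mean_discussion_mpa, 2.45)
  expect_equal(cc$stiffness_grid_mpa, c(1, 2, 3, 5, 10, 15, 20, 25, 30, 50))
})
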