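ref <- reference_sessions()

test_that("noise-free tables are recovered exactly with R^2 = 1", {
  tab <- generate_sweep_table(sweep_noise_spec(0.2279, -0.8315))
  fit <- fit_power_law(tab)
  expect_equal(fit$a, 0.2279, tolerance = 1e-10)
  expect_equal(fit$b, -0.8315, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_power_law(data.frame(stiffness_mpa = 1:2,
                                        strain = c(0.2, 0.1))),
               "at least 3")
  expect_error(fit_power_law(data.frame(stiffness_mpa = 1:4,
                                        strain = c(0.2, 0.1, -0.1, 0.05))),
               "positive")
  # non-converged rows (NA strain) are dropped, not fitted
  tab <- generate_sweep_table(sweep_noise_spec(0.2, -0.8))
  tab$strain[1] <- NA
  fit <- fit_power_law(tab)
  expect_equal(fit$n, nrow(tab) - 1L)
  expect_equal(fit$b, -0.8, tolerance = 1e-10)
})

test_that("prediction and inversion are exact algebraic inverses", {
  fit <- power_law_fit(a = 0.2196, b = -0.8495)
  expect_equal(predict_strain(fit, 1), 0.2196)
  for (E in c(0.5, 1, 2.657, 10, 47.3, 100)) {
    eps <- predict_strain(fit, E)
    expect_equal(estimate_stiffness(fit, eps)$stiffness_mpa, E,
                 tolerance = 1e-12)
  }
  expect_equal(predict_strain(power_law_fit(0.1527, -0.8223), 2.657),
               0.0684, tolerance = 1e-3)
  expect_error(predict_strain(fit, -1), "positive")
  expect_error(estimate_stiffness(fit, 0), "positive")
  # strain equal to the scaling coefficient inverts to exactly 1 MPa
  expect_equal(estimate_stiffness(fit, 0.2196)$stiffness_mpa, 1)
})

test_that("published subject rows invert to the printed stiffness estimates", {
  for (i in seq_len(nrow(ref))) {
    est <- estimate_stiffness(power_law_fit(ref$coef_a[i], ref$coef_b[i]),
                              ref$strain[i], session = ref$session[i])
    expect_lt(abs(est$stiffness_mpa - ref$ccs_mpa[i]) / ref$ccs_mpa[i],
              5e-3)
  }
})

test_that("the generalized model averages coefficients arithmetically", {
  fits <- Map(power_law_fit, ref$coef_a, ref$coef_b)
  gen <- generalized_model(fits)
  expect_equal(round(gen$a, 4), 0.2196)
  expect_equal(round(gen$b, 4), -0.8495)
  expect_true(is.na(gen$r_squared))

  single <- power_law_fit(0.2, -0.8, r_squared = 0.998)
  expect_identical(generalized_model(list(single)), single)
  expect_error(generalized_model(list()), "at least one")

  # cohort mean strain pushed through the generalized model
  est <- estimate_stiffness(gen, 0.1051, source = "generalized")
  expect_equal(est$stiffness_mpa, (0.1051 / gen$a)^(1 / gen$b),
               tolerance = 1e-12)
  expect_equal(est$stiffness_mpa, 2.38, tolerance = 0.01)
})

test_that("scaling all strains rescales a and leaves b unchanged", {
  tab <- generate_sweep_table(sweep_noise_spec(0.18, -0.91))
  f1 <- fit_power_law(tab)
  tab$strain <- tab$strain * 3.7
  f2 <- fit_power_law(tab)
  expect_equal(f2$a, 3.7 * f1$a, tolerance = 1e-9)
  expect_equal(f2$b, f1$b, tolerance = 1e-9)
})

test_that("cohort summary reproduces published mean, SD and repeatability", {
  est <- data.frame(session = ref$session, stiffness_mpa = ref$ccs_mpa)
  cs <- cohort_summary(est, reference_pairs())
  expect_equal(cs$mean_mpa, 2.4039, tolerance = 1e-4)
  expect_equal(cs$sd_mpa, 0.172, tolerance = 1e-3)
  expect_equal(unname(cs$intra_subject_mpa),
               c(0.277, 0.12, 0.1518), tolerance = 1e-9)
  # population SD option
  csp <- cohort_summary(est, sd_type = "population")
  expect_equal(csp$sd_mpa, sd(ref$ccs_mpa) * sqrt(5 / 6), tolerance = 1e-12)
  # identical pair and degenerate cases
  two <- data.frame(session = c("a", "b"), stiffness_mpa = c(2.4, 2.4))
  expect_equal(unname(cohort_summary(two, list(s = c("a", "b")))
                      $intra_subject_mpa), 0)
  one <- cohort_summary(data.frame(session = "a", stiffness_mpa = 2.2))
  expect_true(is.na(one$sd_mpa))
  expect_error(cohort_summary(est, list(bad = c("a", "nope"))),
               "unknown session")
})

test_that("noisy sweeps recover b with small median error and honest SEs", {
  b_gen <- -0.8495
  errs <- numeric(60)
  cover <- logical(60)
  for (k in seq_len(60)) {
    tab <- generate_sweep_table(
      sweep_noise_spec(0.2196, b_gen, noise_sd = 0.02, seed = 1000L + k))
    fit <- fit_power_law(tab)
    errs[k] <- abs(fit$b - b_gen)
    cover[k] <- abs(fit$b - b_gen) <= 3 * fit$se[["b"]]
  }
  expect_lt(median(errs), 0.02)
  expect_gte(mean(cover), 0.95)
})
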