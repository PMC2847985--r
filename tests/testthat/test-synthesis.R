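test_that("noise-free identity-pose acquisitions round-trip every map", {
  tpl <- default_template()
  les <- make_lesion(tpl, "24h", 0.95, rng_seed = 42)
  raw <- synthesize_subject(tpl, lesion = les, noise_sigma = 0)
  br <- raw$brain_mask_native
  gt <- raw$ground_truth

  t2 <- fit_t2_map(raw$echo_train, raw$echo_times_ms, mask = br,
                   geometry = tpl$geometry)
  sel <- t2$validity & gt$t2_ms > 0
  expect_true(all(sel[br]))
  expect_lt(max(abs(t2$values[sel] - gt$t2_ms[sel]) / gt$t2_ms[sel]), 1e-6)

  adc <- compute_adc_map(raw$dwi_b0, raw$dwi_bpos, mask = br)
  sel <- adc$validity & gt$adc_mm2_per_s > 0
  expect_lt(max(abs(adc$values[sel] - gt$adc_mm2_per_s[sel]) /
                gt$adc_mm2_per_s[sel]), 1e-6)

  t1 <- fit_t1_map(raw$ir_series, raw$inversion_times_ms, mask = br,
                   geometry = tpl$geometry)
  sel <- t1$validity & gt$t1_ms > 0
  expect_lt(max(abs(t1$values[sel] - gt$t1_ms[sel]) / gt$t1_ms[sel]), 1e-6)

  cbf <- compute_cbf_map(raw$casl_control, raw$casl_label, t1, mask = br)
  sel <- cbf$validity & gt$cbf_ml_per_100g_min > 0
  expect_lt(max(abs(cbf$values[sel] - gt$cbf_ml_per_100g_min[sel]) /
                gt$cbf_ml_per_100g_min[sel]), 1e-6)
})

test_that("identical seeds reproduce acquisitions bit-for-bit", {
  tpl <- default_template()
  a <- synthesize_subject(tpl, noise_sigma = 25, seed = 99)
  b <- synthesize_subject(tpl, noise_sigma = 25, seed = 99)
  expect_identical(a$echo_train, b$echo_train)
  expect_identical(a$dwi_bpos, b$dwi_bpos)
  expect_identical(a$casl_label, b$casl_label)
  expect_identical(a$ir_series, b$ir_series)
  c <- synthesize_subject(tpl, noise_sigma = 25, seed = 100)
  expect_false(identical(a$dwi_b0, c$dwi_b0))
  # a sequence's draws do not depend on which other sequences are simulated
  d <- synthesize_subject(tpl, noise_sigma = 25, seed = 99, sequences = "dwi")
  expect_identical(a$dwi_b0, d$dwi_b0)
})

test_that("magnitude background noise follows the Rayleigh limit", {
  zero <- array(0, dim = c(100, 100, 20))
  noisy <- add_noise(zero, sigma = 10, seed = 5)
  expect_true(all(noisy >= 0))
  expect_lt(abs(mean(noisy) - 10 * sqrt(pi / 2)) / (10 * sqrt(pi / 2)), 0.01)
  gauss <- add_noise(zero, sigma = 10, seed = 5, model = "gaussian")
  expect_lt(abs(mean(gauss)), 0.1)
})

test_that("negative noise sigma is rejected", {
  tpl <- default_template()
  expect_error(synthesize_subject(tpl, noise_sigma = -1), "non-negative")
  expect_error(add_noise(array(0, c(2, 2, 2)), -0.1, 1), "non-negative")
})

test_that("degenerate cohorts (zero SD, zero noise) give identical subjects", {
  tpl <- default_template()
  spec <- cohort_spec(n_subjects = 3L, strain_label = "Sv/129",
                      noise_sigma = 0, fraction_sd = 0,
                      cv = c(t2 = 0, t1 = 0, adc = 0, cbf = 0, s0 = 0),
                      misalignment_rot_deg = 0, misalignment_trans_vox = 0)
  cohort <- synthesize_cohort(tpl, spec, master_seed = 4, sequences = "dwi")
  b0 <- lapply(cohort$subjects, function(s) s$timepoints[["24h"]]$dwi_b0)
  expect_identical(b0[[1]], b0[[2]])
  expect_identical(b0[[1]], b0[[3]])
})

test_that("cohorts are reproducible from the master seed", {
  tpl <- default_template()
  spec <- cohort_spec(n_subjects = 2L, noise_sigma = 25)
  a <- synthesize_cohort(tpl, spec, master_seed = 11, sequences = "dwi")
  b <- synthesize_cohort(tpl, spec, master_seed = 11, sequences = "dwi")
  for (i in seq_along(a$subjects)) {
    expect_identical(a$subjects[[i]]$timepoints[["2h"]]$dwi_b0,
                     b$subjects[[i]]$timepoints[["2h"]]$dwi_b0)
    expect_identical(a$subjects[[i]]$lesion$lesion_mask_24h,
                     b$subjects[[i]]$lesion$lesion_mask_24h)
    expect_identical(a$subjects[[i]]$multipliers, b$subjects[[i]]$multipliers)
  }
})

test_that("lesion nesting survives the whole generative model", {
  tpl <- default_template()
  spec <- cohort_spec(n_subjects = 4L, noise_sigma = 0)
  cohort <- synthesize_cohort(tpl, spec, master_seed = 21, sequences = "dwi")
  for (s in cohort$subjects)
    expect_false(any(s$lesion$lesion_mask_2h & !s$lesion$lesion_mask_24h))
})
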