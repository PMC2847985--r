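make_t2_map <- function(values, validity = NULL, geometry = NULL) {
  if (is.null(validity)) validity <- array(TRUE, dim = dim(values))
  quantitative_map(values, "ms", validity, geometry)
}

test_that("threshold segmentation matches phantom ground truth exactly", {
  tpl <- default_template()
  les <- make_lesion(tpl, "24h", 0.95, rng_seed = 2)
  raw <- synthesize_subject(tpl, lesion = les, noise_sigma = 0,
                            sequences = "cpmg")
  t2 <- fit_t2_map(raw$echo_train, raw$echo_times_ms,
                   mask = raw$brain_mask_native, geometry = tpl$geometry)
  seg <- segment_infarct_t2(t2, 34, raw$brain_mask_native)
  expect_identical(array(seg$mask, dim = dim(les)),
                   array(les & TRUE, dim = dim(les)))
})

test_that("the 34 ms comparison is strict and configurable", {
  dm <- c(6, 6, 3)
  brain <- array(TRUE, dim = dm)
  at_threshold <- make_t2_map(array(34, dim = dm))
  expect_equal(sum(segment_infarct_t2(at_threshold, 34, brain)$mask), 0)
  low <- make_t2_map(array(10, dim = dm))
  expect_identical(segment_infarct_t2(low, 34, brain)$mask, brain)
  # inverted contrast convention: infarct above the threshold
  high <- make_t2_map(array(60, dim = dm))
  expect_identical(segment_infarct_t2(high, 34, brain, below = FALSE)$mask,
                   brain)
  expect_error(segment_infarct_t2(
    compute_adc_map(array(1, dm), array(1, dm)), 34, brain), "ms")
})

test_that("masks grow monotonically with the threshold", {
  tpl <- default_template()
  raw <- synthesize_subject(tpl, lesion = make_lesion(tpl, "24h", 0.6, 3),
                            noise_sigma = 25, seed = 12, sequences = "cpmg")
  t2 <- fit_t2_map(raw$echo_train, raw$echo_times_ms,
                   mask = raw$brain_mask_native, geometry = tpl$geometry)
  prev <- NULL
  for (thr in c(20, 30, 34, 40, 60)) {
    cur <- segment_infarct_t2(t2, thr, raw$brain_mask_native)$mask
    if (!is.null(prev)) expect_false(any(prev & !cur))
    prev <- cur
  }
})

test_that("CSF removal subtracts ventricles and is idempotent", {
  dm <- c(8, 8, 3)
  m <- binary_lesion_mask(array(TRUE, dim = dm), "t2_threshold", 34)
  vent <- array(FALSE, dim = dm); vent[1:2, 1:2, 1] <- TRUE
  none <- remove_csf(m, array(FALSE, dim = dm))
  expect_identical(none$mask, m$mask)
  once <- remove_csf(m, vent)
  expect_equal(sum(once$mask), prod(dm) - sum(vent))
  twice <- remove_csf(once, vent)
  expect_identical(twice$mask, once$mask)
  inside <- binary_lesion_mask(vent, "t2_threshold", 34)
  expect_equal(sum(remove_csf(inside, vent)$mask), 0)
})

test_that("manual-emulated segmentation returns ground truth with rater error", {
  tpl <- default_template()
  gt <- lesion_ground_truth(tpl, 0.5, 0.9, rng_seed = 6)
  exact <- segment_manual_emulated(gt, "24h", rater_error_vox = 0)
  expect_identical(exact$mask, array(gt$lesion_mask_24h & TRUE,
                                     dim = dim(gt$lesion_mask_24h)))
  expect_identical(exact$method, "manual_emulated")
  dil <- segment_manual_emulated(gt, "24h", rater_error_vox = 1)
  expect_false(any(exact$mask & !dil$mask))
  expect_gt(sum(dil$mask), sum(exact$mask))
  ero <- segment_manual_emulated(gt, "24h", rater_error_vox = -1)
  expect_false(any(ero$mask & !exact$mask))
  expect_error(segment_manual_emulated(list(), "24h"), "ground truth")
})

test_that("volume ratios count lesion voxels against the ipsilateral hemisphere", {
  tpl <- default_template()
  hemi <- template_mask(tpl, "right_hemisphere")
  full <- binary_lesion_mask(hemi, "manual_emulated")
  expect_equal(volume_ratio(full, tpl)$ratio, 1.0)
  empty <- binary_lesion_mask(array(FALSE, dim = dim(hemi)), "manual_emulated")
  expect_equal(volume_ratio(empty, tpl)$ratio, 0.0)

  # a lesion built to occupy a set fraction of the hemisphere
  k <- round(0.43 * sum(hemi))
  les <- array(FALSE, dim = dim(hemi))
  les[which(hemi)[seq_len(k)]] <- TRUE
  vr <- volume_ratio(binary_lesion_mask(les, "manual_emulated"), tpl)
  expect_equal(vr$ratio, k / sum(hemi))
  expect_lt(abs(vr$ratio - 0.43), 1 / sum(hemi))
  expect_equal(vr$lesion_voxels, k)
  expect_equal(vr$voxel_volume_mm3, voxel_volume_mm3(tpl$geometry))
})
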