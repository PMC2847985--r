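test_that("brain extraction passes ground truth through and works automatically", {
  tpl <- default_template()
  raw <- synthesize_subject(tpl, noise_sigma = 0, sequences = "dwi")
  gt <- extract_brain(raw$dwi_b0, "ground_truth",
                      ground_truth_mask = raw$brain_mask_native)
  expect_identical(gt$mask, array(raw$brain_mask_native & TRUE,
                                  dim = dim(raw$brain_mask_native)))
  auto <- extract_brain(raw$dwi_b0, "automatic")
  expect_gte(dice_coefficient(auto$mask, gt$mask), 0.98)
  expect_error(extract_brain(array(0, c(8, 8, 3)), "automatic"), "constant")
})

test_that("self-registration returns the identity pose", {
  tpl <- default_template()
  est <- register_rigid(tpl$reference, tpl$reference, tpl$geometry,
                        tpl$geometry, fixed_mask = template_mask(tpl, "brain"))
  expect_lt(max(abs(est$rotations_deg)), 1e-3)
  expect_lt(max(abs(est$translations_mm)), 1e-3)
  expect_gte(attr(est, "metric_final"), attr(est, "metric_initial") - 1e-9)
})

test_that("registering A to B and B to A gives mutually inverse transforms", {
  tpl <- default_template()
  mis <- rigid_transform(c(2, -1.5, 3), c(0.8, -0.6, 0.5))
  raw <- synthesize_subject(tpl, noise_sigma = 0, misalignment = mis)
  ab <- register_rigid(raw$dwi_b0, tpl$reference, tpl$geometry, tpl$geometry,
                       fixed_mask = template_mask(tpl, "brain"))
  ba <- register_rigid(tpl$reference, raw$dwi_b0, tpl$geometry, tpl$geometry,
                       fixed_mask = raw$brain_mask_native)
  comp <- compose_transforms(ab, ba)
  expect_lt(max(abs(comp$rotations_deg)), 0.5)
  sp <- grid_spacing(tpl$geometry)
  expect_lt(max(abs(comp$translations_mm) / sp), 0.2)
})

test_that("degenerate images are rejected", {
  g <- acq_geometry(matrix_size = c(16, 16), n_slices = 5)
  flat <- array(1, dim = c(16, 16, 5))
  expect_error(register_rigid(flat, flat, g, g), "constant")
})

test_that("misaligned subjects land on the atlas with high lesion overlap", {
  tpl <- default_template()
  les <- make_lesion(tpl, "24h", 0.95, rng_seed = 5)
  mis <- rigid_transform(c(-3, 1.5, 4), c(-1, 0.7, 0.3))
  raw <- synthesize_subject(tpl, lesion = les, noise_sigma = 25,
                            misalignment = mis, seed = 23)
  est <- register_rigid(raw$dwi_b0, tpl$reference, tpl$geometry, tpl$geometry,
                        fixed_mask = template_mask(tpl, "brain"))
  t2 <- fit_t2_map(raw$echo_train, raw$echo_times_ms,
                   mask = raw$brain_mask_native, geometry = tpl$geometry)
  atl <- to_atlas(list(t2 = t2), masks = list(brain = raw$brain_mask_native),
                  transform = est, template = tpl,
                  map_interpolation = "nearest")
  expect_identical(dim(atl$maps$t2$values), grid_dim(tpl$geometry))
  seg <- remove_csf(
    segment_infarct_t2(atl$maps$t2, 34,
                       atl$masks$brain & template_mask(tpl, "brain")),
    template_mask(tpl, "ventricle"))
  expect_gte(dice_coefficient(seg$mask, array(les & TRUE, dim = dim(les))),
             0.95)
})

test_that("to_atlas maps everything onto the template grid with identity pose", {
  tpl <- default_template()
  raw <- synthesize_subject(tpl, noise_sigma = 0)
  t2 <- fit_t2_map(raw$echo_train, raw$echo_times_ms,
                   mask = raw$brain_mask_native, geometry = tpl$geometry)
  adc <- compute_adc_map(raw$dwi_b0, raw$dwi_bpos,
                         mask = raw$brain_mask_native, geometry = tpl$geometry)
  atl <- to_atlas(list(t2 = t2, adc = adc),
                  masks = list(brain = raw$brain_mask_native),
                  transform = rigid_transform(), template = tpl,
                  map_interpolation = "nearest")
  expect_length(atl$maps, 2)
  for (m in atl$maps) expect_identical(dim(m$values), grid_dim(tpl$geometry))
  sel <- t2$validity
  expect_lt(max(abs(atl$maps$t2$values[sel] - t2$values[sel])), 1e-6)
})
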