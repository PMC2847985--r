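test_that("template contains all six label classes with disjoint ROIs", {
  tpl <- default_template()
  codes <- sort(unique(as.integer(tpl$labels)))
  expect_identical(codes, as.integer(atlas_labels()))
  ctx <- template_mask(tpl, "cortex_mca")
  sub <- template_mask(tpl, "subcortex")
  vent <- template_mask(tpl, "ventricle")
  expect_gt(sum(ctx), 0)
  expect_gt(sum(sub), 0)
  expect_gt(sum(vent), 0)
  expect_false(any(ctx & sub))
  expect_false(any(vent & (ctx | sub)))
})

test_that("both ROIs lie entirely in the right (ipsilateral) hemisphere", {
  tpl <- default_template()
  rh <- template_mask(tpl, "right_hemisphere")
  expect_true(all(rh[template_mask(tpl, "cortex_mca")]))
  expect_true(all(rh[template_mask(tpl, "subcortex")]))
  lh <- template_mask(tpl, "left_hemisphere")
  expect_false(any(lh & rh))
  expect_identical(lh | rh, template_mask(tpl, "brain"))
})

test_that("template construction is deterministic and scales to other grids", {
  g <- acq_geometry(matrix_size = c(32, 32), n_slices = 9)
  a <- build_template(g)
  b <- build_template(g)
  expect_identical(a$labels, b$labels)
  expect_identical(a$reference, b$reference)
  expect_identical(sort(unique(as.integer(a$labels))), as.integer(atlas_labels()))
})

test_that("matrices too small to host the labels are rejected", {
  expect_error(build_template(acq_geometry(matrix_size = c(12, 12), n_slices = 5)),
               "too small")
})
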