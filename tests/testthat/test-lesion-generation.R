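test_that("boundary cortical fractions give exactly the expected extents", {
  tpl <- default_template()
  sub <- template_mask(tpl, "subcortex")
  ctx <- template_mask(tpl, "cortex_mca")

  l0 <- make_lesion(tpl, "2h", cortical_fraction = 0, rng_seed = 1)
  expect_identical(array(l0 & TRUE, dim = dim(sub)), sub)

  l1 <- make_lesion(tpl, "24h", cortical_fraction = 1, rng_seed = 1)
  expect_true(all(l1[ctx | sub]))
})

test_that("the realized cortical fraction matches the request to one voxel", {
  tpl <- default_template()
  ctx <- template_mask(tpl, "cortex_mca")
  for (f in c(0.25, 0.6, 0.95)) {
    les <- make_lesion(tpl, "2h", cortical_fraction = f, rng_seed = 7)
    got <- sum(les & ctx) / sum(ctx)
    expect_lt(abs(got - f), 1 / sum(ctx) + 1e-12)
  }
})

test_that("lesions grow as a connected region from the subcortex", {
  tpl <- default_template()
  les <- make_lesion(tpl, "24h", cortical_fraction = 0.5, rng_seed = 3)
  # every lesion voxel is reachable from the subcortex within the lesion
  reach <- template_mask(tpl, "subcortex")
  repeat {
    nxt <- strokemri:::dilate6(reach) & les
    if (sum(nxt) == sum(reach)) break
    reach <- nxt
  }
  expect_identical(sum(reach), sum(les))
})

test_that("2 h lesions nest inside 24 h lesions for any seed", {
  tpl <- default_template()
  for (seed in 1:100) {
    f2 <- runif(1, 0, 1)
    f24 <- runif(1, f2, 1)
    gt <- lesion_ground_truth(tpl, f2, f24, rng_seed = seed)
    expect_false(any(gt$lesion_mask_2h & !gt$lesion_mask_24h))
  }
})

test_that("lesion generation rejects fractions outside [0, 1]", {
  tpl <- default_template()
  expect_error(make_lesion(tpl, "2h", cortical_fraction = -0.1), "\\[0, 1\\]")
  expect_error(make_lesion(tpl, "2h", cortical_fraction = 1.2), "\\[0, 1\\]")
})
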