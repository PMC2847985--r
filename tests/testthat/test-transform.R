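test_that("rigid transforms compose and invert to identity", {
  set.seed(12)
  for (k in 1:25) {
    tr <- rigid_transform(runif(3, -15, 15), runif(3, -4, 4))
    id <- compose_transforms(invert_transform(tr), tr)
    expect_lt(max(abs(id$rotations_deg)), 1e-10)
    expect_lt(max(abs(id$translations_mm)), 1e-10)
  }
})

test_that("composition matches sequential application on points", {
  a <- rigid_transform(c(4, -2, 7), c(1, 0.5, -1))
  b <- rigid_transform(c(-1, 3, 2), c(-0.2, 1, 0.4))
  w <- matrix(rnorm(30), ncol = 3)
  expect_equal(apply_transform(compose_transforms(b, a), w),
               apply_transform(b, apply_transform(a, w)), tolerance = 1e-12)
})

test_that("transform JSON serialization round-trips", {
  tr <- rigid_transform(c(3.25, -1.5, 0.75), c(0.4, -1.2, 2))
  f <- tempfile(fileext = ".json")
  write_transform_json(tr, f)
  back <- read_transform_json(f)
  expect_equal(back$rotations_deg, tr$rotations_deg)
  expect_equal(back$translations_mm, tr$translations_mm)
})

test_that("identity nearest resampling is bit-exact", {
  g <- acq_geometry(matrix_size = c(32, 32), n_slices = 7)
  vol <- array(rnorm(32 * 32 * 7), dim = c(32, 32, 7))
  out <- resample_volume(vol, rigid_transform(), g, g, "nearest")
  expect_identical(array(out, dim = dim(vol)), vol)
  expect_true(all(attr(out, "valid")))
})

test_that("integer voxel shifts restore interior voxels exactly", {
  g <- acq_geometry(matrix_size = c(32, 32), n_slices = 7)
  vol <- array(seq_len(32 * 32 * 7), dim = c(32, 32, 7)) * 1.0
  sp <- grid_spacing(g)
  fwd <- rigid_transform(translations_mm = c(sp[1], 0, 0))
  shifted <- resample_volume(vol, fwd, g, g, "nearest")
  back <- resample_volume(array(shifted, dim = dim(vol)),
                          invert_transform(fwd), g, g, "nearest")
  interior <- array(FALSE, dim = dim(vol))
  interior[3:30, 3:30, 2:6] <- TRUE
  expect_identical(back[interior], vol[interior])
})

test_that("out-of-field voxels take the fill value and are marked invalid", {
  g <- acq_geometry(matrix_size = c(16, 16), n_slices = 5)
  vol <- array(1, dim = c(16, 16, 5))
  out <- resample_volume(vol, rigid_transform(translations_mm = c(5, 0, 0)),
                         g, g, "trilinear", fill = -7)
  valid <- attr(out, "valid")
  expect_true(any(!valid))
  expect_true(all(out[!valid] == -7))
  expect_true(all(abs(out[valid] - 1) < 1e-12))
})

test_that("trilinear interpolation of label volumes is guarded", {
  g <- acq_geometry(matrix_size = c(16, 16), n_slices = 5)
  lab <- array(FALSE, dim = c(16, 16, 5)); lab[8, 8, 3] <- TRUE
  expect_error(resample_volume(lab, rigid_transform(), g, g, "trilinear"),
               "nearest")
  expect_warning(resample_volume(lab, rigid_transform(), g, g, "trilinear",
                                 allow_label_trilinear = TRUE), "nearest")
})
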