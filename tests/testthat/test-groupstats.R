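test_that("probability maps are the voxel-wise mean of the binary masks", {
  dm <- c(6, 6, 2)
  masks <- lapply(1:8, function(i) {
    m <- array(FALSE, dim = dm)
    m[1, 1, 1] <- TRUE            # all subjects
    if (i == 1) m[2, 2, 1] <- TRUE # one subject
    if (i <= 3) m[3, 3, 2] <- TRUE # three subjects
    m
  })
  pm <- probability_map(masks, "test", "24h")
  expect_equal(pm$values[1, 1, 1], 1.0)
  expect_equal(pm$values[2, 2, 1], 0.125)
  expect_equal(pm$values[3, 3, 2], 0.375)
  expect_equal(pm$n_subjects, 8)
  # quantization: every value a multiple of 1/n
  expect_true(all(abs(pm$values * 8 - round(pm$values * 8)) < 1e-12))
  expect_error(probability_map(list()), "at least one")
})

test_that("ROI probability summaries reduce exactly like the probability map", {
  tpl <- default_template()
  roi <- template_mask(tpl, "subcortex")
  set.seed(44)
  masks <- lapply(1:8, function(i) {
    m <- array(FALSE, dim = dim(roi))
    keep <- which(roi)[runif(sum(roi)) < runif(1)]
    m[keep] <- TRUE
    m
  })
  rs <- roi_probability(masks, roi)
  pm <- probability_map(masks)
  # conservation: the group mean of per-subject ROI fractions equals the ROI
  # mean of the probability map (algebraic identity)
  expect_equal(rs$mean, 100 * mean(pm$values[roi]), tolerance = 1e-12)
  expect_equal(rs$n, 8)
})

test_that("ROI probability mean and SEM match hand computation", {
  dm <- c(10, 1, 1)
  roi <- array(TRUE, dim = dm)
  fracs <- c(40, 50, 50, 60, 50, 60, 50, 70)
  masks <- lapply(fracs, function(f) {
    m <- array(FALSE, dim = dm)
    m[seq_len(f / 10), 1, 1] <- TRUE
    m
  })
  rs <- roi_probability(masks, roi)
  expect_equal(rs$mean, 53.75)
  expect_equal(rs$sem, 3.23898, tolerance = 1e-5)
  expect_error(roi_probability(masks, array(FALSE, dim = dm)), "empty")
})

test_that("sem is the sample SD over sqrt(n) and scales homogeneously", {
  expect_equal(sem(rep(7, 5)), 0)
  expect_equal(sem(c(1, 2, 3, 4)), 1.290994 / 2, tolerance = 1e-6)
  x <- rnorm(20)
  expect_equal(sem(3.7 * x), 3.7 * sem(x), tolerance = 1e-12)
  expect_error(sem(1), "at least 2")
})

test_that("ROI map means respect the validity mask", {
  dm <- c(4, 4, 2)
  vals <- array(5, dim = dm)
  validity <- array(TRUE, dim = dm)
  validity[1, , ] <- FALSE
  vals[1, , ] <- NA
  m <- quantitative_map(vals, "mL/100g/min", validity, NULL)
  roi <- array(TRUE, dim = dm)
  expect_equal(roi_mean_map(m, roi), 5)
  roi_bad <- array(FALSE, dim = dm); roi_bad[1, 1, 1] <- TRUE
  expect_error(roi_mean_map(m, roi_bad), "overlap")
  s <- roi_mean_summary(list(m, m, m), roi)
  expect_equal(s$mean, 5)
  expect_equal(s$sem, 0)
})
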