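te20 <- 4.2 * (1:20)

test_that("T2 fit is exact on noiseless monoexponential voxels", {
  et <- voxel_echo_train(1000, 34, 4.2 * (1:32))
  m <- fit_t2_map(et, 4.2 * (1:32), n_echoes_used = 20)
  expect_true(m$validity[1, 1, 1])
  expect_equal(m$values[1, 1, 1], 34, tolerance = 1e-6)
  expect_identical(m$units, "ms")
})

test_that("degenerate voxels are flagged invalid, not filled", {
  et <- array(0, dim = c(1, 1, 1, 20))
  m <- fit_t2_map(et, te20)
  expect_false(m$validity[1, 1, 1])
  expect_true(is.na(m$values[1, 1, 1]))
})

test_that("T2 fit preconditions are enforced", {
  et <- voxel_echo_train(1, 50, te20)
  expect_error(fit_t2_map(et, te20, n_echoes_used = 25), "echoes")
  expect_error(fit_t2_map(et, rev(te20)), "increasing")
  expect_error(fit_t2_map(array(0, c(2, 2, 2)), te20), "4-D")
})

test_that("noisy T2 estimates are nearly unbiased and match an NLS oracle", {
  # 1000 Rician replicates of one voxel at SNR 40
  n <- 1000
  s0 <- 1000; t2 <- 50; sigma <- 25
  clean <- array(rep(s0 * exp(-te20 / t2), each = n), dim = c(n, 1, 1, 20))
  noisy <- add_noise(clean, sigma, seed = 8)
  m <- fit_t2_map(noisy, te20)
  vals <- m$values[m$validity]
  expect_gt(length(vals), 990)
  expect_lt(abs(mean(vals) - t2) / t2, 0.02)

  # independent per-voxel oracle on a handful of replicates
  for (i in 1:5) {
    y <- noisy[i, 1, 1, ]
    fit <- minpack.lm::nlsLM(y ~ a * exp(-te20 / tt),
                             start = list(a = max(y), tt = 40))
    expect_equal(m$values[i, 1, 1], coef(fit)[["tt"]], tolerance = 1e-5)
  }
})

test_that("T1 fit recovers noiseless inversion-recovery voxels", {
  ti <- default_inversion_times_ms()
  s <- abs(1000 * (1 - 2 * exp(-ti / 2200)))
  ir <- array(s, dim = c(1, 1, 1, length(ti)))
  m <- fit_t1_map(ir, ti)
  expect_true(m$validity[1, 1, 1])
  expect_equal(m$values[1, 1, 1], 2200, tolerance = 1e-4)
})

test_that("constant (non-recovering) series are invalid", {
  ti <- default_inversion_times_ms()
  ir <- array(500, dim = c(1, 1, 1, length(ti)))
  m <- fit_t1_map(ir, ti)
  expect_false(m$validity[1, 1, 1])
})

test_that("noisy T1 estimates have small bias at SNR 40", {
  ti <- default_inversion_times_ms()
  n <- 1000
  s0 <- 1000; t1 <- 2000; sigma <- 25
  clean <- array(rep(abs(s0 * (1 - 2 * exp(-ti / t1))), each = n),
                 dim = c(n, 1, 1, length(ti)))
  noisy <- add_noise(clean, sigma, seed = 9)
  m <- fit_t1_map(noisy, ti)
  vals <- m$values[m$validity]
  expect_gt(length(vals), 950)
  expect_lt(abs(mean(vals) - t1) / t1, 0.03)
})

test_that("ADC follows the two-point log-ratio formula exactly", {
  one <- function(x) array(x, dim = c(1, 1, 1))
  # equal signals: zero ADC
  m0 <- compute_adc_map(one(500), one(500))
  expect_equal(m0$values[1, 1, 1], 0)
  # attenuation exp(-1) at b = 800: ADC = 1/800 = 0.00125 mm^2/s
  m1 <- compute_adc_map(one(1000), one(1000 * exp(-1)))
  expect_equal(m1$values[1, 1, 1], 0.00125, tolerance = 1e-12)
  # attenuation exp(-0.624): the cortical early-ischemia level 7.8e-4
  m2 <- compute_adc_map(one(1000), one(1000 * exp(-0.624)))
  expect_equal(m2$values[1, 1, 1], 7.8e-4, tolerance = 1e-12)
  # non-positive signals are invalid; negative ADC retained but flagged
  m3 <- compute_adc_map(one(0), one(10))
  expect_false(m3$validity[1, 1, 1])
  m4 <- compute_adc_map(one(500), one(600))
  expect_true(m4$validity[1, 1, 1])
  expect_lt(m4$values[1, 1, 1], 0)
  expect_true(m4$diagnostics$negative[1, 1, 1])
  expect_error(compute_adc_map(one(1), one(1), b_s_per_mm2 = 0), "positive")
})

test_that("CBF follows the single-compartment quantification", {
  one <- function(x) array(x, dim = c(1, 1, 1))
  cc <- casl_constants()
  expect_equal(cc$alpha, 0.7)
  expect_equal(cc$lambda_ml_per_g, 0.95)
  # zero label-control difference: zero CBF
  m0 <- compute_cbf_map(one(800), one(800), one(2200))
  expect_equal(m0$values[1, 1, 1], 0)
  # hand-inverted pair at the early-ischemia cortical level
  cbf_true <- 34.1; t1 <- 2200; sc <- 1000
  sl <- sc * (1 - cbf_true * 2 * 0.7 * (t1 / 1000) / (6000 * 0.95))
  m1 <- compute_cbf_map(one(sc), one(sl), one(t1))
  expect_equal(m1$values[1, 1, 1], 34.1, tolerance = 1e-6)
  # halving alpha doubles CBF (linearity in 1/alpha)
  m2 <- compute_cbf_map(one(sc), one(sl), one(t1),
                        casl_constants(alpha = 0.35))
  expect_equal(m2$values[1, 1, 1], 2 * m1$values[1, 1, 1], tolerance = 1e-9)
  expect_error(casl_constants(alpha = 1.4), "\\(0, 1\\]")
})

test_that("all mappings are invariant under global intensity scaling", {
  ti <- default_inversion_times_ms()
  set.seed(31)
  for (k in 1:20) {
    s0 <- runif(1, 200, 2000); t2 <- runif(1, 15, 120)
    t1 <- runif(1, 800, 3500); adc <- runif(1, 3e-4, 2e-3)
    c_scale <- runif(1, 0.1, 10)
    et <- voxel_echo_train(s0, t2, te20)
    expect_equal(fit_t2_map(et * c_scale, te20)$values[1, 1, 1],
                 fit_t2_map(et, te20)$values[1, 1, 1], tolerance = 1e-7)
    ir <- array(abs(s0 * (1 - 2 * exp(-ti / t1))), dim = c(1, 1, 1, length(ti)))
    expect_equal(fit_t1_map(ir * c_scale, ti)$values[1, 1, 1],
                 fit_t1_map(ir, ti)$values[1, 1, 1], tolerance = 1e-6)
    one <- function(x) array(x, dim = c(1, 1, 1))
    expect_equal(
      compute_adc_map(one(s0 * c_scale), one(s0 * exp(-800 * adc) * c_scale))$values[1, 1, 1],
      compute_adc_map(one(s0), one(s0 * exp(-800 * adc)))$values[1, 1, 1],
      tolerance = 1e-12)
    sl <- s0 * 0.98
    expect_equal(
      compute_cbf_map(one(s0 * c_scale), one(sl * c_scale), one(t1))$values[1, 1, 1],
      compute_cbf_map(one(s0), one(sl), one(t1))$values[1, 1, 1],
      tolerance = 1e-12)
  }
})

test_that("ADC is decreasing in S_b and CBF increasing in the label difference", {
  one <- function(x) array(x, dim = c(1, 1, 1))
  sb <- seq(100, 900, by = 100)
  adc <- vapply(sb, function(s)
    compute_adc_map(one(1000), one(s))$values[1, 1, 1], numeric(1))
  expect_true(all(diff(adc) < 0))
  diffs <- seq(0, 100, by = 10)
  cbf <- vapply(diffs, function(d)
    compute_cbf_map(one(1000), one(1000 - d), one(2000))$values[1, 1, 1],
    numeric(1))
  expect_true(all(diff(cbf) > 0))
})

test_that("no voxel outside the input mask becomes valid", {
  tpl <- default_template()
  raw <- synthesize_subject(tpl, noise_sigma = 25, seed = 17,
                            sequences = c("cpmg", "dwi"))
  mask <- template_mask(tpl, "subcortex")
  t2 <- fit_t2_map(raw$echo_train, raw$echo_times_ms, mask = mask)
  expect_false(any(t2$validity & !mask))
  adc <- compute_adc_map(raw$dwi_b0, raw$dwi_bpos, mask = mask)
  expect_false(any(adc$validity & !mask))
})
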