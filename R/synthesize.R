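#' Default tissue parameter levels for the phantom
#'
#' Subject-level mean values of the voxel-wise tissue parameters, by tissue
#' compartment. Infarcted tissue takes strain-, timepoint- and ROI-specific CBF
#' and ADC levels matching the group means the tMCAO model produces at 17.6 T
#' (CBF in mL/100 g/min, ADC in mm^2/s); lesion voxels outside both ROIs use
#' the subcortical levels. T2 of infarcted tissue (30 ms) sits below the 34 ms
#' segmentation threshold with a safety margin, healthy tissue (45 ms) above
#' it; ventricular CSF has long T2/T1 and free-water ADC.
#'
#' @param strain `"C57Bl/6"` or `"Sv/129"`.
#' @param timepoint `"2h"` or `"24h"`.
#' @return nested list with components `healthy`, `csf`, `infarct` (the latter
#'   with `cortex` and `subcortex` CBF/ADC levels).
#' @export
default_tissue_levels <- function(strain = c("C57Bl/6", "Sv/129"),
                                  timepoint = c("24h", "2h")) {
  strain <- match.arg(strain)
  timepoint <- match.arg(timepoint)
  cbf <- list(
    "C57Bl/6" = list("2h" = c(cortex = 38.7, subcortex = 32.8),
                     "24h" = c(cortex = 25.2, subcortex = 23.4)),
    "Sv/129"  = list("2h" = c(cortex = 34.1, subcortex = 30.4),
                     "24h" = c(cortex = 22.3, subcortex = 20.8)))
  adc <- list(
    "C57Bl/6" = list("2h" = c(cortex = 7.8e-4, subcortex = 7.2e-4),
                     "24h" = c(cortex = 5.7e-4, subcortex = 5.3e-4)),
    "Sv/129"  = list("2h" = c(cortex = 7.8e-4, subcortex = 7.3e-4),
                     "24h" = c(cortex = 5.8e-4, subcortex = 5.4e-4)))
  list(
    healthy = list(t2_ms = 45, t1_ms = 2200, adc_mm2_per_s = 8.0e-4,
                   cbf_ml_per_100g_min = 90, s0 = 1000),
    csf = list(t2_ms = 200, t1_ms = 4300, adc_mm2_per_s = 3.0e-3,
               cbf_ml_per_100g_min = 5, s0 = 1200),
    infarct = list(t2_ms = 30, t1_ms = 2600,
                   adc_mm2_per_s = adc[[strain]][[timepoint]],
                   cbf_ml_per_100g_min = cbf[[strain]][[timepoint]],
                   s0 = 1000)
  )
}

#' Build voxel-wise ground-truth tissue parameter fields
#'
#' Paints the subject-level tissue levels onto the atlas grid: healthy values
#' in non-lesioned brain, CSF values in the ventricles, and infarct values
#' (ROI-specific for CBF and ADC) inside the lesion. All fields are strictly
#' positive inside the brain; outside the brain every field is 0 (no signal).
#'
#' @param template an `atlas_template`.
#' @param lesion logical lesion mask on the atlas grid (e.g. from
#'   [make_lesion()]), or `NULL` for a lesion-free brain.
#' @param levels tissue levels as from [default_tissue_levels()].
#' @return object of class `tissue_field`: list of 3-D arrays `t2_ms`, `t1_ms`,
#'   `adc_mm2_per_s`, `cbf_ml_per_100g_min`, `s0`, plus `geometry`.
#' @export
tissue_parameter_field <- function(template, lesion = NULL,
                                   levels = default_tissue_levels()) {
  geom <- template$geometry
  brain <- template_mask(template, "brain")
  vent <- template_mask(template, "ventricle")
  ctx <- template_mask(template, "cortex_mca")
  if (is.null(lesion)) lesion <- array(FALSE, dim = grid_dim(geom))
  stop_if_grid_mismatch(template$labels, lesion)
  lesion <- lesion & brain & !vent

  paint <- function(healthy, csf, inf_ctx, inf_sub) {
    v <- vol_array(geom, 0)
    v[brain] <- healthy
    v[vent] <- csf
    v[lesion & ctx] <- inf_ctx
    v[lesion & !ctx] <- inf_sub
    v
  }
  h <- levels$healthy; c0 <- levels$csf; inf <- levels$infarct
  scalar2 <- function(x) if (length(x) == 1L) c(cortex = x, subcortex = x) else x
  adc <- scalar2(inf$adc_mm2_per_s); cbf <- scalar2(inf$cbf_ml_per_100g_min)
  # S0 is an analytic field (smooth edges + texture) shared with the template
  # reference; infarction leaves proton density unchanged in this phantom
  w <- vox_to_world(grid_index_matrix(geom), geom)
  out <- list(
    t2_ms = paint(h$t2_ms, c0$t2_ms, inf$t2_ms, inf$t2_ms),
    t1_ms = paint(h$t1_ms, c0$t1_ms, inf$t1_ms, inf$t1_ms),
    adc_mm2_per_s = paint(h$adc_mm2_per_s, c0$adc_mm2_per_s,
                          adc[["cortex"]], adc[["subcortex"]]),
    cbf_ml_per_100g_min = paint(h$cbf_ml_per_100g_min, c0$cbf_ml_per_100g_min,
                                cbf[["cortex"]], cbf[["subcortex"]]),
    s0 = array(s0_analytic(w, geom, h$s0, c0$s0), dim = grid_dim(geom)),
    s0_levels = c(tissue = h$s0, csf = c0$s0),
    geometry = geom
  )
  for (f in c("t2_ms", "t1_ms", "adc_mm2_per_s", "cbf_ml_per_100g_min", "s0"))
    if (any(out[[f]][brain] <= 0))
      stop("tissue parameter fields must be strictly positive inside the brain")
  structure(out, class = "tissue_field")
}

#' Add Rician (magnitude) noise to a noise-free magnitude image
#'
#' MR magnitude images are the modulus of a complex signal with independent
#' Gaussian noise of standard deviation `sigma` in each channel:
#' `|S + sigma Z1 + i sigma Z2|`. In background (`S = 0`) the result is
#' Rayleigh with mean `sigma * sqrt(pi/2)`. `model = "gaussian"` adds plain
#' additive Gaussian noise instead (useful for analytic checks).
#'
#' @param vol noise-free magnitude volume (non-negative).
#' @param sigma noise standard deviation per channel (>= 0).
#' @param seed integer seed; identical seeds give identical draws.
#' @param model `"rician"` or `"gaussian"`.
#' @export
add_noise <- function(vol, sigma, seed, model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (sigma < 0) stop("noise sigma must be non-negative")
  if (sigma == 0) return(vol)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n <- length(vol)
  if (model == "rician") {
    re <- vol + stats::rnorm(n, 0, sigma)
    im <- stats::rnorm(n, 0, sigma)
    array(sqrt(re^2 + im^2), dim = dim(vol))
  } else {
    array(vol + stats::rnorm(n, 0, sigma), dim = dim(vol))
  }
}

# CASL single-compartment constants; see compute_cbf_map()
#' CASL model constants (inversion efficiency and partition coefficient)
#' @param alpha labeling inversion efficiency, in (0, 1].
#' @param lambda_ml_per_g brain-blood partition coefficient of water, mL/g.
#' @export
casl_constants <- function(alpha = 0.7, lambda_ml_per_g = 0.95) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (lambda_ml_per_g <= 0) stop("lambda must be positive")
  list(alpha = alpha, lambda_ml_per_g = lambda_ml_per_g)
}

# invert the single-compartment CBF formula to a label image:
# CBF [mL/100g/min] = 6000 * (lambda / T1[s]) * (Sc - Sl) / (2 alpha Sc)
casl_label_from_cbf <- function(control, cbf, t1_ms, constants) {
  frac <- cbf * 2 * constants$alpha * (t1_ms / 1000) /
    (6000 * constants$lambda_ml_per_g)
  control * (1 - frac)
}

#' Default inversion times for the inversion-recovery T1 series (ms)
#' @export
default_inversion_times_ms <- function() c(100, 250, 500, 1000, 2000, 4000, 8000)

#' Synthesize one subject's raw multimodal acquisitions
#'
#' Applies the forward model of each sequence to the ground-truth tissue
#' fields, resamples every volume from atlas space into the subject's native
#' pose (the inverse of the subject-to-atlas `misalignment`), and adds Rician
#' noise:
#' * CPMG echo train: `S(x, TE_k) = S0(x) exp(-TE_k / T2(x))`;
#' * DWI: `S_b(x) = S0'(x) exp(-b ADC(x))` at b = 0 and the positive b;
#' * CASL: control = S0, label constructed by inverting the single-compartment
#'   perfusion formula, so that [compute_cbf_map()] with the true T1 and the
#'   same constants returns the ground-truth CBF exactly in the noise-free
#'   limit;
#' * inversion recovery: `|S0 (1 - B exp(-TI / T1))|` with B = 2.
#'
#' @param template an `atlas_template`.
#' @param lesion logical lesion mask (atlas space) or `NULL`.
#' @param tissue a `tissue_field`; defaults to painting `levels` onto the
#'   template/lesion.
#' @param geometry acquisition geometry (defaults to the template's).
#' @param noise_sigma Rician channel SD, in the same arbitrary units as `s0`
#'   (s0 = 1000 and `noise_sigma = 25` gives SNR 40).
#' @param misalignment `rigid_transform` mapping subject world to atlas world.
#' @param seed integer; fully determines all noise draws.
#' @param levels tissue levels used when `tissue` is `NULL`.
#' @param noise_model `"rician"` or `"gaussian"`.
#' @param sequences which acquisitions to simulate (any of `"cpmg"`, `"dwi"`,
#'   `"casl"`, `"ir"`); unrequested sequences are `NULL` in the result. Each
#'   sequence draws noise from its own derived seed, so the simulated values
#'   of a sequence do not depend on which others are requested.
#' @return object of class `subject_raw`: echo train (4-D), DWI pair, CASL
#'   pair, IR series (4-D), brain mask in native space, acquisition metadata,
#'   and the ground-truth transform/seed.
#' @export
synthesize_subject <- function(template, lesion = NULL, tissue = NULL,
                               geometry = template$geometry,
                               noise_sigma = 0,
                               misalignment = rigid_transform(),
                               seed = 1L,
                               levels = default_tissue_levels(),
                               noise_model = "rician",
                               sequences = c("cpmg", "dwi", "casl", "ir")) {
  sequences <- match.arg(sequences, several.ok = TRUE)
  if (noise_sigma < 0) stop("noise sigma must be non-negative")
  if (is.null(tissue)) tissue <- tissue_parameter_field(template, lesion, levels)
  stopifnot(inherits(misalignment, "rigid_transform"))
  src <- template$geometry
  dm <- grid_dim(geometry)

  # atlas -> subject native pose: acquisition of a displaced head is emulated
  # by evaluating the phantom at the atlas position of every subject voxel —
  # tissue classes by nearest-neighbour lookup (sharp boundaries, as in a real
  # acquisition) and the proton-density texture analytically at the exact
  # transformed coordinates
  atl2sub <- invert_transform(misalignment)
  # tissue classes are looked up nearest-neighbour: an acquisition of a
  # displaced head sees sharp class boundaries, and interpolating relaxation
  # times across the brain edge would create nonphysical short-T2 rims
  pull <- function(vol, interp = "nearest")
    resample_volume(vol, atl2sub, src, geometry, interpolation = interp)

  t2 <- pull(tissue$t2_ms); t1 <- pull(tissue$t1_ms)
  adc <- pull(tissue$adc_mm2_per_s); cbf <- pull(tissue$cbf_ml_per_100g_min)
  w_atlas <- apply_transform(misalignment,
                             vox_to_world(grid_index_matrix(geometry), geometry))
  s0 <- if (!is.null(tissue$s0_levels))
    array(s0_analytic(w_atlas, src, tissue$s0_levels[["tissue"]],
                      tissue$s0_levels[["csf"]]), dim = dm)
  else pull(tissue$s0)
  brain_native <- pull(template_mask(template, "brain"), "nearest")

  # per-sequence seeds derived by the documented counter scheme
  nz <- function(x, s) add_noise(x, noise_sigma, s, model = noise_model)
  te <- echo_times_ms(geometry)
  echo_train <- NULL
  if ("cpmg" %in% sequences) {
    inside <- s0 > 0 & t2 > 0
    echo_train <- array(0, dim = c(dm, geometry$n_echoes))
    decay <- array(0, dim = dm)
    for (k in seq_along(te)) {
      decay[inside] <- exp(-te[k] / t2[inside])
      echo_train[, , , k] <- nz(s0 * decay, derive_seed(seed, 1, k))
    }
  }

  b <- geometry$b_values_s_per_mm2[2]
  dwi_b0 <- dwi_bpos <- NULL
  if ("dwi" %in% sequences) {
    dwi_b0 <- s0
    dwi_bpos <- array(0, dim = dm)
    ok <- s0 > 0 & adc > 0
    dwi_bpos[ok] <- s0[ok] * exp(-b * adc[ok])
    dwi_b0 <- nz(dwi_b0, derive_seed(seed, 2, 1))
    dwi_bpos <- nz(dwi_bpos, derive_seed(seed, 2, 2))
  }

  casl_control <- casl_label <- NULL
  if ("casl" %in% sequences) {
    constants <- casl_constants()
    casl_control <- s0
    casl_label <- array(0, dim = dm)
    ok0 <- s0 > 0
    casl_label[ok0] <-
      casl_label_from_cbf(s0[ok0], cbf[ok0], pmax(t1[ok0], 1e-9), constants)
    casl_control <- nz(casl_control, derive_seed(seed, 3, 1))
    casl_label <- nz(casl_label, derive_seed(seed, 3, 2))
  }

  ti <- default_inversion_times_ms()
  ir_series <- NULL
  if ("ir" %in% sequences) {
    ir_series <- array(0, dim = c(dm, length(ti)))
    okt <- s0 > 0 & t1 > 0
    for (k in seq_along(ti)) {
      sl <- array(0, dim = dm)
      sl[okt] <- abs(s0[okt] * (1 - 2 * exp(-ti[k] / t1[okt])))
      ir_series[, , , k] <- nz(sl, derive_seed(seed, 4, k))
    }
  }

  structure(list(
    echo_train = echo_train, echo_times_ms = te,
    dwi_b0 = dwi_b0, dwi_bpos = dwi_bpos, b_s_per_mm2 = b,
    casl_control = casl_control, casl_label = casl_label,
    ir_series = ir_series, inversion_times_ms = ti,
    brain_mask_native = brain_native,
    misalignment = misalignment, noise_sigma = noise_sigma, seed = seed,
    geometry = geometry,
    ground_truth = list(t2_ms = t2, t1_ms = t1, adc_mm2_per_s = adc,
                        cbf_ml_per_100g_min = cbf, s0 = s0)
  ), class = "subject_raw")
}

#' Cohort specification for the phantom study
#'
#' Defines the between-subject generative model of one strain group: number of
#' subjects, tissue-level means with between-subject coefficients of variation
#' (normal, truncated at zero), lesion cortical fractions per timepoint with
#' between-subject SD (truncated to `[0,1]`), the acquisition noise level and
#' the misalignment ranges (uniform per axis).
#'
#' Default lesion fractions follow the natural history of the tMCAO model:
#' subcortical infarction is complete at both timepoints, the cortical MCA
#' territory is roughly half involved at 2 h (53-61% depending on strain) and
#' nearly completely involved (92-95%) at 24 h. Default between-subject CVs
#' are 15% for the functional parameters (CBF, ADC, S0) and 5% for the
#' relaxometric ones (T2, T1), keeping subjects on the correct side of the
#' 34 ms segmentation threshold.
#'
#' @param n_subjects subjects per group (the study design uses 8).
#' @param strain_label strain name; sets default lesion fractions and
#'   infarct tissue levels.
#' @param cortical_fraction_2h,cortical_fraction_24h mean lesion extent in the
#'   cortical ROI; defaults by strain.
#' @param fraction_sd between-subject SD of the cortical fractions.
#' @param cv named between-subject coefficients of variation.
#' @param noise_sigma Rician channel SD (25 = SNR 40 at s0 = 1000).
#' @param misalignment_rot_deg,misalignment_trans_vox half-ranges of the
#'   uniform per-axis misalignment (degrees / voxels).
#' @param noise_model `"rician"` or `"gaussian"`.
#' @param threshold_ms,t2_margin_ms segmentation threshold and safety margin:
#'   the between-subject T2 draw is truncated so that every subject's infarct
#'   T2 stays below `threshold_ms - t2_margin_ms` and healthy T2 above
#'   `threshold_ms + t2_margin_ms`, preserving the contrast the threshold
#'   segmentation relies on.
#' @export
cohort_spec <- function(n_subjects = 8L,
                        strain_label = c("C57Bl/6", "Sv/129"),
                        cortical_fraction_2h = NULL,
                        cortical_fraction_24h = NULL,
                        fraction_sd = 0.08,
                        cv = c(t2 = 0.05, t1 = 0.05, adc = 0.15,
                               cbf = 0.15, s0 = 0.15),
                        noise_sigma = 25,
                        misalignment_rot_deg = 5,
                        misalignment_trans_vox = 2,
                        noise_model = "rician",
                        threshold_ms = 34, t2_margin_ms = 2) {
  strain_label <- match.arg(strain_label)
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  defaults_2h <- c("C57Bl/6" = 0.607, "Sv/129" = 0.533)
  defaults_24h <- c("C57Bl/6" = 0.951, "Sv/129" = 0.921)
  if (is.null(cortical_fraction_2h))
    cortical_fraction_2h <- defaults_2h[[strain_label]]
  if (is.null(cortical_fraction_24h))
    cortical_fraction_24h <- defaults_24h[[strain_label]]
  list(n_subjects = as.integer(n_subjects), strain_label = strain_label,
       cortical_fraction_2h = cortical_fraction_2h,
       cortical_fraction_24h = cortical_fraction_24h,
       fraction_sd = fraction_sd, cv = cv, noise_sigma = noise_sigma,
       misalignment_rot_deg = misalignment_rot_deg,
       misalignment_trans_vox = misalignment_trans_vox,
       noise_model = noise_model,
       threshold_ms = threshold_ms, t2_margin_ms = t2_margin_ms)
}

rtruncnorm0 <- function(n, mean, sd, lower = 0, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x <= lower | x > upper
  tries <- 0L
  while (any(bad) && tries < 100L) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x <= lower | x > upper
    tries <- tries + 1L
  }
  pmin(pmax(x, lower + .Machine$double.eps), upper)
  }

scale_levels <- function(levels, mult) {
  for (cmp in c("healthy", "csf", "infarct")) {
    levels[[cmp]]$t2_ms <- levels[[cmp]]$t2_ms * mult[["t2"]]
    levels[[cmp]]$t1_ms <- levels[[cmp]]$t1_ms * mult[["t1"]]
    levels[[cmp]]$adc_mm2_per_s <- levels[[cmp]]$adc_mm2_per_s * mult[["adc"]]
    levels[[cmp]]$cbf_ml_per_100g_min <-
      levels[[cmp]]$cbf_ml_per_100g_min * mult[["cbf"]]
    levels[[cmp]]$s0 <- levels[[cmp]]$s0 * mult[["s0"]]
  }
  levels
}

#' Synthesize a multi-subject, two-timepoint cohort
#'
#' Draws per-subject tissue multipliers (normal with the spec'ed CVs, truncated
#' at zero), lesion fractions and misalignments, derives per-subject seeds from
#' the master seed by the counter scheme, and synthesizes paired 2 h / 24 h
#' raw acquisitions for every subject. The same master seed always reproduces
#' the cohort bit-for-bit.
#'
#' @param template an `atlas_template`.
#' @param spec a [cohort_spec()].
#' @param master_seed integer master seed.
#' @param sequences acquisitions to simulate, passed to
#'   [synthesize_subject()].
#' @param timepoints which imaging timepoints to simulate (default both).
#' @return list of class `cohort_raw`: per subject, a list with `subject_id`,
#'   `strain`, `lesion` (`lesion_gt`), per-timepoint `subject_raw` data under
#'   `timepoints$, and the drawn generative parameters.
#' @export
synthesize_cohort <- function(template, spec = cohort_spec(), master_seed = 1L,
                              sequences = c("cpmg", "dwi", "casl", "ir"),
                              timepoints = c("2h", "24h")) {
  n <- spec$n_subjects
  # T2 multiplier bounds preserving the threshold margin for every subject
  lv0 <- default_tissue_levels(spec$strain_label)
  t2_lo <- (spec$threshold_ms + spec$t2_margin_ms) / lv0$healthy$t2_ms
  t2_hi <- (spec$threshold_ms - spec$t2_margin_ms) / lv0$infarct$t2_ms
  old <- local_seed(derive_seed(master_seed, 0))
  mult <- lapply(seq_len(n), function(i)
    c(t2 = rtruncnorm0(1, 1, spec$cv[["t2"]], t2_lo, t2_hi),
      t1 = rtruncnorm0(1, 1, spec$cv[["t1"]]),
      adc = rtruncnorm0(1, 1, spec$cv[["adc"]]),
      cbf = rtruncnorm0(1, 1, spec$cv[["cbf"]]),
      s0 = rtruncnorm0(1, 1, spec$cv[["s0"]])))
  f2 <- rtruncnorm0(n, spec$cortical_fraction_2h, spec$fraction_sd, 0, 1)
  f24 <- rtruncnorm0(n, spec$cortical_fraction_24h, spec$fraction_sd, 0, 1)
  sp <- grid_spacing(template$geometry)
  mis <- lapply(seq_len(n * 2), function(i) {
    rot <- stats::runif(3, -spec$misalignment_rot_deg, spec$misalignment_rot_deg)
    tr <- stats::runif(3, -spec$misalignment_trans_vox, spec$misalignment_trans_vox) * sp
    rigid_transform(rot, tr)
  })
  restore_seed(old)

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    lesion <- lesion_ground_truth(template, f2[i], max(f24[i], f2[i]),
                                  spec$strain_label,
                                  rng_seed = derive_seed(master_seed, i, 99))
    tps <- list()
    for (tp_i in c(1L, 2L)) {
      tp <- c("2h", "24h")[tp_i]
      if (!tp %in% timepoints) next
      levels <- scale_levels(default_tissue_levels(spec$strain_label, tp),
                             mult[[i]])
      tps[[tp]] <- synthesize_subject(
        template, lesion = lesion_mask(lesion, tp),
        geometry = template$geometry,
        noise_sigma = spec$noise_sigma,
        misalignment = mis[[(i - 1L) * 2L + tp_i]],
        seed = derive_seed(master_seed, i, tp_i),
        levels = levels, noise_model = spec$noise_model,
        sequences = sequences)
    }
    subjects[[i]] <- list(subject_id = sprintf("%s_%02d",
                                               gsub("[^A-Za-z0-9]", "", spec$strain_label), i),
                          strain = spec$strain_label,
                          lesion = lesion, timepoints = tps,
                          multipliers = mult[[i]],
                          cortical_fractions = c("2h" = f2[i],
                                                 "24h" = max(f24[i], f2[i])))
  }
  structure(list(subjects = subjects, spec = spec, master_seed = master_seed,
                 template_geometry = template$geometry),
            class = "cohort_raw")
}
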