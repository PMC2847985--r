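#' Default end-to-end pipeline configuration
#'
#' One nested list drives the whole analysis: the two strain cohorts (each a
#' [cohort_spec()]), the acquisition geometry, the analysis constants (echoes
#' used by the T2 fit, b-value, CASL alpha/lambda, segmentation threshold),
#' registration options, and output controls. Every constant can be
#' overridden by replacing the corresponding element; [run_pipeline()] records
#' the fully resolved configuration (and its hash) in its result.
#'
#' @param n_subjects subjects per group.
#' @param noise_sigma Rician channel SD for both groups.
#' @param misalignment_rot_deg,misalignment_trans_vox misalignment half-ranges.
#' @param registration_enabled if `FALSE`, identity transforms are used
#'   (appropriate for zero-misalignment phantoms).
#' @param master_seed master seed; per-group/subject/sequence seeds derive
#'   from it.
#' @param output_dir directory for artifacts, or `NULL` to keep everything in
#'   memory.
#' @export
default_config <- function(n_subjects = 8L, noise_sigma = 25,
                           misalignment_rot_deg = 5, misalignment_trans_vox = 2,
                           registration_enabled = TRUE,
                           master_seed = 1L, output_dir = NULL) {
  list(
    geometry = acq_geometry(),
    groups = list(
      cohort_spec(n_subjects, "C57Bl/6", noise_sigma = noise_sigma,
                  misalignment_rot_deg = misalignment_rot_deg,
                  misalignment_trans_vox = misalignment_trans_vox),
      cohort_spec(n_subjects, "Sv/129", noise_sigma = noise_sigma,
                  misalignment_rot_deg = misalignment_rot_deg,
                  misalignment_trans_vox = misalignment_trans_vox)
    ),
    analysis = list(n_echoes_used = 20L, alpha = 0.7, lambda_ml_per_g = 0.95,
                    threshold_ms = 34, threshold_below = TRUE,
                    t1_source = "fitted", t1_fixed_ms = 2200),
    registration = list(enabled = registration_enabled),
    brain_extraction = "ground_truth",
    pairing = "cohort_order",
    master_seed = as.integer(master_seed),
    output_dir = output_dir,
    log_level = "info"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values present in the file override the corresponding [default_config()]
#' entries (shallow-merged per top-level section).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @export
read_config <- function(path) {
  user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(user)) {
    if (nm %in% names(cfg) && is.list(cfg[[nm]]) && is.list(user[[nm]]) &&
        nm != "groups") {
      for (sub in names(user[[nm]])) cfg[[nm]][[sub]] <- user[[nm]][[sub]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

pipe_log <- function(config, stage, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# analyse one synthetic subject at one timepoint: native-space maps
subject_native_maps <- function(raw, config) {
  an <- config$analysis
  brain <- extract_brain(raw$echo_train[, , , 1],
                         mode = config$brain_extraction,
                         ground_truth_mask = raw$brain_mask_native)
  g <- raw$geometry
  t2 <- fit_t2_map(raw$echo_train, raw$echo_times_ms,
                   n_echoes_used = an$n_echoes_used, mask = brain$mask,
                   geometry = g)
  t1 <- if (identical(an$t1_source, "fitted"))
    fit_t1_map(raw$ir_series, raw$inversion_times_ms, mask = brain$mask,
               geometry = g)
  else quantitative_map(array(an$t1_fixed_ms, dim = grid_dim(g)), "ms",
                        array(TRUE, dim = grid_dim(g)), g)
  adc <- compute_adc_map(raw$dwi_b0, raw$dwi_bpos, raw$b_s_per_mm2,
                         mask = brain$mask, geometry = g)
  cbf <- compute_cbf_map(raw$casl_control, raw$casl_label, t1,
                         casl_constants(an$alpha, an$lambda_ml_per_g),
                         mask = brain$mask, geometry = g)
  list(brain = brain, t2 = t2, t1 = t1, adc = adc, cbf = cbf)
}

#' Run the full phantom-cohort analysis pipeline
#'
#' Stages: synthesize both strain cohorts; fit native-space T2/T1/ADC/CBF
#' maps per subject and timepoint; register each subject step-wise to the
#' atlas (intra-subject 2 h to 24 h, then 24 h to template; identity
#' transforms when registration is disabled); resample maps and masks into
#' atlas space; segment the infarct by the T2 threshold and remove
#' intraventricular CSF; compute within-group probability maps, ROI
#' probability/CBF/ADC summaries, manual-emulated whole-brain volumetry, and
#' matched-pairs Wilcoxon comparisons between the strains.
#'
#' Identical configuration and master seed reproduce the result exactly.
#'
#' @param config a [default_config()]-shaped list.
#' @return object of class `cohort_result`; see [cohort_result_tables()].
#' @export
run_pipeline <- function(config = default_config()) {
  t0 <- Sys.time()
  template <- build_template(config$geometry)
  an <- config$analysis
  rois <- list(cortex_mca = template_mask(template, "cortex_mca"),
               subcortex = template_mask(template, "subcortex"))
  vent <- template_mask(template, "ventricle")

  groups <- list()
  for (gi in seq_along(config$groups)) {
    spec <- config$groups[[gi]]
    pipe_log(config, "simulate", "group %s: n = %d, sigma = %g",
             spec$strain_label, spec$n_subjects, spec$noise_sigma)
    cohort <- synthesize_cohort(template, spec,
                                master_seed = derive_seed(config$master_seed, gi))
    subjects <- list()
    for (si in seq_along(cohort$subjects)) {
      sub <- cohort$subjects[[si]]
      pipe_log(config, "analyze", "%s", sub$subject_id)
      native <- lapply(sub$timepoints, subject_native_maps, config = config)

      if (isTRUE(config$registration$enabled)) {
        xf <- register_subject_stepwise(
          sub$timepoints[["2h"]]$dwi_b0,
          sub$timepoints[["24h"]]$dwi_b0,
          config$geometry, template)
        transforms <- list("2h" = xf$to_atlas_2h, "24h" = xf$to_atlas_24h)
      } else {
        transforms <- list("2h" = rigid_transform(), "24h" = rigid_transform())
      }

      tp_results <- list()
      for (tp in c("2h", "24h")) {
        atl <- to_atlas(native[[tp]][c("t1", "adc", "cbf")],
                        masks = list(brain = native[[tp]]$brain$mask),
                        transform = transforms[[tp]], template = template)
        # the segmentation input is warped nearest-neighbour so the threshold
        # operates on fitted relaxation times, not on partial-volume mixtures
        atl$maps$t2 <- to_atlas(native[[tp]]["t2"], transform = transforms[[tp]],
                                template = template,
                                map_interpolation = "nearest")$maps$t2
        seg <- segment_infarct_t2(atl$maps$t2, an$threshold_ms,
                                  atl$masks$brain & template_mask(template, "brain"),
                                  below = an$threshold_below,
                                  timepoint = tp, subject_id = sub$subject_id)
        seg <- remove_csf(seg, vent)
        manual <- segment_manual_emulated(sub$lesion, tp,
                                          subject_id = sub$subject_id)
        tp_results[[tp]] <- list(
          maps_atlas = atl$maps, brain_atlas = atl$masks$brain,
          lesion_t2 = seg, lesion_manual = manual,
          volumetry = volume_ratio(manual, template),
          transform = transforms[[tp]],
          roi_values = list(
            probability = vapply(rois, function(r)
              100 * sum(seg$mask & r) / sum(r), numeric(1)),
            cbf = vapply(rois, function(r)
              roi_mean_map(atl$maps$cbf, r), numeric(1)),
            adc = vapply(rois, function(r)
              roi_mean_map(atl$maps$adc, r), numeric(1))
          ))
      }
      subjects[[sub$subject_id]] <- list(subject_id = sub$subject_id,
                                         strain = sub$strain,
                                         timepoints = tp_results)
    }
    groups[[spec$strain_label]] <- list(spec = spec, subjects = subjects)
  }

  # group-level summaries
  summaries <- list()
  group_maps <- list()
  for (gname in names(groups)) {
    for (tp in c("2h", "24h")) {
      subs <- groups[[gname]]$subjects
      segs <- lapply(subs, function(s) s$timepoints[[tp]]$lesion_t2)
      pm <- probability_map(segs, gname, tp)
      key <- paste(gname, tp, sep = "|")
      per <- function(field, roi_i)
        vapply(subs, function(s)
          s$timepoints[[tp]]$roi_values[[field]][[roi_i]], numeric(1))
      summaries[[key]] <- list(
        group = gname, timepoint = tp, n = length(subs),
        probability = lapply(names(rois), function(r) roi_summary(per("probability", r), r)),
        cbf = lapply(names(rois), function(r) roi_summary(per("cbf", r), r)),
        adc = lapply(names(rois), function(r) roi_summary(per("adc", r), r)),
        volume_ratio = roi_summary(vapply(subs, function(s)
          s$timepoints[[tp]]$volumetry$ratio, numeric(1)), "hemisphere")
      )
      names(summaries[[key]]$probability) <- names(rois)
      names(summaries[[key]]$cbf) <- names(rois)
      names(summaries[[key]]$adc) <- names(rois)
      mean_map <- function(field) {
        vols <- lapply(subs, function(s) {
          v <- s$timepoints[[tp]]$maps_atlas[[field]]$values
          v[!s$timepoints[[tp]]$maps_atlas[[field]]$validity] <- NA
          v
        })
        acc <- Reduce(`+`, lapply(vols, function(v) ifelse(is.na(v), 0, v)))
        cnt <- Reduce(`+`, lapply(vols, function(v) !is.na(v)))
        out <- acc / pmax(cnt, 1)
        out[cnt == 0] <- NA
        out
      }
      group_maps[[key]] <- list(probability = pm,
                                t2 = mean_map("t2"), cbf = mean_map("cbf"),
                                adc = mean_map("adc"))
    }
  }

  # between-strain matched-pairs comparisons (subject i of one strain paired
  # with subject i of the other, in cohort order)
  comparisons <- list()
  if (length(groups) == 2L) {
    g1 <- names(groups)[1]; g2 <- names(groups)[2]
    pull <- function(g, tp, field, roi_i)
      vapply(groups[[g]]$subjects, function(s)
        s$timepoints[[tp]]$roi_values[[field]][[roi_i]], numeric(1))
    for (tp in c("2h", "24h")) {
      for (field in c("cbf", "adc")) for (r in names(rois)) {
        w <- wilcoxon_signed_rank_exact(pull(g1, tp, field, r),
                                        pull(g2, tp, field, r))
        comparisons[[sprintf("%s_%s_%s", field, r, tp)]] <-
          c(list(measure = field, roi = r, timepoint = tp,
                 groups = c(g1, g2)), unclass(w))
      }
      ratio_g <- function(g) vapply(groups[[g]]$subjects, function(s)
        s$timepoints[[tp]]$volumetry$ratio, numeric(1))
      w <- wilcoxon_signed_rank_exact(ratio_g(g1), ratio_g(g2))
      comparisons[[sprintf("volume_ratio_%s", tp)]] <-
        c(list(measure = "volume_ratio", roi = "hemisphere", timepoint = tp,
               groups = c(g1, g2)), unclass(w))
    }
  }

  result <- structure(list(
    summaries = summaries, comparisons = comparisons, group_maps = group_maps,
    groups = groups, template = template,
    provenance = list(config = config,
                      # hash covers the scientific configuration, not where
                      # the artifacts land or how chatty the run is
                      config_hash = rlang::hash(
                        config[setdiff(names(config),
                                       c("output_dir", "log_level"))]),
                      master_seed = config$master_seed,
                      package_version = as.character(utils::packageVersion("strokemri")),
                      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  ), class = "cohort_result")

  if (!is.null(config$output_dir)) write_cohort_result(result, config$output_dir)
  result
}

#' Flatten a cohort result into data frames
#'
#' @param result a `cohort_result`.
#' @return list of data frames: `roi_stats` (group x timepoint x ROI mean/SEM
#'   for probability, CBF, ADC), `volumetry` (per subject) and `comparisons`.
#' @export
cohort_result_tables <- function(result) {
  rows <- list()
  for (s in result$summaries) {
    for (field in c("probability", "cbf", "adc")) {
      for (r in names(s[[field]])) {
        x <- s[[field]][[r]]
        rows[[length(rows) + 1L]] <- data.frame(
          group = s$group, timepoint = s$timepoint, roi = r,
          measure = field, mean = x$mean, sem = x$sem, n = x$n)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = s$group, timepoint = s$timepoint, roi = "hemisphere",
      measure = "volume_ratio", mean = s$volume_ratio$mean,
      sem = s$volume_ratio$sem, n = s$volume_ratio$n)
  }
  roi_stats <- do.call(rbind, rows)

  vol <- list()
  for (g in result$groups) for (sub in g$subjects) for (tp in c("2h", "24h")) {
    v <- sub$timepoints[[tp]]$volumetry
    vol[[length(vol) + 1L]] <- data.frame(
      subject = sub$subject_id, strain = sub$strain, timepoint = tp,
      method = v$method, lesion_voxels = v$lesion_voxels,
      hemisphere_voxels = v$hemisphere_voxels, ratio = v$ratio,
      voxel_volume_mm3 = v$voxel_volume_mm3)
  }
  volumetry <- do.call(rbind, vol)

  cmp <- do.call(rbind, lapply(names(result$comparisons), function(nm) {
    x <- result$comparisons[[nm]]
    data.frame(comparison = nm, measure = x$measure, roi = x$roi,
               timepoint = x$timepoint, W = x$statistic_W,
               n_effective = x$n_effective, p_two_sided = x$p_two_sided,
               method = x$method)
  }))
  list(roi_stats = roi_stats, volumetry = volumetry, comparisons = cmp)
}

# serializable view of a cohort result (numbers only, no volumes)
cohort_result_json <- function(result) {
  tb <- cohort_result_tables(result)
  list(provenance = list(config_hash = result$provenance$config_hash,
                         master_seed = result$provenance$master_seed,
                         package_version = result$provenance$package_version),
       roi_stats = tb$roi_stats, volumetry = tb$volumetry,
       comparisons = tb$comparisons)
}

#' Write a cohort result to disk
#'
#' `results.json` (summaries, volumetry, comparisons, provenance; no
#' timestamps, so identical runs are byte-identical), the two CSV tables, and
#' the group probability maps as NIfTI volumes.
#'
#' @param result a `cohort_result`.
#' @param dir output directory.
#' @export
write_cohort_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tb <- cohort_result_tables(result)
  jsonlite::write_json(cohort_result_json(result),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(tb$roi_stats, file.path(dir, "roi_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(tb$volumetry, file.path(dir, "volumetry.csv"),
                   row.names = FALSE)
  utils::write.csv(tb$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  geom <- result$template$geometry
  for (key in names(result$group_maps)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", key)
    write_volume_nifti(result$group_maps[[key]]$probability$values, geom,
                       file.path(dir, sprintf("probmap_%s.nii.gz", safe)))
  }
  invisible(dir)
}

#' Render figures and tables from a cohort result
#'
#' Writes four figures (probability-map panel, group-mean T2 panel, group-mean
#' CBF/ADC panel, volume-ratio bar chart with SEM error bars) and two CSV
#' tables (ROI probabilities; ROI CBF/ADC means). Purely presentational: every
#' number is taken from the `cohort_result`.
#'
#' @param result a `cohort_result`.
#' @param dir output directory.
#' @param slice slice index shown in map panels (default: middle slice).
#' @return invisible character vector of the files written.
#' @export
render_reports <- function(result, dir, slice = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dm <- grid_dim(result$template$geometry)
  if (is.null(slice)) slice <- ceiling(dm[3] / 2)
  tb <- cohort_result_tables(result)

  slice_df <- function(field) {
    do.call(rbind, lapply(names(result$group_maps), function(key) {
      v <- if (field == "probability") result$group_maps[[key]]$probability$values
           else result$group_maps[[key]][[field]]
      sl <- v[, , slice]
      data.frame(x = rep(seq_len(dm[1]), dm[2]),
                 y = rep(seq_len(dm[2]), each = dm[1]),
                 value = as.vector(sl), panel = key)
    }))
  }
  panel_plot <- function(field, title, limits = NULL) {
    df <- slice_df(field)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::facet_wrap(~panel) +
      ggplot2::coord_fixed() +
      ggplot2::scale_fill_viridis_c(limits = limits, na.value = "grey20") +
      ggplot2::labs(title = title, fill = field) +
      ggplot2::theme_minimal()
  }
  files <- character(0)
  save_fig <- function(name, plot, w = 7, h = 6) {
    f <- file.path(dir, name)
    grDevices::png(f, width = w * 100, height = h * 100, res = 100)
    print(plot)
    grDevices::dev.off()
    files <<- c(files, f)
  }
  save_fig("fig_probability_maps.png",
           panel_plot("probability", "Within-group probability of infarction",
                      limits = c(0, 1)))
  save_fig("fig_t2_maps.png", panel_plot("t2", "Group-mean T2 (ms)"))
  save_fig("fig_cbf_maps.png", panel_plot("cbf", "Group-mean CBF (mL/100g/min)"))

  ratio <- tb$roi_stats[tb$roi_stats$measure == "volume_ratio", ]
  bar <- ggplot2::ggplot(ratio, ggplot2::aes(x = .data$timepoint,
                                             y = .data$mean,
                                             fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::labs(y = "infarct / hemisphere volume ratio", x = NULL,
                  title = "Infarct volume ratios (mean +/- SEM)") +
    ggplot2::theme_minimal()
  save_fig("fig_volume_ratios.png", bar, w = 6, h = 4)

  prob_tab <- tb$roi_stats[tb$roi_stats$measure == "probability", ]
  func_tab <- tb$roi_stats[tb$roi_stats$measure %in% c("cbf", "adc"), ]
  utils::write.csv(prob_tab, f1 <- file.path(dir, "table_infarct_probabilities.csv"),
                   row.names = FALSE)
  utils::write.csv(func_tab, f2 <- file.path(dir, "table_cbf_adc.csv"),
                   row.names = FALSE)
  invisible(c(files, f1, f2))
}
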