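#' Binary lesion mask container
#'
#' @param mask logical 3-D array (atlas space).
#' @param method `"t2_threshold"` or `"manual_emulated"`.
#' @param threshold_ms threshold used (for `t2_threshold`).
#' @param timepoint `"2h"` or `"24h"`.
#' @param subject_id subject annotation.
#' @export
binary_lesion_mask <- function(mask, method = c("t2_threshold", "manual_emulated"),
                               threshold_ms = NA_real_, timepoint = NA_character_,
                               subject_id = NA_character_) {
  method <- match.arg(method)
  structure(list(mask = mask, method = method, threshold_ms = threshold_ms,
                 timepoint = timepoint, subject_id = subject_id),
            class = "lesion_mask")
}

as_mask_array <- function(x) {
  if (inherits(x, "lesion_mask")) x$mask
  else if (inherits(x, "brain_mask")) x$mask
  else x != 0
}

#' Threshold-based infarct segmentation from a T2 map
#'
#' Voxels inside the brain mask whose fitted T2 lies strictly below
#' `threshold_ms` (34 ms by default) are labelled infarcted. Invalid map
#' voxels are excluded, never imputed. The comparison is strict, so a uniform
#' map at exactly the threshold yields an empty mask; set `below = FALSE` to
#' select prolonged-T2 voxels instead if a phantom or field strength inverts
#' the contrast.
#'
#' @param t2_map a [quantitative_map()] with units ms.
#' @param threshold_ms segmentation threshold in ms (default 34).
#' @param brain_mask a `brain_mask` or logical 3-D array.
#' @param below if `TRUE` (default) infarct is T2 < threshold; if `FALSE`,
#'   T2 > threshold.
#' @param timepoint,subject_id annotations carried into the result.
#' @return a [binary_lesion_mask()] with method `"t2_threshold"`.
#' @export
segment_infarct_t2 <- function(t2_map, threshold_ms = 34, brain_mask,
                               below = TRUE, timepoint = NA_character_,
                               subject_id = NA_character_) {
  stopifnot(inherits(t2_map, "quant_map"))
  if (t2_map$units != "ms") stop("t2_map units must be ms")
  bm <- as_mask_array(brain_mask)
  stop_if_grid_mismatch(t2_map$values, bm)
  if (!any(bm)) stop("brain mask is empty")
  sel <- bm & t2_map$validity
  m <- array(FALSE, dim = dim(bm))
  m[sel] <- if (below) t2_map$values[sel] < threshold_ms
            else t2_map$values[sel] > threshold_ms
  binary_lesion_mask(m, "t2_threshold", threshold_ms, timepoint, subject_id)
}

#' Remove intraventricular CSF from a lesion mask
#'
#' Subtracts the atlas ventricle voxels from the segmentation, emulating the
#' single manual step of the original analysis. Idempotent.
#'
#' @param lesion a [binary_lesion_mask()].
#' @param ventricle_mask logical 3-D array on the same grid.
#' @export
remove_csf <- function(lesion, ventricle_mask) {
  stopifnot(inherits(lesion, "lesion_mask"))
  vm <- as_mask_array(ventricle_mask)
  stop_if_grid_mismatch(lesion$mask, vm)
  lesion$mask <- lesion$mask & !vm
  lesion
}

#' Emulated manual lesion segmentation from phantom ground truth
#'
#' Stands in for manual delineation on high-resolution T2-weighted anatomy:
#' returns the phantom's ground-truth lesion, optionally degraded by a rater
#' error of `rater_error_vox` morphological dilation (positive) or erosion
#' (negative) steps. With a seed the sign of the error is drawn once per call,
#' emulating rater variability reproducibly.
#'
#' @param ground_truth a `lesion_gt` from [lesion_ground_truth()].
#' @param timepoint `"2h"` or `"24h"`.
#' @param rater_error_vox integer number of dilation (>0) or erosion (<0)
#'   steps; 0 returns the ground truth exactly.
#' @param subject_id annotation.
#' @return a [binary_lesion_mask()] with method `"manual_emulated"`.
#' @export
segment_manual_emulated <- function(ground_truth, timepoint = c("24h", "2h"),
                                    rater_error_vox = 0L,
                                    subject_id = NA_character_) {
  if (!inherits(ground_truth, "lesion_gt"))
    stop("manual-emulated segmentation requires phantom ground truth")
  timepoint <- match.arg(timepoint)
  m <- lesion_mask(ground_truth, timepoint)
  m <- array(as.logical(m), dim = dim(m))
  k <- as.integer(rater_error_vox)
  if (k > 0) m <- dilate6_n(m, k)
  if (k < 0) for (i in seq_len(-k)) m <- erode6(m)
  binary_lesion_mask(m, "manual_emulated", NA_real_, timepoint, subject_id)
}

#' Infarct/hemisphere volume ratio
#'
#' Counts lesion voxels inside the ipsilateral (right) hemisphere and divides
#' by the hemisphere voxel count, the standard normalisation for whole-brain
#' infarct volumetry in the filament stroke model.
#'
#' @param lesion a [binary_lesion_mask()] in atlas space.
#' @param template an `atlas_template`.
#' @param side hemisphere used as denominator (only `"ipsilateral"`, the
#'   right hemisphere, is meaningful in this model).
#' @return object of class `volumetry_result`: lesion/hemisphere voxel counts,
#'   their ratio, and the voxel volume in mm^3.
#' @export
volume_ratio <- function(lesion, template, side = "ipsilateral") {
  stopifnot(inherits(lesion, "lesion_mask"))
  side <- match.arg(side, "ipsilateral")
  hemi <- template_mask(template, "right_hemisphere")
  stop_if_grid_mismatch(lesion$mask, hemi)
  if (!any(hemi)) stop("hemisphere label is empty")
  lv <- sum(lesion$mask & hemi)
  hv <- sum(hemi)
  ratio <- lv / hv
  if (any(lesion$mask & !hemi))
    attr(ratio, "outside_hemisphere") <- sum(lesion$mask & !hemi)
  structure(list(lesion_voxels = lv, hemisphere_voxels = hv,
                 ratio = as.numeric(ratio),
                 outside_hemisphere_voxels = sum(lesion$mask & !hemi),
                 voxel_volume_mm3 = voxel_volume_mm3(template$geometry),
                 subject_id = lesion$subject_id, timepoint = lesion$timepoint,
                 method = lesion$method),
            class = "volumetry_result")
}
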