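# NIfTI-1 I/O. Volumes are written with the grid spacing in pixdim; units and
# provenance go into a JSON sidecar next to each file, since the NIfTI
# description field is limited to 80 bytes.

nifti_image <- function(vol, geometry, datatype = "double") {
  vol <- vol * 1
  sp <- grid_spacing(geometry)
  attr(vol, "pixdim") <- if (length(dim(vol)) == 4L) c(sp, 1) else sp
  RNifti::asNifti(vol, datatype = datatype)
}

#' Write a 3-D/4-D volume as NIfTI-1
#' @param vol array to write (logical is converted to uint8).
#' @param geometry an `acq_geometry` providing the voxel spacing.
#' @param path output `.nii` / `.nii.gz` path.
#' @param datatype NIfTI datatype (e.g. `"double"`, `"uint8"`, `"int16"`).
#' @export
write_volume_nifti <- function(vol, geometry, path, datatype = "double") {
  if (is.logical(vol)) {
    vol <- array(as.integer(vol), dim = dim(vol))
    datatype <- "uint8"
  }
  RNifti::writeNifti(nifti_image(vol, geometry, datatype), path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#' @param path NIfTI file.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' Write a quantitative map (NIfTI + JSON sidecar with units)
#' @param map a [quantitative_map()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @export
write_map_nifti <- function(map, path) {
  stopifnot(inherits(map, "quant_map"))
  geom <- if (is.null(map$geometry)) acq_geometry(matrix_size = dim(map$values)[1:2],
                                                  n_slices = dim(map$values)[3])
          else map$geometry
  vals <- map$values
  vals[!map$validity & !is.finite(vals)] <- 0
  write_volume_nifti(vals, geom, path)
  write_volume_nifti(map$validity, geom, sub("\\.nii(\\.gz)?$", "_validity.nii\\1", path))
  jsonlite::write_json(list(units = map$units, n_valid = sum(map$validity)),
                       paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write one synthetic subject to disk (NIfTI volumes + ground-truth sidecar)
#'
#' One file per sequence (4-D for the echo train and IR series), the native
#' brain mask, and a JSON sidecar recording the seed, noise level, true
#' subject-to-atlas transform and the timing metadata.
#'
#' @param subject a `subject_raw`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @export
write_subject_nifti <- function(subject, dir, prefix = "subject") {
  stopifnot(inherits(subject, "subject_raw"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- subject$geometry
  p <- function(name) file.path(dir, sprintf("%s_%s.nii.gz", prefix, name))
  write_volume_nifti(subject$echo_train, g, p("cpmg"))
  write_volume_nifti(subject$dwi_b0, g, p("dwi_b0"))
  write_volume_nifti(subject$dwi_bpos, g, p("dwi_b800"))
  write_volume_nifti(subject$casl_control, g, p("casl_control"))
  write_volume_nifti(subject$casl_label, g, p("casl_label"))
  write_volume_nifti(subject$ir_series, g, p("ir"))
  write_volume_nifti(subject$brain_mask_native, g, p("brainmask"))
  jsonlite::write_json(list(
    seed = subject$seed, noise_sigma = subject$noise_sigma,
    echo_times_ms = subject$echo_times_ms,
    inversion_times_ms = subject$inversion_times_ms,
    b_s_per_mm2 = subject$b_s_per_mm2,
    misalignment = list(rotations_deg = subject$misalignment$rotations_deg,
                        translations_mm = subject$misalignment$translations_mm)
  ), file.path(dir, sprintf("%s_groundtruth.json", prefix)),
  auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write the atlas template (labels + reference) as NIfTI-1
#' @param template an `atlas_template`.
#' @param dir output directory.
#' @export
write_template_nifti <- function(template, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume_nifti(array(as.integer(template$labels), dim = dim(template$labels)),
                     template$geometry, file.path(dir, "template_labels.nii.gz"),
                     datatype = "int16")
  write_volume_nifti(template$reference, template$geometry,
                     file.path(dir, "template_reference.nii.gz"))
  invisible(dir)
}
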