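#' Acquisition geometry of a multimodal mouse-brain MRI session
#'
#' Describes the common voxel grid of all sequences (in-plane matrix, field of
#' view, coronal slice stack) together with the per-sequence timing parameters
#' needed by the forward models and the quantitative fits: the CPMG echo train
#' (echo spacing, number of echoes), the two diffusion weightings, and the
#' repetition times.
#'
#' The through-plane grid spacing is the interslice distance (slices are
#' acquired thinner than their spacing, as usual for multislice 2-D imaging);
#' voxel volume for volumetry uses the in-plane spacing times the interslice
#' distance, i.e. one grid cell.
#'
#' @param matrix_size integer vector of length 2, in-plane matrix (nx, ny).
#' @param fov_mm numeric length 2, in-plane field of view in mm.
#' @param n_slices integer, number of coronal slices.
#' @param slice_thickness_mm slice excitation thickness in mm (metadata).
#' @param interslice_distance_mm centre-to-centre slice spacing in mm; this is
#'   the z grid spacing.
#' @param echo_spacing_ms CPMG inter-echo spacing in ms; echo k is read out at
#'   `k * echo_spacing_ms`.
#' @param n_echoes number of echoes in the CPMG train (at least 20; the T2 fit
#'   consumes the first 20).
#' @param b_values_s_per_mm2 the two diffusion weightings; exactly one zero and
#'   one positive value.
#' @param tr_ms named numeric of per-sequence repetition times (metadata).
#' @return An object of class `acq_geometry`.
#' @export
acq_geometry <- function(matrix_size = c(64L, 64L),
                         fov_mm = c(25, 25),
                         n_slices = 13L,
                         slice_thickness_mm = 0.5,
                         interslice_distance_mm = 1.0,
                         echo_spacing_ms = 4.2,
                         n_echoes = 32L,
                         b_values_s_per_mm2 = c(0, 800),
                         tr_ms = c(cpmg = 2000, dwi = 2000, casl = 1000, ir = 10000)) {
  matrix_size <- as.integer(matrix_size)
  if (length(matrix_size) == 1L) matrix_size <- rep(matrix_size, 2L)
  fov_mm <- as.numeric(fov_mm)
  if (length(fov_mm) == 1L) fov_mm <- rep(fov_mm, 2L)
  stopifnot(length(matrix_size) == 2L, length(fov_mm) == 2L)
  if (any(matrix_size <= 0L) || any(fov_mm <= 0) || n_slices <= 0L)
    stop("matrix_size, fov_mm and n_slices must be positive")
  if (slice_thickness_mm <= 0 || interslice_distance_mm <= 0)
    stop("slice geometry must be positive")
  if (n_echoes < 20L)
    stop("n_echoes must be >= 20 (the T2 fit consumes the first 20 echoes)")
  b <- sort(as.numeric(b_values_s_per_mm2))
  if (length(b) != 2L || b[1] != 0 || b[2] <= 0)
    stop("b_values_s_per_mm2 must contain exactly one zero and one positive value")
  structure(list(
    matrix_size = matrix_size,
    fov_mm = fov_mm,
    n_slices = as.integer(n_slices),
    slice_thickness_mm = slice_thickness_mm,
    interslice_distance_mm = interslice_distance_mm,
    echo_spacing_ms = echo_spacing_ms,
    n_echoes = as.integer(n_echoes),
    b_values_s_per_mm2 = b,
    tr_ms = tr_ms
  ), class = "acq_geometry")
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf("<acq_geometry> %dx%dx%d grid, FOV %.1fx%.1f mm, dz %.2f mm\n",
              x$matrix_size[1], x$matrix_size[2], x$n_slices,
              x$fov_mm[1], x$fov_mm[2], x$interslice_distance_mm))
  cat(sprintf("  CPMG: %d echoes, spacing %.2f ms; b = {%g, %g} s/mm^2\n",
              x$n_echoes, x$echo_spacing_ms,
              x$b_values_s_per_mm2[1], x$b_values_s_per_mm2[2]))
  invisible(x)
}

#' Grid dimensions of a geometry
#' @param geometry an `acq_geometry`.
#' @return integer vector (nx, ny, nz).
#' @export
grid_dim <- function(geometry) {
  c(geometry$matrix_size, geometry$n_slices)
}

#' Grid spacing in mm
#' @param geometry an `acq_geometry`.
#' @return numeric (dx, dy, dz) in mm; dz is the interslice distance.
#' @export
grid_spacing <- function(geometry) {
  c(geometry$fov_mm / geometry$matrix_size, geometry$interslice_distance_mm)
}

#' Voxel volume in mm^3 (one grid cell)
#' @param geometry an `acq_geometry`.
#' @export
voxel_volume_mm3 <- function(geometry) prod(grid_spacing(geometry))

#' CPMG echo times in ms
#' @param geometry an `acq_geometry`.
#' @return numeric vector `echo_spacing_ms * (1:n_echoes)`.
#' @export
echo_times_ms <- function(geometry) geometry$echo_spacing_ms * seq_len(geometry$n_echoes)

# World coordinates: mm, origin at the volume centre, axes along voxel axes
# (RAS-like: x left->right, y posterior->anterior, z slice direction).
# Voxel indices are 0-based in these conversions.

#' Convert 0-based voxel indices to world mm coordinates
#' @param idx n x 3 matrix of 0-based voxel indices (may be fractional).
#' @param geometry an `acq_geometry`.
#' @return n x 3 matrix of world coordinates in mm, origin at the volume centre.
#' @export
vox_to_world <- function(idx, geometry) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sp <- grid_spacing(geometry)
  dm <- grid_dim(geometry)
  sweep(sweep(idx, 2L, (dm - 1) / 2, "-"), 2L, sp, "*")
}

#' Convert world mm coordinates to 0-based (fractional) voxel indices
#' @param w n x 3 matrix of world coordinates in mm.
#' @param geometry an `acq_geometry`.
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_vox <- function(w, geometry) {
  w <- matrix(as.numeric(w), ncol = 3L)
  sp <- grid_spacing(geometry)
  dm <- grid_dim(geometry)
  sweep(sweep(w, 2L, sp, "/"), 2L, (dm - 1) / 2, "+")
}

#' All voxel centres of a grid as 0-based indices
#' @param geometry an `acq_geometry`.
#' @return (nx*ny*nz) x 3 matrix in array (column-major) order.
#' @export
grid_index_matrix <- function(geometry) {
  dm <- grid_dim(geometry)
  cbind(
    rep.int(seq_len(dm[1]) - 1L, dm[2] * dm[3]),
    rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), dm[3]),
    rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2])
  )
}

#' Allocate a volume on the grid of a geometry
#' @param geometry an `acq_geometry`.
#' @param value fill value.
#' @export
vol_array <- function(geometry, value = 0) {
  array(value, dim = grid_dim(geometry))
}

stop_if_grid_mismatch <- function(..., what = "volumes") {
  dims <- lapply(list(...), dim)
  ref <- dims[[1]]
  for (d in dims)
    if (length(d) != length(ref) || any(d != ref))
      stop(sprintf("grid mismatch: %s must share one grid", what))
  invisible(NULL)
}
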