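#' Brain extraction
#'
#' In `ground_truth` mode the supplied phantom brain mask is returned
#' unchanged, emulating the manual scalp/skull stripping performed on real
#' animals. In `automatic` mode the volume is thresholded with Otsu's method,
#' the largest 6-connected component is kept and a one-step morphological
#' closing fills internal gaps.
#'
#' @param volume 3-D intensity volume (e.g. the first CPMG echo).
#' @param mode `"ground_truth"` or `"automatic"`.
#' @param ground_truth_mask logical 3-D mask (required in ground-truth mode).
#' @return object of class `brain_mask`: list with logical `mask` and `source`.
#' @export
extract_brain <- function(volume, mode = c("ground_truth", "automatic"),
                          ground_truth_mask = NULL) {
  mode <- match.arg(mode)
  if (mode == "ground_truth") {
    if (is.null(ground_truth_mask)) stop("ground_truth mode needs a phantom mask")
    m <- ground_truth_mask != 0
    if (!any(m)) stop("brain extraction produced an empty mask")
    return(structure(list(mask = array(m, dim = dim(ground_truth_mask)),
                          source = "ground_truth"), class = "brain_mask"))
  }
  if (all(volume == volume[1])) stop("cannot extract brain from a constant image")
  thr <- otsu_threshold(volume)
  m <- volume > thr
  if (!any(m)) stop("brain extraction produced an empty mask")
  m <- largest_component(m)
  m <- closing_inplane(m, 1L)
  structure(list(mask = m, source = "threshold_morphology"), class = "brain_mask")
}

# masked normalized cross-correlation between two vectors
ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

# Build a fast NCC objective for a fixed mask: the world coordinates of the
# masked fixed voxels are precomputed once; each evaluation pulls them back
# through the candidate pose and interpolates the moving image there.
# Out-of-field voxels are dropped from the correlation.
make_ncc_objective <- function(moving, fixed, fixed_mask, moving_geom, fixed_geom) {
  sel <- which(fixed_mask)
  dmf <- grid_dim(fixed_geom)
  idx <- arrayInd(sel, dmf) - 1L
  w_fixed <- vox_to_world(idx, fixed_geom)
  f_vals <- fixed[sel]
  function(par) {
    tr <- rigid_transform(par[1:3], par[4:6])
    w_mov <- apply_transform(invert_transform(tr), w_fixed)
    q <- world_to_vox(w_mov, moving_geom)
    s <- sample_trilinear(moving, q)
    if (sum(s$valid) < 32) return(NA_real_)
    ncc(s$values[s$valid], f_vals[s$valid])
  }
}

# metric for a candidate pose (exposed for monotonicity checks)
registration_metric <- function(par, moving, fixed, fixed_mask,
                                moving_geom, fixed_geom) {
  make_ncc_objective(moving, fixed, fixed_mask, moving_geom, fixed_geom)(par)
}

#' Rigid 6-DOF registration by masked NCC and derivative-free search
#'
#' Estimates the rigid transform mapping `moving` onto `fixed` by maximising
#' the normalized cross-correlation inside the fixed mask. The search is
#' multi-resolution: a 2x in-plane downsampled level is explored first with a
#' small multi-start stencil (identity plus axis-aligned offsets of the given
#' rotation/translation radii) followed by Nelder-Mead refinement, and the
#' best coarse pose is refined at full resolution. Both images are lightly
#' Gaussian-smoothed before the metric is evaluated so that the optimum is
#' well-defined at sub-voxel scale.
#'
#' @param moving,fixed 3-D intensity volumes.
#' @param moving_geometry,fixed_geometry their `acq_geometry`s.
#' @param fixed_mask logical 3-D mask on the fixed grid restricting the metric
#'   (default: voxels where `fixed` exceeds 1% of its maximum, dilated once).
#' @param init optional `rigid_transform` starting pose.
#' @param multistart_rot_deg,multistart_trans_vox multi-start stencil radii.
#' @param smooth_sigma_vox Gaussian pre-smoothing sigma (in voxels, in-plane).
#' @param maxit_coarse,maxit_fine Nelder-Mead iteration budgets.
#' @return a `rigid_transform` (moving world to fixed world) with attributes
#'   `metric_initial`, `metric_final` and `converged`.
#' @export
register_rigid <- function(moving, fixed, moving_geometry, fixed_geometry,
                           fixed_mask = NULL, init = rigid_transform(),
                           multistart_rot_deg = 2, multistart_trans_vox = 1,
                           smooth_sigma_vox = 2,
                           maxit_coarse = 400L, maxit_fine = 250L) {
  stop_if_grid_mismatch(fixed, if (is.null(fixed_mask)) fixed else fixed_mask)
  if (stats::sd(moving) == 0 || stats::sd(fixed) == 0)
    stop("cannot register constant (degenerate) images")
  if (is.null(fixed_mask))
    fixed_mask <- dilate6(fixed > 0.01 * max(fixed))
  if (!any(fixed_mask)) stop("fixed mask is empty")

  sig <- c(smooth_sigma_vox, smooth_sigma_vox, 0.5 * smooth_sigma_vox)
  mov_s <- smooth_gaussian(moving, sig)
  fix_s <- smooth_gaussian(fixed, sig)

  # coarse level: 2x in-plane downsampling (same FOV, half the matrix)
  coarse_geom <- function(g) {
    acq_geometry(matrix_size = g$matrix_size %/% 2L, fov_mm = g$fov_mm,
                 n_slices = g$n_slices,
                 slice_thickness_mm = g$slice_thickness_mm,
                 interslice_distance_mm = g$interslice_distance_mm,
                 echo_spacing_ms = g$echo_spacing_ms, n_echoes = g$n_echoes,
                 b_values_s_per_mm2 = g$b_values_s_per_mm2, tr_ms = g$tr_ms)
  }
  mg_c <- coarse_geom(moving_geometry)
  fg_c <- coarse_geom(fixed_geometry)
  mov_c <- downsample2_inplane(mov_s)
  fix_c <- downsample2_inplane(fix_s)
  msk_c <- downsample2_inplane(fixed_mask * 1) > 0.25

  obj_coarse <- make_ncc_objective(mov_c, fix_c, msk_c, mg_c, fg_c)
  obj_fine <- make_ncc_objective(mov_s, fix_s, fixed_mask, moving_geometry,
                                 fixed_geometry)
  f_coarse <- function(p) { m <- obj_coarse(p); if (is.na(m)) 1 else -m }
  f_fine <- function(p) { m <- obj_fine(p); if (is.na(m)) 1 else -m }

  p0 <- c(init$rotations_deg, init$translations_mm)
  sp <- grid_spacing(fixed_geometry)
  starts <- list(p0)
  for (ax in 1:3) for (sgn in c(-1, 1)) {
    pr <- p0; pr[ax] <- pr[ax] + sgn * multistart_rot_deg
    starts[[length(starts) + 1L]] <- pr
    pt <- p0; pt[3 + ax] <- pt[3 + ax] + sgn * multistart_trans_vox * sp[ax]
    starts[[length(starts) + 1L]] <- pt
  }
  vals <- vapply(starts, f_coarse, numeric(1))
  best <- starts[order(vals)[1:2]]
  coarse_fits <- lapply(best, function(p)
    stats::optim(p, f_coarse, method = "Nelder-Mead",
                 control = list(maxit = maxit_coarse, reltol = 1e-12)))
  cbest <- coarse_fits[[which.min(vapply(coarse_fits, `[[`, numeric(1), "value"))]]

  fine <- stats::optim(cbest$par, f_fine, method = "Nelder-Mead",
                       control = list(maxit = maxit_fine, reltol = 1e-14))
  # one restart from the optimum tightens the simplex for sub-voxel accuracy
  fine <- stats::optim(fine$par, f_fine, method = "Nelder-Mead",
                       control = list(maxit = maxit_fine, reltol = 1e-14,
                                      parscale = c(rep(0.5, 3), sp * 0.5)))
  metric_initial <- -f_fine(p0)
  metric_final <- -fine$value
  if (is.na(metric_final) || metric_final < metric_initial - 1e-9)
    warning(sprintf("registration did not improve the metric (%.5f -> %.5f)",
                    metric_initial, metric_final))
  out <- rigid_transform(fine$par[1:3], fine$par[4:6])
  attr(out, "metric_initial") <- metric_initial
  attr(out, "metric_final") <- metric_final
  attr(out, "converged") <- fine$convergence == 0
  out
}

#' Step-wise registration of one subject's timepoints to the atlas
#'
#' Mirrors the step-wise 6-DOF procedure used for serial small-animal imaging:
#' the 2 h volume is first aligned to the 24 h volume of the same subject
#' (intra-subject alignment), the 24 h volume is registered to the template
#' reference, and the 2 h-to-atlas transform is obtained by composition.
#'
#' @param vol_2h,vol_24h native-space intensity volumes of the two timepoints.
#' @param geometry their acquisition geometry.
#' @param template an `atlas_template`.
#' @param ... passed to [register_rigid()].
#' @return list with `rigid_transform`s `to_atlas_2h`, `to_atlas_24h` and the
#'   intermediate `intra_2h_to_24h`.
#' @export
register_subject_stepwise <- function(vol_2h, vol_24h, geometry, template, ...) {
  intra <- register_rigid(vol_2h, vol_24h, geometry, geometry, ...)
  to_atl_24 <- register_rigid(vol_24h, template$reference, geometry,
                              template$geometry,
                              fixed_mask = dilate6(template_mask(template, "brain")),
                              ...)
  list(intra_2h_to_24h = intra,
       to_atlas_24h = to_atl_24,
       to_atlas_2h = compose_transforms(to_atl_24, intra))
}

#' Resample a subject's maps and masks into atlas space
#'
#' Applies the estimated subject-to-atlas transform to every quantitative map
#' (trilinear, with validity masks propagated by nearest-neighbour
#' interpolation and out-of-field voxels invalidated) and to every mask
#' (nearest), landing all of them on the template grid.
#'
#' @param maps named list of [quantitative_map()]s in native space.
#' @param masks named list of logical 3-D arrays in native space.
#' @param transform `rigid_transform` mapping subject world to atlas world.
#' @param template an `atlas_template`.
#' @param source_geometry native-space geometry of the masks (and of any map
#'   that does not carry its own); defaults to the template grid.
#' @return list with elements `maps` and `masks` on the template grid.
#' @export
to_atlas <- function(maps, masks = list(), transform, template,
                     source_geometry = template$geometry,
                     map_interpolation = c("trilinear", "nearest")) {
  map_interpolation <- match.arg(map_interpolation)
  geom_t <- template$geometry
  out_maps <- lapply(maps, function(m) {
    stopifnot(inherits(m, "quant_map"))
    src_geom <- if (is.null(m$geometry)) source_geometry else m$geometry
    vals <- m$values
    vals[!m$validity] <- 0
    if (map_interpolation == "trilinear") {
      # validity-weighted (normalized) interpolation: invalid voxels carry
      # zero weight instead of bleeding zeros into the interpolated values
      num <- resample_volume(vals, transform, src_geom, geom_t, "trilinear")
      den <- resample_volume(m$validity * 1, transform, src_geom, geom_t,
                             "trilinear")
      validity <- den > 0.5 & attr(num, "valid")
      vv <- array(NA_real_, dim = grid_dim(geom_t))
      vv[validity] <- num[validity] / den[validity]
    } else {
      rs <- resample_volume(vals, transform, src_geom, geom_t, "nearest")
      vmask <- resample_volume(m$validity, transform, src_geom, geom_t,
                               "nearest")
      validity <- vmask & attr(rs, "valid")
      vv <- array(as.numeric(rs), dim = grid_dim(geom_t))
      vv[!validity] <- NA_real_
    }
    quantitative_map(vv, m$units, validity, geom_t, list())
  })
  out_masks <- lapply(masks, function(m) {
    rs <- resample_volume(m != 0, transform, source_geometry, geom_t, "nearest")
    array(rs & attr(rs, "valid"), dim = grid_dim(geom_t))
  })
  list(maps = out_maps, masks = out_masks)
}
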