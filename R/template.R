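#' Atlas label codes
#'
#' Integer codes used in the template label volume: background, left-hemisphere
#' tissue, right-hemisphere tissue, the cortical ROI in the centre of the MCA
#' territory, the subcortical ROI (caudoputamen + pyramidal tract), and the
#' ventricles. The two ROIs lie entirely in the right (ipsilateral) hemisphere.
#' @export
atlas_labels <- function() {
  c(background = 0L, left_hemisphere = 1L, right_hemisphere = 2L,
    cortex_mca = 3L, subcortex = 4L, ventricle = 5L)
}

#' Build the digital mouse-brain atlas template
#'
#' Constructs a deterministic label volume on the acquisition grid: an
#' ellipsoidal brain split into left/right hemispheres, a lateral cortical-band
#' ROI standing for the centre of the MCA territory, a deep subcortical ROI
#' (caudoputamen + pyramidal tract analogue) and paired ventricles near the
#' midline, plus a piecewise-constant reference intensity volume (with a smooth
#' spatial modulation) used as the registration target.
#'
#' The construction is purely geometric, so identical geometry always yields a
#' bit-identical template. Both ROIs are carved from the right hemisphere and
#' are disjoint from each other and from the ventricles.
#'
#' @param geometry an [acq_geometry()]; in-plane matrix must be at least 16.
#' @return An object of class `atlas_template` with elements `labels` (integer
#'   3-D array), `reference` (numeric 3-D array) and `geometry`.
#' @export
build_template <- function(geometry = acq_geometry()) {
  stopifnot(inherits(geometry, "acq_geometry"))
  dm <- grid_dim(geometry)
  if (any(geometry$matrix_size < 16L))
    stop("matrix size too small to host all atlas labels (need >= 16 in-plane)")
  lb <- atlas_labels()

  idx <- grid_index_matrix(geometry)
  w <- vox_to_world(idx, geometry)
  rr <- template_radii(geometry)
  rx <- rr["rx"]; ry <- rr["ry"]; rz <- rr["rz"]
  e <- (w[, 1] / rx)^2 + (w[, 2] / ry)^2 + (w[, 3] / rz)^2
  brain <- e <= 1

  labels <- integer(nrow(w))
  labels[brain & w[, 1] < 0] <- lb[["left_hemisphere"]]
  labels[brain & w[, 1] >= 0] <- lb[["right_hemisphere"]]

  # cortical MCA-centre ROI: outer band of the right hemisphere, lateral and
  # restricted to the central slices (the imaging slab is centred at bregma)
  zfrac <- abs(w[, 3]) / rz
  cortex <- brain & w[, 1] >= 0 & e >= 0.45 & (w[, 1] / rx) >= 0.30 & zfrac <= 0.68
  labels[cortex] <- lb[["cortex_mca"]]

  # subcortical ROI: deep ellipsoid in the right hemisphere (basal ganglia)
  sub_c <- c(0.38 * rx, -0.05 * ry, 0)
  es <- ((w[, 1] - sub_c[1]) / (0.22 * rx))^2 +
        ((w[, 2] - sub_c[2]) / (0.28 * ry))^2 +
        ((w[, 3] - sub_c[3]) / (0.45 * rz))^2
  subc <- brain & es <= 1 & !cortex
  labels[subc] <- lb[["subcortex"]]

  # paired ventricles near the midline, clear of both ROIs
  for (sgn in c(-1, 1)) {
    ev <- ventricle_metric(w, rr, sgn)
    vent <- brain & ev <= 1 & !cortex & !subc
    labels[vent] <- lb[["ventricle"]]
  }

  lab_arr <- array(labels, dim = dm)
  if (!all(lb %in% unique(labels)))
    stop("degenerate template: not all label classes are present on this grid")

  # reference intensity: the noise-free proton-density (b = 0) image of a
  # healthy brain — the same analytic S0 field every synthesized subject is
  # built from — so subject b0 images and the template share contrast exactly
  # and the correlation metric peaks at the true pose
  lv <- default_tissue_levels()
  ref <- s0_analytic(w, geometry, lv$healthy$s0, lv$csf$s0)
  ref_arr <- array(ref, dim = dm)

  structure(list(labels = lab_arr, reference = ref_arr, geometry = geometry),
            class = "atlas_template")
}

#' @export
print.atlas_template <- function(x, ...) {
  tb <- table(factor(x$labels, levels = atlas_labels(),
                     labels = names(atlas_labels())))
  cat("<atlas_template>\n")
  print(tb)
  invisible(x)
}

# ellipsoid radii of the phantom brain for a given grid (mm)
template_radii <- function(geometry) {
  fov <- geometry$fov_mm
  zspan <- (geometry$n_slices - 1) / 2 * grid_spacing(geometry)[3]
  c(rx = 0.72 * fov[1] / 2, ry = 0.80 * fov[2] / 2,
    rz = max(zspan * 0.95, grid_spacing(geometry)[3]))
}

ventricle_metric <- function(w, rr, sgn) {
  ((w[, 1] - sgn * 0.12 * rr[["rx"]]) / (0.07 * rr[["rx"]]))^2 +
  ((w[, 2] - 0.18 * rr[["ry"]]) / (0.16 * rr[["ry"]]))^2 +
  ((w[, 3]) / (0.30 * rr[["rz"]]))^2
}

# Smooth deterministic proton-density texture, a function of atlas world
# coordinates (mm): low-frequency sinusoids emulating the intensity structure
# real brains present to an intra-modality registration metric. Shared by the
# template reference and every synthesized subject's S0 field.
s0_texture <- function(w) {
  1 + 0.12 * sin(2 * pi * w[, 1] / 9.5) * cos(2 * pi * w[, 2] / 7.5) +
      0.08 * cos(2 * pi * (w[, 2] + 0.6 * w[, 1]) / 11) +
      0.06 * sin(2 * pi * w[, 3] / 9 + w[, 1] / 4)
}

# Analytic proton-density (S0) field of the phantom, as a function of atlas
# world coordinates: tissue level inside the brain ellipsoid with a smooth
# (sigmoidal, ~1 voxel) edge profile emulating partial-volume roll-off, a CSF
# bump in each ventricle, multiplied by the texture. Evaluating this function
# at exact transformed coordinates gives displaced subjects an acquisition-
# like image free of resampling blur, which keeps the registration metric's
# optimum at the true pose.
s0_analytic <- function(w, geometry, s0_tissue, s0_csf, edge_soft = 0.06) {
  rr <- template_radii(geometry)
  e <- (w[, 1] / rr[["rx"]])^2 + (w[, 2] / rr[["ry"]])^2 + (w[, 3] / rr[["rz"]])^2
  w_brain <- stats::plogis((1 - e) / edge_soft)
  w_vent <- pmax(stats::plogis((1 - ventricle_metric(w, rr, -1)) / edge_soft),
                 stats::plogis((1 - ventricle_metric(w, rr, 1)) / edge_soft))
  (s0_tissue + (s0_csf - s0_tissue) * w_vent) * w_brain * s0_texture(w)
}

#' Extract a named mask from the template
#'
#' @param template an `atlas_template`.
#' @param what one of `"brain"`, `"left_hemisphere"`, `"right_hemisphere"`
#'   (hemisphere tissue including its ROIs and ventricle), `"cortex_mca"`,
#'   `"subcortex"`, `"ventricle"`.
#' @return logical 3-D array.
#' @export
template_mask <- function(template, what = c("brain", "right_hemisphere",
                                             "left_hemisphere", "cortex_mca",
                                             "subcortex", "ventricle")) {
  what <- match.arg(what)
  lb <- atlas_labels()
  lab <- template$labels
  if (what == "brain") return(lab > 0L)
  if (what %in% c("cortex_mca", "subcortex", "ventricle"))
    return(lab == lb[[what]])
  # hemispheres: tissue label plus ROIs/ventricle voxels on that side of x = 0
  dm <- dim(lab)
  geom <- template$geometry
  wx <- array(vox_to_world(grid_index_matrix(geom), geom)[, 1], dim = dm)
  side <- if (what == "right_hemisphere") wx >= 0 else wx < 0
  (lab > 0L) & side
}

.growth_cache <- new.env(parent = emptyenv())

# deterministic geodesic ordering of the cortical ROI used by lesion growth:
# BFS layers (6-connectivity) from an origin voxel, ties broken by Euclidean
# distance to the origin, then by linear index. A prefix of this ordering is
# always a connected set, and orderings for the same origin are identical, so
# lesions with larger cortical fractions nest those with smaller ones.
cortex_growth_order <- function(template, origin_lin) {
  key <- sprintf("%s|%d", paste(dim(template$labels), collapse = "x"), origin_lin)
  cached <- get0(key, envir = .growth_cache, inherits = FALSE)
  if (!is.null(cached)) return(cached)
  lab <- template$labels
  roi <- lab == atlas_labels()[["cortex_mca"]]
  dm <- dim(roi)
  depth <- array(NA_integer_, dim = dm)
  frontier <- array(FALSE, dim = dm)
  frontier[origin_lin] <- TRUE
  depth[origin_lin] <- 0L
  d <- 0L
  while (any(frontier)) {
    d <- d + 1L
    grown <- dilate6(frontier)
    frontier <- grown & roi & is.na(depth)
    depth[frontier] <- d
  }
  lin <- which(roi & !is.na(depth))
  idx <- arrayInd(lin, dm) - 1L
  org <- arrayInd(origin_lin, dm) - 1L
  sp <- grid_spacing(template$geometry)
  dist <- sqrt(((idx[, 1] - org[1]) * sp[1])^2 +
               ((idx[, 2] - org[2]) * sp[2])^2 +
               ((idx[, 3] - org[3]) * sp[3])^2)
  out <- lin[order(depth[lin], dist, lin)]
  assign(key, out, envir = .growth_cache)
  out
}

# origin voxel for cortical growth: one of the cortical ROI voxels nearest the
# subcortex centroid; rng_seed picks deterministically among the closest few,
# emulating between-animal variation in where cortical extension begins.
cortex_growth_origin <- function(template, rng_seed) {
  lab <- template$labels
  dm <- dim(lab)
  roi_lin <- which(lab == atlas_labels()[["cortex_mca"]])
  sub_lin <- which(lab == atlas_labels()[["subcortex"]])
  sp <- grid_spacing(template$geometry)
  ctr <- colMeans(sweep(arrayInd(sub_lin, dm), 2L, sp, "*"))
  roi_ijk <- sweep(arrayInd(roi_lin, dm), 2L, sp, "*")
  dist <- sqrt(rowSums(sweep(roi_ijk, 2L, ctr, "-")^2))
  cand <- roi_lin[order(dist, roi_lin)][seq_len(min(5L, length(roi_lin)))]
  old <- local_seed(rng_seed)
  on.exit(restore_seed(old))
  cand[sample.int(length(cand), 1L)]
}

#' Generate a ground-truth lesion mask
#'
#' The lesion always covers the full subcortical ROI (subcortical infarction is
#' complete early after occlusion, reflecting the poor collateral supply of the
#' basal ganglia) plus a connected portion of the cortical MCA ROI covering
#' `cortical_fraction` of its voxels, grown geodesically from an origin near
#' the subcortex. Growth ordering is deterministic given the template and seed,
#' so for the same seed a larger fraction strictly nests a smaller one — this
#' guarantees 2 h lesions are subsets of 24 h lesions.
#'
#' @param template an `atlas_template`.
#' @param timepoint `"2h"` or `"24h"` (recorded; the geometry of the mask is
#'   controlled by `cortical_fraction`).
#' @param cortical_fraction fraction of the cortical ROI infarcted, in `[0,1]`.
#' @param rng_seed integer seed selecting the cortical growth origin.
#' @return logical 3-D array with attributes `timepoint`, `cortical_fraction`,
#'   `rng_seed`.
#' @export
make_lesion <- function(template, timepoint = c("24h", "2h"),
                        cortical_fraction, rng_seed = 1L) {
  timepoint <- match.arg(timepoint)
  if (!is.numeric(cortical_fraction) || cortical_fraction < 0 || cortical_fraction > 1)
    stop("cortical_fraction must lie in [0, 1]")
  lesion <- template_mask(template, "subcortex")
  roi_lin <- which(template_mask(template, "cortex_mca"))
  n_take <- round(cortical_fraction * length(roi_lin))
  if (n_take > 0) {
    origin <- cortex_growth_origin(template, rng_seed)
    ord <- cortex_growth_order(template, origin)
    lesion[ord[seq_len(n_take)]] <- TRUE
  }
  structure(lesion, timepoint = timepoint, cortical_fraction = cortical_fraction,
            rng_seed = rng_seed)
}

#' Paired 2 h / 24 h lesion ground truth for one subject
#'
#' Builds nested lesion masks for both imaging timepoints from one seed: the
#' lesion evolves from the subcortex into the cortex over time, so the 24 h
#' cortical fraction must be at least the 2 h fraction (enforced).
#'
#' @param template an `atlas_template`.
#' @param cortical_fraction_2h,cortical_fraction_24h fractions of the cortical
#'   ROI infarcted at each timepoint, in `[0,1]`.
#' @param strain_label cohort strain annotation (e.g. `"C57Bl/6"`, `"Sv/129"`).
#' @param rng_seed integer seed shared by both timepoints (guarantees nesting).
#' @return An object of class `lesion_gt` with logical volumes
#'   `lesion_mask_2h`, `lesion_mask_24h` and the generating parameters.
#' @export
lesion_ground_truth <- function(template, cortical_fraction_2h,
                                cortical_fraction_24h,
                                strain_label = "C57Bl/6", rng_seed = 1L) {
  f24 <- max(cortical_fraction_24h, cortical_fraction_2h)
  m2 <- make_lesion(template, "2h", cortical_fraction_2h, rng_seed)
  m24 <- make_lesion(template, "24h", f24, rng_seed)
  structure(list(lesion_mask_2h = m2, lesion_mask_24h = m24,
                 strain_label = strain_label,
                 cortical_fraction_2h = cortical_fraction_2h,
                 cortical_fraction_24h = f24,
                 rng_seed = rng_seed),
            class = "lesion_gt")
}

#' Lesion mask of a `lesion_gt` at a timepoint
#' @param lesion a `lesion_gt`.
#' @param timepoint `"2h"` or `"24h"`.
#' @export
lesion_mask <- function(lesion, timepoint = c("24h", "2h")) {
  timepoint <- match.arg(timepoint)
  if (timepoint == "2h") lesion$lesion_mask_2h else lesion$lesion_mask_24h
}
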