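#' Rigid (6-DOF) spatial transform
#'
#' Three rotations (degrees, applied in x-y-z order, i.e. `R = Rz Ry Rx`) about
#' the volume centre and three translations (mm). A transform maps points in
#' the moving volume's world frame to the fixed volume's world frame:
#' `w' = R (w - c) + c + t`, with `c` the rotation centre (the volume centre,
#' i.e. the world origin of the grids used here).
#'
#' @param rotations_deg numeric length 3, rotations about x, y, z in degrees.
#' @param translations_mm numeric length 3, translations in mm.
#' @param center_mm rotation centre in world mm (default the volume centre,
#'   which is the world origin).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotations_deg = c(0, 0, 0),
                            translations_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  stopifnot(length(rotations_deg) == 3L, length(translations_mm) == 3L)
  structure(list(rotations_deg = as.numeric(rotations_deg),
                 translations_mm = as.numeric(translations_mm),
                 center_mm = as.numeric(center_mm)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %.3f %.3f %.3f | trans (mm): %.3f %.3f %.3f\n",
              x$rotations_deg[1], x$rotations_deg[2], x$rotations_deg[3],
              x$translations_mm[1], x$translations_mm[2], x$translations_mm[3]))
  invisible(x)
}

rotation_matrix_zyx <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

euler_zyx_from_matrix <- function(R) {
  beta <- asin(max(-1, min(1, -R[3, 1])))
  alpha <- atan2(R[3, 2], R[3, 3])
  gamma <- atan2(R[2, 1], R[1, 1])
  c(alpha, beta, gamma) * 180 / pi
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param transform a `rigid_transform`.
#' @export
transform_matrix <- function(transform) {
  R <- rotation_matrix_zyx(transform$rotations_deg)
  c0 <- transform$center_mm
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- c0 + transform$translations_mm - R %*% c0
  A
}

matrix_to_transform <- function(A, center_mm = c(0, 0, 0)) {
  R <- A[1:3, 1:3]
  a <- A[1:3, 4]
  t <- as.numeric(a - center_mm + R %*% center_mm)
  rigid_transform(euler_zyx_from_matrix(R), t, center_mm)
}

#' Compose two rigid transforms (`first` applied first, then `second`)
#' @param second,first `rigid_transform`s sharing a rotation centre.
#' @export
compose_transforms <- function(second, first) {
  stopifnot(all(second$center_mm == first$center_mm))
  matrix_to_transform(transform_matrix(second) %*% transform_matrix(first),
                      second$center_mm)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  matrix_to_transform(solve(transform_matrix(transform)), transform$center_mm)
}

#' Apply a rigid transform to world points
#' @param transform a `rigid_transform`.
#' @param w n x 3 matrix of world coordinates (mm).
#' @export
apply_transform <- function(transform, w) {
  A <- transform_matrix(transform)
  w <- matrix(as.numeric(w), ncol = 3L)
  sweep(w %*% t(A[1:3, 1:3]), 2L, A[1:3, 4], "+")
}

is_identity_transform <- function(transform, tol = 1e-12) {
  all(abs(transform$rotations_deg) < tol) && all(abs(transform$translations_mm) < tol)
}

# vectorised trilinear sampling of vol at fractional 0-based voxel coords;
# returns list(values, valid); out-of-field -> fill and valid = FALSE
sample_trilinear <- function(vol, q, fill = 0) {
  dm <- dim(vol)
  qi <- q[, 1]; qj <- q[, 2]; qk <- q[, 3]
  valid <- qi >= 0 & qi <= dm[1] - 1 &
           qj >= 0 & qj <= dm[2] - 1 &
           qk >= 0 & qk <= dm[3] - 1
  out <- rep(fill, length(qi))
  if (any(valid)) {
    # clamp the base corner so exact top-edge queries interpolate with weight 1
    i0v <- pmin(floor(qi[valid]), dm[1] - 2)
    j0v <- pmin(floor(qj[valid]), dm[2] - 2)
    k0v <- pmin(floor(qk[valid]), dm[3] - 2)
    fiv <- qi[valid] - i0v; fjv <- qj[valid] - j0v; fkv <- qk[valid] - k0v
    lin <- function(di, dj, dk)
      vol[cbind(i0v + di + 1, j0v + dj + 1, k0v + dk + 1)]
    out[valid] <-
      lin(0, 0, 0) * (1 - fiv) * (1 - fjv) * (1 - fkv) +
      lin(1, 0, 0) * fiv * (1 - fjv) * (1 - fkv) +
      lin(0, 1, 0) * (1 - fiv) * fjv * (1 - fkv) +
      lin(1, 1, 0) * fiv * fjv * (1 - fkv) +
      lin(0, 0, 1) * (1 - fiv) * (1 - fjv) * fkv +
      lin(1, 0, 1) * fiv * (1 - fjv) * fkv +
      lin(0, 1, 1) * (1 - fiv) * fjv * fkv +
      lin(1, 1, 1) * fiv * fjv * fkv
  }
  list(values = out, valid = valid)
}

sample_nearest <- function(vol, q, fill = 0) {
  dm <- dim(vol)
  i <- round(q[, 1]); j <- round(q[, 2]); k <- round(q[, 3])
  valid <- i >= 0 & i <= dm[1] - 1 & j >= 0 & j <= dm[2] - 1 &
           k >= 0 & k <= dm[3] - 1
  out <- rep(fill, nrow(q))
  out[valid] <- vol[cbind(i[valid] + 1, j[valid] + 1, k[valid] + 1)]
  list(values = out, valid = valid)
}

#' Resample a volume under a rigid transform onto a target grid
#'
#' `transform` maps the moving volume's world frame to the fixed (target)
#' frame; each target voxel is pulled back through the inverse transform and
#' the moving volume is interpolated there. Out-of-field voxels receive `fill`
#' and are reported in the `valid` attribute so they can be excluded from
#' downstream masks and ROI statistics.
#'
#' Nearest-neighbour interpolation must be used for label/mask volumes;
#' passing a logical or integer volume with `interpolation = "trilinear"` is
#' an error (set `allow_label_trilinear = TRUE` to demote it to a warning).
#'
#' @param volume 3-D array (numeric, integer or logical).
#' @param transform a `rigid_transform` (moving world to fixed world).
#' @param source_geometry,target_geometry `acq_geometry` of the moving volume
#'   and of the output grid.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill value assigned outside the moving field of view.
#' @param allow_label_trilinear demote the label/trilinear guard to a warning.
#' @return array on the target grid, with logical attribute `valid`.
#' @export
resample_volume <- function(volume, transform, source_geometry, target_geometry,
                            interpolation = c("trilinear", "nearest"),
                            fill = 0, allow_label_trilinear = FALSE) {
  interpolation <- match.arg(interpolation)
  if (interpolation == "trilinear" && (is.logical(volume) || is.integer(volume))) {
    msg <- "trilinear interpolation requested for a label/mask volume; use nearest"
    if (allow_label_trilinear) warning(msg) else stop(msg)
  }
  was_logical <- is.logical(volume)
  vol <- if (was_logical) (volume * 1) else volume
  tdm <- grid_dim(target_geometry)

  if (interpolation == "nearest" && is_identity_transform(transform) &&
      identical(grid_dim(source_geometry), tdm) &&
      identical(grid_spacing(source_geometry), grid_spacing(target_geometry))) {
    out <- volume
    attr(out, "valid") <- array(TRUE, dim = tdm)
    return(out)
  }

  w_fixed <- vox_to_world(grid_index_matrix(target_geometry), target_geometry)
  w_moving <- apply_transform(invert_transform(transform), w_fixed)
  q <- world_to_vox(w_moving, source_geometry)
  s <- if (interpolation == "trilinear") sample_trilinear(vol, q, fill)
       else sample_nearest(vol, q, fill)
  out <- array(s$values, dim = tdm)
  if (was_logical) out <- array(out != 0, dim = tdm)
  attr(out, "valid") <- array(s$valid, dim = tdm)
  out
}

#' Serialize a rigid transform to JSON
#' @param transform a `rigid_transform`.
#' @param path output file.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(list(
    rotations_deg = transform$rotations_deg,
    translations_mm = transform$translations_mm,
    center_mm = transform$center_mm,
    convention = "moving-world to fixed-world; R = Rz Ry Rx about volume centre"
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path file written by [write_transform_json()].
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotations_deg, x$translations_mm, x$center_mm)
}
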