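# Small 3-D image utilities: axis shifts, 6-connected morphology, Otsu
# thresholding, connected components (via igraph), separable Gaussian
# smoothing and 2x in-plane downsampling. All operate on plain 3-D arrays.

shift3 <- function(x, dx = 0L, dy = 0L, dz = 0L, fill = FALSE) {
  dm <- dim(x)
  out <- array(fill, dim = dm)
  sx <- seq_len(dm[1]); sy <- seq_len(dm[2]); sz <- seq_len(dm[3])
  src_x <- sx - dx; src_y <- sy - dy; src_z <- sz - dz
  ok_x <- src_x >= 1L & src_x <= dm[1]
  ok_y <- src_y >= 1L & src_y <= dm[2]
  ok_z <- src_z >= 1L & src_z <= dm[3]
  out[sx[ok_x], sy[ok_y], sz[ok_z]] <- x[src_x[ok_x], src_y[ok_y], src_z[ok_z]]
  out
}

dilate6 <- function(mask) {
  mask |
    shift3(mask,  1L, 0L, 0L) | shift3(mask, -1L, 0L, 0L) |
    shift3(mask, 0L,  1L, 0L) | shift3(mask, 0L, -1L, 0L) |
    shift3(mask, 0L, 0L,  1L) | shift3(mask, 0L, 0L, -1L)
}

erode6 <- function(mask) {
  mask &
    shift3(mask,  1L, 0L, 0L, TRUE) & shift3(mask, -1L, 0L, 0L, TRUE) &
    shift3(mask, 0L,  1L, 0L, TRUE) & shift3(mask, 0L, -1L, 0L, TRUE) &
    shift3(mask, 0L, 0L,  1L, TRUE) & shift3(mask, 0L, 0L, -1L, TRUE)
}

dilate6_n <- function(mask, n) {
  for (i in seq_len(n)) mask <- dilate6(mask)
  mask
}

dilate4_inplane <- function(mask) {
  mask |
    shift3(mask,  1L, 0L, 0L) | shift3(mask, -1L, 0L, 0L) |
    shift3(mask, 0L,  1L, 0L) | shift3(mask, 0L, -1L, 0L)
}

erode4_inplane <- function(mask) {
  mask &
    shift3(mask,  1L, 0L, 0L, TRUE) & shift3(mask, -1L, 0L, 0L, TRUE) &
    shift3(mask, 0L,  1L, 0L, TRUE) & shift3(mask, 0L, -1L, 0L, TRUE)
}

# in-plane closing: appropriate for multislice stacks whose through-plane
# spacing is several times the in-plane voxel size
closing_inplane <- function(mask, n = 1L) {
  out <- mask
  for (i in seq_len(n)) out <- dilate4_inplane(out)
  for (i in seq_len(n)) out <- erode4_inplane(out)
  out
}

closing6 <- function(mask, n = 1L) {
  out <- mask
  for (i in seq_len(n)) out <- dilate6(out)
  for (i in seq_len(n)) out <- erode6(out)
  out
}

# Otsu's threshold on a numeric vector (maximises between-class variance)
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) stop("cannot threshold a constant image")
  h <- tabulate(pmin(n_bins, 1L + floor((x - r[1]) / diff(r) * n_bins)), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# largest 6-connected component of a logical volume
largest_component <- function(mask) {
  lin <- which(mask)
  if (length(lin) == 0L) stop("empty mask")
  dm <- dim(mask)
  id <- array(0L, dim = dm)
  id[lin] <- seq_along(lin)
  edges <- integer(0)
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    nb <- shift3(id, d[1], d[2], d[3], 0L)
    both <- mask & nb > 0L
    edges <- c(edges, rbind(id[both], nb[both]))
  }
  g <- igraph::make_graph(edges, n = length(lin), directed = FALSE)
  comp <- igraph::components(g)
  keep <- lin[comp$membership == which.max(comp$csize)]
  out <- array(FALSE, dim = dm)
  out[keep] <- TRUE
  out
}

# separable Gaussian smoothing, sigma in voxels per axis (0 skips an axis)
smooth_gaussian <- function(vol, sigma = c(0.8, 0.8, 0)) {
  sigma <- rep_len(sigma, 3L)
  dm <- dim(vol)
  out <- vol
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0 || dm[ax] < 3L) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    x <- aperm(out, perm)
    mdim <- dim(x)
    xm <- matrix(x, nrow = mdim[1])
    n <- mdim[1]
    acc <- matrix(0, nrow = n, ncol = ncol(xm))
    for (j in -r:r) {
      src <- pmin(pmax(seq_len(n) + j, 1L), n) # replicate edges
      acc <- acc + k[j + r + 1L] * xm[src, , drop = FALSE]
    }
    x <- array(acc, dim = mdim)
    out <- aperm(x, order(perm))
  }
  out
}

# 2x in-plane block-mean downsampling (z untouched)
downsample2_inplane <- function(vol) {
  dm <- dim(vol)
  nx <- dm[1] %/% 2L; ny <- dm[2] %/% 2L
  v <- vol[seq_len(2L * nx), seq_len(2L * ny), , drop = FALSE]
  (v[seq(1, 2 * nx, 2), seq(1, 2 * ny, 2), , drop = FALSE] +
   v[seq(2, 2 * nx, 2), seq(1, 2 * ny, 2), , drop = FALSE] +
   v[seq(1, 2 * nx, 2), seq(2, 2 * ny, 2), , drop = FALSE] +
   v[seq(2, 2 * nx, 2), seq(2, 2 * ny, 2), , drop = FALSE]) / 4
}

#' Dice overlap coefficient between two binary masks
#' @param a,b logical arrays on one grid.
#' @return `2|A∩B| / (|A|+|B|)`; 1 if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stop_if_grid_mismatch(a, b, what = "masks")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}
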