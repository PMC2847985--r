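#' Quantitative parametric map
#'
#' Container for a voxel-wise parametric image: fitted values, physical units,
#' a validity mask marking voxels where the estimate is trustworthy (fit
#' converged, inputs positive), and optional per-voxel diagnostics such as the
#' residual norm. Values outside the validity mask are `NA` unless the
#' producing operation deliberately retains them (e.g. negative ADC/CBF, which
#' are kept unclamped and flagged so group means stay unbiased).
#'
#' @param values numeric 3-D array.
#' @param units one of `"ms"`, `"mm^2/s"`, `"mL/100g/min"`.
#' @param validity logical 3-D array.
#' @param geometry the `acq_geometry` of the grid.
#' @param diagnostics optional list (e.g. `residual_norm`, `negative`).
#' @export
quantitative_map <- function(values, units = c("ms", "mm^2/s", "mL/100g/min"),
                             validity, geometry, diagnostics = list()) {
  units <- match.arg(units)
  stop_if_grid_mismatch(values, validity)
  if (any(!is.finite(values[validity])))
    stop("values must be finite on the validity mask")
  structure(list(values = values, units = units, validity = validity,
                 geometry = geometry, diagnostics = diagnostics),
            class = "quant_map")
}

#' @export
print.quant_map <- function(x, ...) {
  v <- x$values[x$validity]
  cat(sprintf("<quant_map> [%s] %s grid, %d valid voxels, median %.4g\n",
              x$units, paste(dim(x$values), collapse = "x"),
              sum(x$validity), stats::median(v)))
  invisible(x)
}

# vectorised symmetric 2x2 solve: (A + damp*diag(A)) x = b per row
solve_damped_2 <- function(a11, a12, a22, b1, b2, damp) {
  d11 <- a11 * (1 + damp); d22 <- a22 * (1 + damp)
  det <- d11 * d22 - a12^2
  det[det == 0] <- NA_real_
  list(x1 = (b1 * d22 - b2 * a12) / det,
       x2 = (b2 * d11 - b1 * a12) / det)
}

# vectorised symmetric 3x3 solve with Levenberg damping on the diagonal
solve_damped_3 <- function(a11, a12, a13, a22, a23, a33, b1, b2, b3, damp) {
  a11 <- a11 * (1 + damp); a22 <- a22 * (1 + damp); a33 <- a33 * (1 + damp)
  c11 <- a22 * a33 - a23^2
  c12 <- a13 * a23 - a12 * a33
  c13 <- a12 * a23 - a13 * a22
  det <- a11 * c11 + a12 * c12 + a13 * c13
  det[det == 0] <- NA_real_
  c22 <- a11 * a33 - a13^2
  c23 <- a12 * a13 - a11 * a23
  c33 <- a11 * a22 - a12^2
  list(x1 = (c11 * b1 + c12 * b2 + c13 * b3) / det,
       x2 = (c12 * b1 + c22 * b2 + c23 * b3) / det,
       x3 = (c13 * b1 + c23 * b2 + c33 * b3) / det)
}

# pull a (space x frames) matrix of masked voxels out of a 4-D volume
series_matrix <- function(series, mask) {
  dm <- dim(series)
  stopifnot(length(dm) == 4L)
  m <- matrix(series, nrow = prod(dm[1:3]), ncol = dm[4])
  m[which(mask), , drop = FALSE]
}

#' Voxel-wise T2 relaxometry from a CPMG echo train
#'
#' Fits the monoexponential `S(TE) = S0 exp(-TE / T2)` to the first
#' `n_echoes_used` echoes of each voxel: the log-linear closed form provides
#' the initial estimate, refined by damped (Levenberg) Gauss-Newton least
#' squares on the untransformed signal, vectorised across voxels. T2 is
#' reported in ms. Voxels with any non-positive signal among the echoes used,
#' or whose fit fails to converge, are flagged invalid rather than filled.
#'
#' @param echo_train 4-D array (x, y, z, echo).
#' @param echo_times_ms strictly increasing echo times, ms.
#' @param n_echoes_used number of leading echoes entering the fit (default 20).
#' @param mask logical 3-D array of voxels to fit (default: all).
#' @param rel_tol relative convergence tolerance on the parameters.
#' @param max_iter maximum Gauss-Newton iterations.
#' @return a [quantitative_map()] in ms with residual-norm diagnostics.
#' @export
fit_t2_map <- function(echo_train, echo_times_ms, n_echoes_used = 20L,
                       mask = NULL, rel_tol = 1e-8, max_iter = 100L,
                       geometry = attr(echo_train, "geometry")) {
  dm <- dim(echo_train)
  if (length(dm) != 4L) stop("echo_train must be a 4-D array (space x echoes)")
  if (length(echo_times_ms) < n_echoes_used || n_echoes_used < 3L)
    stop("need length(echo_times_ms) >= n_echoes_used >= 3")
  if (any(diff(echo_times_ms) <= 0)) stop("echo times must be strictly increasing")
  if (dm[4] < n_echoes_used) stop("fewer echoes than n_echoes_used")
  if (is.null(mask)) mask <- array(TRUE, dim = dm[1:3])
  stop_if_grid_mismatch(array(0, dm[1:3]), mask)

  te <- echo_times_ms[seq_len(n_echoes_used)]
  Y <- series_matrix(echo_train, mask)[, seq_len(n_echoes_used), drop = FALSE]
  fit <- exp_decay_fit(Y, te, rel_tol, max_iter)

  vox <- which(mask)
  values <- array(NA_real_, dim = dm[1:3])
  validity <- array(FALSE, dim = dm[1:3])
  resid <- array(NA_real_, dim = dm[1:3])
  t2 <- 1 / fit$rate
  ok <- fit$ok & is.finite(t2) & t2 > 0
  values[vox[ok]] <- t2[ok]
  validity[vox[ok]] <- TRUE
  resid[vox[ok]] <- sqrt(fit$sse[ok])
  quantitative_map(values, "ms", validity, geometry,
                   diagnostics = list(residual_norm = resid))
}

# shared vectorised mono-exponential engine: fits y = s0 * exp(-t * rate)
exp_decay_fit <- function(Y, t, rel_tol = 1e-8, max_iter = 100L) {
  V <- nrow(Y)
  usable <- rowSums(!is.finite(Y) | Y <= 0) == 0L
  s0 <- rep(NA_real_, V); rate <- rep(NA_real_, V)
  sse <- rep(NA_real_, V); conv <- rep(FALSE, V)
  if (any(usable)) {
    Yu <- Y[usable, , drop = FALSE]
    L <- log(Yu)
    n <- length(t)
    tbar <- mean(t); tc <- t - tbar
    stt <- sum(tc^2)
    slope <- as.numeric(L %*% tc) / stt
    inter <- rowMeans(L) - slope * tbar
    r2 <- pmax(-slope, 1e-8)
    a <- exp(inter)
    sse_of <- function(a, r2) {
      M <- exp(-outer(r2, t)) * a
      rowSums((Yu - M)^2)
    }
    cur_sse <- sse_of(a, r2)
    V_u <- sum(usable)
    damp <- rep(1e-3, V_u)
    active <- rep(TRUE, V_u)
    settled <- rep(FALSE, V_u) # met the tolerance or stalled at a minimum
    for (it in seq_len(max_iter)) {
      if (!any(active)) break
      E <- exp(-outer(r2, t))
      M <- E * a
      R <- Yu - M
      # J columns: dM/da = E ; dM/dr2 = -a * t * E
      a11 <- rowSums(E * E)
      Jt <- -sweep(E, 2L, t, "*") * a
      a12 <- rowSums(E * Jt)
      a22 <- rowSums(Jt * Jt)
      b1 <- rowSums(E * R)
      b2 <- rowSums(Jt * R)
      step_ok <- rep(FALSE, V_u)
      for (tries in 1:8) {
        idx <- active & !step_ok
        if (!any(idx)) break
        s <- solve_damped_2(a11[idx], a12[idx], a22[idx], b1[idx], b2[idx],
                            damp[idx])
        a_new <- a[idx] + s$x1
        r_new <- r2[idx] + s$x2
        new_sse <- {
          Mn <- exp(-outer(r_new, t)) * a_new
          rowSums((Yu[idx, , drop = FALSE] - Mn)^2)
        }
        better <- is.finite(new_sse) & new_sse <= cur_sse[idx] + 1e-30
        widx <- which(idx)
        gi <- widx[better]
        if (length(gi)) {
          rel <- pmax(abs(s$x1[better]) / pmax(abs(a[gi]), 1e-12),
                      abs(s$x2[better]) / pmax(abs(r2[gi]), 1e-12))
          a[gi] <- a_new[better]
          r2[gi] <- r_new[better]
          cur_sse[gi] <- new_sse[better]
          damp[gi] <- pmax(damp[gi] / 3, 1e-12)
          step_ok[gi] <- TRUE
          done <- gi[rel < rel_tol]
          active[done] <- FALSE
          settled[done] <- TRUE
        }
        bi <- widx[!better]
        if (length(bi)) damp[bi] <- damp[bi] * 10
      }
      # voxels whose damping exploded: no descent step exists, i.e. the fit
      # is at a (local) minimum — accept it as settled
      stalled <- active & damp > 1e8
      active[stalled] <- FALSE
      settled[stalled] <- TRUE
    }
    oku <- settled & is.finite(a) & is.finite(r2) & a > 0 & r2 > 0
    s0[usable] <- a; rate[usable] <- r2; sse[usable] <- cur_sse
    okv <- rep(FALSE, V); okv[which(usable)[oku]] <- TRUE
    conv <- okv
  }
  list(s0 = s0, rate = rate, sse = sse, ok = conv)
}

#' Voxel-wise T1 mapping from a magnitude inversion-recovery series
#'
#' Fits the three-parameter magnitude model `|S0 (1 - B exp(-TI / T1))|` per
#' voxel. Polarity of the pre-null points is restored by testing the two
#' plausible sign patterns around the magnitude minimum and keeping the fit
#' with the lower residual; the signed model `a - c exp(-TI R1)` is then
#' refined by vectorised damped Gauss-Newton (with `B = c/a`). Constant
#' (non-recovering) series and non-converged voxels are flagged invalid.
#'
#' @param ir_series 4-D array (x, y, z, inversion time).
#' @param inversion_times_ms at least 3 strictly increasing inversion times.
#' @param mask logical 3-D array of voxels to fit.
#' @param rel_tol,max_iter convergence controls as in [fit_t2_map()].
#' @return a [quantitative_map()] in ms.
#' @export
fit_t1_map <- function(ir_series, inversion_times_ms, mask = NULL,
                       rel_tol = 1e-8, max_iter = 100L,
                       geometry = attr(ir_series, "geometry")) {
  dm <- dim(ir_series)
  if (length(dm) != 4L) stop("ir_series must be a 4-D array")
  ti <- as.numeric(inversion_times_ms)
  if (length(ti) < 3L) stop("need at least 3 inversion times")
  if (any(diff(ti) <= 0)) stop("inversion times must be strictly increasing")
  if (dm[4] != length(ti)) stop("series length does not match inversion times")
  if (is.null(mask)) mask <- array(TRUE, dim = dm[1:3])

  Y <- series_matrix(ir_series, mask)
  V <- nrow(Y)
  usable <- rowSums(!is.finite(Y)) == 0L &
    apply(Y, 1L, function(r) stats::sd(r) > 0) &
    Y[, length(ti)] > 0
  a <- rep(NA_real_, V); t1 <- rep(NA_real_, V)
  sse <- rep(NA_real_, V); okv <- rep(FALSE, V)
  if (any(usable)) {
    Yu <- Y[usable, , drop = FALSE]
    kmin <- max.col(-Yu, ties.method = "first")
    best <- NULL
    for (variant in 1:2) {
      flip_upto <- if (variant == 1L) kmin else kmin - 1L
      Sgn <- Yu
      fm <- outer(flip_upto, seq_along(ti), ">=")
      Sgn[fm] <- -Sgn[fm]
      f <- ir_signed_fit(Sgn, ti, rel_tol, max_iter)
      if (is.null(best)) best <- f else {
        swap <- !is.na(f$sse) & (is.na(best$sse) | f$sse < best$sse)
        for (nm in names(best)) best[[nm]][swap] <- f[[nm]][swap]
      }
    }
    a[usable] <- best$a
    t1[usable] <- 1 / best$r1
    sse[usable] <- best$sse
    okv[which(usable)[best$ok & is.finite(best$r1) & best$r1 > 0 & best$a > 0]] <- TRUE
  }
  vox <- which(mask)
  values <- array(NA_real_, dim = dm[1:3])
  validity <- array(FALSE, dim = dm[1:3])
  resid <- array(NA_real_, dim = dm[1:3])
  values[vox[okv]] <- t1[okv]
  validity[vox[okv]] <- TRUE
  resid[vox[okv]] <- sqrt(sse[okv])
  quantitative_map(values, "ms", validity, geometry,
                   diagnostics = list(residual_norm = resid))
}

# vectorised GN for the signed IR model s = a - c * exp(-ti * r1)
ir_signed_fit <- function(S, ti, rel_tol = 1e-8, max_iter = 100L) {
  V <- nrow(S); n <- length(ti)
  a <- S[, n]
  c0 <- a - S[, 1]
  # crude null-crossing estimate for R1: s = 0 at TI0 => T1 = TI0 / log(c/a)
  kmin <- max.col(-abs(S), ties.method = "first")
  ti0 <- ti[kmin]
  ratio <- pmax(c0 / pmax(a, 1e-12), 1.05)
  r1 <- log(ratio) / pmax(ti0, ti[1])
  r1 <- pmin(pmax(r1, 1 / (50 * ti[n])), 50 / ti[1])
  cc <- pmax(c0, 1e-12)
  sse_of <- function(a, cc, r1) rowSums((S - (a - cc * exp(-outer(r1, ti))))^2)
  cur_sse <- sse_of(a, cc, r1)
  damp <- rep(1e-3, V)
  active <- rep(TRUE, V)
  settled <- rep(FALSE, V)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    E <- exp(-outer(r1, ti))
    M <- a - cc * E
    R <- S - M
    J2 <- -E                       # dM/dc
    J3 <- sweep(E, 2L, ti, "*") * cc # dM/dr1
    a11 <- n
    a12 <- rowSums(J2); a13 <- rowSums(J3)
    a22 <- rowSums(J2 * J2); a23 <- rowSums(J2 * J3); a33 <- rowSums(J3 * J3)
    b1 <- rowSums(R); b2 <- rowSums(J2 * R); b3 <- rowSums(J3 * R)
    step_ok <- rep(FALSE, V)
    for (tries in 1:8) {
      idx <- active & !step_ok
      if (!any(idx)) break
      s <- solve_damped_3(rep(a11, sum(idx)), a12[idx], a13[idx], a22[idx],
                          a23[idx], a33[idx], b1[idx], b2[idx], b3[idx],
                          damp[idx])
      an <- a[idx] + s$x1; cn <- cc[idx] + s$x2; rn <- r1[idx] + s$x3
      nsse <- rowSums((S[idx, , drop = FALSE] -
                         (an - cn * exp(-outer(rn, ti))))^2)
      better <- is.finite(nsse) & nsse <= cur_sse[idx] + 1e-30 & rn > 0
      widx <- which(idx)
      gi <- widx[better]
      if (length(gi)) {
        rel <- pmax(abs(s$x1[better]) / pmax(abs(a[gi]), 1e-12),
                    abs(s$x2[better]) / pmax(abs(cc[gi]), 1e-12),
                    abs(s$x3[better]) / pmax(abs(r1[gi]), 1e-12))
        a[gi] <- an[better]; cc[gi] <- cn[better]; r1[gi] <- rn[better]
        cur_sse[gi] <- nsse[better]
        damp[gi] <- pmax(damp[gi] / 3, 1e-12)
        step_ok[gi] <- TRUE
        done <- gi[rel < rel_tol]
        active[done] <- FALSE
        settled[done] <- TRUE
      }
      bi <- widx[!better]
      if (length(bi)) damp[bi] <- damp[bi] * 10
    }
    stalled <- active & damp > 1e8
    active[stalled] <- FALSE
    settled[stalled] <- TRUE
  }
  list(a = a, c = cc, r1 = r1, sse = cur_sse, ok = settled)
}

#' Apparent diffusion coefficient map from a two-point DWI acquisition
#'
#' `ADC(x) = -(1/b) ln(S_b(x) / S_0(x))` in mm^2/s. At the standard
#' b = 800 s/mm^2 the coefficient -1/b equals -0.00125 exactly. Voxels with a
#' non-positive signal in either image are invalid; negative ADC estimates
#' (possible under noise) are retained unclamped and flagged in
#' `diagnostics$negative`.
#'
#' @param dwi_b0,dwi_bpos 3-D volumes at b = 0 and at the positive b-value.
#' @param b_s_per_mm2 positive diffusion weighting (default 800).
#' @param mask optional logical 3-D array.
#' @return a [quantitative_map()] in mm^2/s.
#' @export
compute_adc_map <- function(dwi_b0, dwi_bpos, b_s_per_mm2 = 800, mask = NULL,
                            geometry = attr(dwi_b0, "geometry")) {
  stop_if_grid_mismatch(dwi_b0, dwi_bpos)
  if (b_s_per_mm2 <= 0) stop("b value must be positive")
  dm <- dim(dwi_b0)
  if (is.null(mask)) mask <- array(TRUE, dim = dm)
  stop_if_grid_mismatch(dwi_b0, mask)
  ok <- mask & dwi_b0 > 0 & dwi_bpos > 0
  values <- array(NA_real_, dim = dm)
  values[ok] <- -(1 / b_s_per_mm2) * log(dwi_bpos[ok] / dwi_b0[ok])
  neg <- array(FALSE, dim = dm)
  neg[ok] <- values[ok] < 0
  quantitative_map(values, "mm^2/s", ok, geometry,
                   diagnostics = list(negative = neg))
}

#' Cerebral blood flow map from a CASL control/label pair
#'
#' Single-compartment quantification:
#' `CBF(x) = (lambda / T1(x)) * (S_control - S_label) / (2 alpha S_control)`,
#' with T1 in seconds internally and the result scaled by 6000 to
#' mL/100 g/min. Voxels with non-positive control signal or without a valid T1
#' are invalid; negative CBF values are retained and flagged.
#'
#' @param casl_control,casl_label 3-D volumes.
#' @param t1_map a T1 [quantitative_map()] in ms (or a numeric 3-D array /
#'   scalar of fixed literature T1 values in ms).
#' @param constants a [casl_constants()] list (alpha, lambda).
#' @param mask optional logical 3-D array.
#' @return a [quantitative_map()] in mL/100g/min.
#' @export
compute_cbf_map <- function(casl_control, casl_label, t1_map,
                            constants = casl_constants(), mask = NULL,
                            geometry = attr(casl_control, "geometry")) {
  stop_if_grid_mismatch(casl_control, casl_label)
  if (constants$alpha <= 0 || constants$alpha > 1) stop("alpha must lie in (0, 1]")
  dm <- dim(casl_control)
  if (inherits(t1_map, "quant_map")) {
    if (t1_map$units != "ms") stop("t1_map units must be ms")
    t1 <- t1_map$values
    t1_valid <- t1_map$validity
  } else {
    t1 <- if (length(t1_map) == 1L) array(t1_map, dim = dm) else t1_map
    t1_valid <- is.finite(t1) & t1 > 0
  }
  stop_if_grid_mismatch(casl_control, t1)
  if (is.null(mask)) mask <- array(TRUE, dim = dm)
  ok <- mask & casl_control > 0 & t1_valid & t1 > 0
  values <- array(NA_real_, dim = dm)
  values[ok] <- 6000 * (constants$lambda_ml_per_g / (t1[ok] / 1000)) *
    (casl_control[ok] - casl_label[ok]) / (2 * constants$alpha * casl_control[ok])
  neg <- array(FALSE, dim = dm)
  neg[ok] <- values[ok] < 0
  quantitative_map(values, "mL/100g/min", ok, geometry,
                   diagnostics = list(negative = neg))
}
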