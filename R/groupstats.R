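#' Standard error of the mean
#'
#' Sample standard deviation (n-1 denominator) divided by the square root of
#' the number of observations.
#'
#' @param values numeric vector with at least 2 finite values.
#' @export
sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("sem needs at least 2 values")
  stats::sd(values) / sqrt(length(values))
}

#' Within-group probability-of-infarction map
#'
#' Voxel-wise arithmetic mean of the subjects' binary lesion masks: each voxel
#' holds the fraction of subjects whose infarct includes it, a multiple of
#' 1/n.
#'
#' @param masks list of [binary_lesion_mask()]s (or logical arrays) on one
#'   atlas grid.
#' @param group_label,timepoint annotations.
#' @return object of class `prob_map` with `values` in `[0,1]` and
#'   `n_subjects`.
#' @export
probability_map <- function(masks, group_label = NA_character_,
                            timepoint = NA_character_) {
  if (length(masks) < 1L) stop("need at least one mask")
  arrs <- lapply(masks, as_mask_array)
  do.call(stop_if_grid_mismatch, c(arrs, list(what = "lesion masks")))
  acc <- Reduce(`+`, lapply(arrs, function(a) a * 1))
  structure(list(values = acc / length(arrs), n_subjects = length(arrs),
                 group_label = group_label, timepoint = timepoint),
            class = "prob_map")
}

#' ROI infarct probability summary
#'
#' Per subject, the percentage of ROI voxels covered by the lesion; across
#' subjects, mean and SEM. The group mean equals the ROI average of the
#' probability map times 100 (an algebraic identity), so a ROI that every
#' subject infarcts completely reports exactly 100 with zero SEM.
#'
#' @param masks list of [binary_lesion_mask()]s on the atlas grid.
#' @param roi_mask logical 3-D array, nonempty.
#' @param roi_label annotation.
#' @return object of class `roi_summary` (per-subject values in percent).
#' @export
roi_probability <- function(masks, roi_mask, roi_label = NA_character_) {
  roi <- as_mask_array(roi_mask)
  if (!any(roi)) stop("ROI is empty")
  vals <- vapply(masks, function(m) {
    a <- as_mask_array(m)
    stop_if_grid_mismatch(a, roi)
    100 * sum(a & roi) / sum(roi)
  }, numeric(1))
  roi_summary(vals, roi_label)
}

roi_summary <- function(per_subject_values, roi_label = NA_character_) {
  n <- length(per_subject_values)
  structure(list(roi_label = roi_label,
                 per_subject_values = as.numeric(per_subject_values),
                 mean = mean(per_subject_values),
                 sem = if (n >= 2) sem(per_subject_values) else NA_real_,
                 n = n),
            class = "roi_summary")
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf("<roi_summary> %s: %.3f +/- %.3f (n = %d)\n",
              x$roi_label, x$mean, x$sem, x$n))
  invisible(x)
}

#' Per-subject ROI mean of a quantitative map
#'
#' Mean of the map values over ROI voxels that are also valid; errors if the
#' ROI and the validity mask are disjoint.
#'
#' @param map a [quantitative_map()].
#' @param roi_mask logical 3-D array.
#' @export
roi_mean_map <- function(map, roi_mask) {
  stopifnot(inherits(map, "quant_map"))
  roi <- as_mask_array(roi_mask)
  stop_if_grid_mismatch(map$values, roi)
  sel <- roi & map$validity
  if (!any(sel)) stop("ROI does not overlap the validity mask")
  mean(map$values[sel])
}

#' Summarize per-subject ROI means across a group
#'
#' @param maps list of [quantitative_map()]s, one per subject.
#' @param roi_mask logical 3-D array.
#' @param roi_label annotation.
#' @return a `roi_summary` in the map's units.
#' @export
roi_mean_summary <- function(maps, roi_mask, roi_label = NA_character_) {
  vals <- vapply(maps, roi_mean_map, numeric(1), roi_mask = roi_mask)
  roi_summary(vals, roi_label)
}

# exact null distribution of W+ given |d| ranks: shift convolution over the
# doubled ranks (mid-ranks are half-integers, so 2r is integral)
wilcoxon_null_counts <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L) # counts[w+1] = #assignments with 2W == w
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact matched-pairs Wilcoxon signed-rank test
#'
#' Computes differences `d = x - y`, discards zeros (classical convention),
#' ranks `|d|` with mid-ranks for ties, and sums the ranks of positive
#' differences into the statistic W. For `n_eff <= exact_limit` (12 by
#' default) the two-sided p-value is exact: the null distribution of W over
#' all `2^n` sign assignments, conditional on the observed ranks, is built by
#' convolution and `p = min(1, 2 min(P(W <= w), P(W >= w)))`. Larger samples
#' use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_limit largest `n_eff` for which the exact enumeration-based
#'   distribution is used.
#' @param zero_method `"wilcox"` (discard zero differences) or `"pratt"`
#'   (rank zeros, then drop their contribution).
#' @return object of class `wilcoxon_result`: `statistic_W`, `n_effective`,
#'   `p_two_sided`, `method`, and `all_zero` flag.
#' @export
wilcoxon_signed_rank_exact <- function(x, y, exact_limit = 12L,
                                       zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("need at least one pair")
  d <- as.numeric(x) - as.numeric(y)
  if (all(d == 0)) {
    return(structure(list(statistic_W = 0, n_effective = 0L, p_two_sided = 1,
                          method = "degenerate", all_zero = TRUE),
                     class = "wilcoxon_result"))
  }
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    counts <- wilcoxon_null_counts(r)
    w2 <- as.integer(round(2 * W))
    total <- 2^n
    p_le <- sum(counts[seq_len(w2 + 1L)]) / total
    p_ge <- sum(counts[seq.int(w2 + 1L, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact_enumeration"
  } else {
    mu <- n * (n + 1) / 4
    # variance with tie correction over the retained ranks
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  structure(list(statistic_W = W, n_effective = n, p_two_sided = p,
                 method = method, all_zero = FALSE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> W = %g, n_eff = %d, p = %.6g (%s)\n",
              x$statistic_W, x$n_effective, x$p_two_sided, x$method))
  invisible(x)
}
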