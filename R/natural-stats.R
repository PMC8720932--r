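# Corpus-level statistics: the metric distribution over a set of natural
# scenes is the reference against which stimuli are judged. Only positive
# deviations count — the rectified z-score max(0, (x - mu)/sigma) encodes
# the hypothesis that chromatic contrast below natural levels does not
# cause discomfort, while contrast exceeding nature does.

#' Summarize a corpus of metric values as a reference distribution
#'
#' @param metric_values Numeric vector of per-image average chromaticity
#'   differences (>= 2 values, not all identical).
#' @return Object of class `natural_distribution` with `samples`, `mu`
#'   (mean), `sigma` (sample SD, n-1 denominator) and `density` (Gaussian
#'   kernel estimate, Silverman bandwidth; descriptive only — z-scores use
#'   `mu` and `sigma`).
#' @export
corpus_distribution <- function(metric_values) {
  metric_values <- as.numeric(metric_values)
  if (length(metric_values) < 2) stop("need at least 2 values", call. = FALSE)
  if (!all(is.finite(metric_values))) stop("non-finite metric values", call. = FALSE)
  if (stats::sd(metric_values) == 0) stop("degenerate distribution", call. = FALSE)
  structure(list(
    samples = metric_values,
    mu = mean(metric_values),
    sigma = stats::sd(metric_values),
    density = stats::density(metric_values, bw = "nrd0")),
    class = "natural_distribution")
}

#' @export
print.natural_distribution <- function(x, ...) {
  cat(sprintf("<natural_distribution>  n = %d, mu = %.4g, sigma = %.4g, median = %.4g\n",
              length(x$samples), x$mu, x$sigma, stats::median(x$samples)))
  invisible(x)
}

#' Sample random square patches from an image and compute their metric
#'
#' Draws `n` top-left offsets uniformly (with replacement) over all valid
#' positions, using the given seed; patches may overlap. Each patch's
#' average chromaticity difference is computed without further resizing
#' (patches are used at their native size).
#'
#' @param img sRGB array at least `size` x `size`.
#' @param n Number of patches.
#' @param size Patch side in pixels (default 256).
#' @param seed Integer seed making the draw reproducible.
#' @param source_id Identifier recorded with every patch.
#' @return Data frame with columns source_id, top, left (0-based offsets),
#'   size, metric.
#' @export
sample_patches <- function(img, n, size = 256, seed = 1L, source_id = "image") {
  d <- dim(img)
  if (d[1] < size || d[2] < size)
    stop("image smaller than requested patch size", call. = FALSE)
  offs <- withr::with_seed(seed, list(
    top  = sample.int(d[1] - size + 1L, n, replace = TRUE) - 1L,
    left = sample.int(d[2] - size + 1L, n, replace = TRUE) - 1L))
  metric <- vapply(seq_len(n), function(i) {
    p <- img[offs$top[i] + seq_len(size), offs$left[i] + seq_len(size), ,
             drop = FALSE]
    average_chromaticity_difference(p, resize = FALSE)
  }, numeric(1))
  data.frame(source_id = source_id, top = offs$top, left = offs$left,
             size = size, metric = metric)
}

#' Crop away the left third of an image
#'
#' Preprocessing used for calibrated scene sets whose left third contains a
#' calibration target: a 756 x 1134 frame becomes its right-hand 756 x 756
#' region before the metric is computed.
#'
#' @param img sRGB array whose width is a multiple of 3 (a one- or
#'   two-pixel remainder is tolerated and absorbed into the crop).
#' @return The right-hand two-thirds of the image.
#' @export
crop_left_third <- function(img) {
  W <- dim(img)[2]
  keep <- (floor(W / 3) + 1L):W
  img[, keep, , drop = FALSE]
}

#' Rectified z-scores against a reference distribution
#'
#' z_i = max(0, (x_i - mu) / sigma): standardized deviation from the
#' natural-scene distribution with negative deviations sent to zero.
#'
#' @param values Numeric vector of metric values.
#' @param dist A `natural_distribution`, or anything with `mu` and `sigma`
#'   elements (sigma > 0).
#' @return Vector of non-negative rectified z-scores.
#' @export
rectified_zscores <- function(values, dist) {
  if (dist$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  pmax(0, (values - dist$mu) / dist$sigma)
}

#' Shift analysis: correlation of rectified deviation with discomfort
#'
#' For each shift delta, the reference distribution's mean is displaced to
#' mu + delta (sigma unchanged — the distribution is translated rigidly
#' along the metric axis), rectified z-scores of the stimuli are recomputed,
#' and their Spearman correlation with mean discomfort ratings is measured
#' with a bootstrap percentile CI. When a shift rectifies every score to
#' zero the correlation is undefined and recorded as NA, never as 0.
#'
#' At shifts low enough that no score is rectified, the ranks of the
#' z-scores equal the ranks of the raw metrics, so the curve reproduces the
#' plain Spearman correlation exactly.
#'
#' @param metrics Per-image metric values.
#' @param mean_ratings Per-image mean discomfort ratings (same length >= 3).
#' @param dist Reference `natural_distribution`.
#' @param shifts Vector of delta values; default spans +/- 3 sigma in 25
#'   steps.
#' @param B Bootstrap replicates per shift.
#' @param seed Integer seed; each shift uses a deterministic subseed.
#' @return Data frame of class `shift_curve`: shift, rho, ci_lo, ci_hi.
#' @export
shift_correlation_analysis <- function(metrics, mean_ratings, dist,
                                       shifts = NULL, B = 1000, seed = 1L) {
  stopifnot(length(metrics) == length(mean_ratings), length(metrics) >= 3)
  if (is.null(shifts))
    shifts <- seq(-3 * dist$sigma, 3 * dist$sigma, length.out = 25)
  if (length(shifts) == 0) stop("empty shift grid", call. = FALSE)
  rows <- lapply(seq_along(shifts), function(i) {
    z <- pmax(0, (metrics - (dist$mu + shifts[i])) / dist$sigma)
    if (stats::sd(z) == 0)
      return(data.frame(shift = shifts[i], rho = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    bs <- spearman_bootstrap(z, mean_ratings, B = B, seed = seed + i)
    data.frame(shift = shifts[i], rho = bs$rho, ci_lo = bs$ci_lo,
               ci_hi = bs$ci_hi)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("shift_curve", class(out))
  out
}

#' Rank patches by metric and return the extremes
#'
#' @param patches Data frame from [sample_patches] (possibly row-bound over
#'   sources); must have columns source_id, top, left, metric.
#' @param k Number of extreme patches on each end, k <= nrow(patches).
#' @return List with `top` (k highest-metric patches, descending) and
#'   `bottom` (k lowest, ascending). Ties are broken by (source_id, top,
#'   left) for determinism.
#' @export
rank_extreme_patches <- function(patches, k) {
  stopifnot(k <= nrow(patches))
  ord <- order(-patches$metric, patches$source_id, patches$top, patches$left)
  sorted <- patches[ord, , drop = FALSE]
  list(top = utils::head(sorted, k),
       bottom = utils::tail(sorted, k)[seq(k, 1), , drop = FALSE])
}
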