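# Average local chromaticity difference: for every pixel, the mean Euclidean
# (u', v') distance to its existing 8-connected neighbors; the image metric
# is the unweighted mean of these per-pixel values over all pixels (border
# pixels average over fewer neighbors: 3 in corners, 5 on edges, 8 inside).

#' Euclidean chromaticity distance in the (u', v') plane
#'
#' @param p,q Length-2 numeric vectors (u', v'), or matrices of coordinates
#'   with two columns (compared rowwise).
#' @return Non-negative distance(s); zero iff the chromaticities coincide.
#' @export
pair_distance <- function(p, q) {
  if (is.null(dim(p))) {
    if (!all(is.finite(p)) || !all(is.finite(q)))
      stop("non-finite chromaticity", call. = FALSE)
    return(sqrt(sum((p - q)^2)))
  }
  sqrt(rowSums((p - q)^2))
}

# Mean absolute/Euclidean difference to existing 8-neighbors for a field
# given as a list of aligned H x W channel matrices (one channel -> scalar
# plane, two -> chromaticity plane). Returns the H x W heatmap.
local_field_difference <- function(channels) {
  d <- dim(channels[[1]])
  H <- d[1]; W <- d[2]
  if (H < 2 || W < 2)
    stop("field must be at least 2 x 2 for neighborhood differences",
         call. = FALSE)
  total <- matrix(0, H, W)
  count <- matrix(0, H, W)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- max(1, 1 - di):min(H, H - di)
    ci <- max(1, 1 - dj):min(W, W - dj)
    sq <- 0
    for (ch in channels) {
      dd <- ch[ri, ci, drop = FALSE] - ch[ri + di, ci + dj, drop = FALSE]
      sq <- sq + dd * dd
    }
    total[ri, ci] <- total[ri, ci] + sqrt(sq)
    count[ri, ci] <- count[ri, ci] + 1
  }
  total / count
}

#' Per-pixel local chromaticity difference heatmap
#'
#' For each pixel, the mean (u', v') distance to all of its 8-connected
#' neighbors that exist: corners average 3 distances, non-corner border
#' pixels 5, interior pixels 8.
#'
#' @param field A [chromalum] object (its luminance plane is ignored).
#' @return H x W matrix of non-negative local differences.
#' @export
local_chromaticity_difference <- function(field) {
  stopifnot(inherits(field, "chromalum"))
  local_field_difference(list(field$u_prime, field$v_prime))
}

#' Average chromaticity difference of an image
#'
#' The package's color metric. The image is resized to 256 x 256 with
#' nearest-neighbor sampling (skipped when both dimensions are already at
#' most 256, and suppressible with `resize = FALSE` for pre-cut patches),
#' converted to (u', v') chromaticity, and the local chromaticity-difference
#' heatmap is averaged over all pixels. The result is a dimensionless u'v'
#' distance: 0 iff the chromaticity field is constant.
#'
#' @param img H x W x 3 sRGB array, or a [chromalum] object (used as-is,
#'   never resized).
#' @param resize Resize inputs larger than 256 x 256 down to 256 x 256
#'   before conversion (the default processing chain).
#' @return Non-negative scalar metric value.
#' @export
average_chromaticity_difference <- function(img, resize = TRUE) {
  if (inherits(img, "chromalum"))
    return(mean(local_chromaticity_difference(img)))
  assert_rgb_image(img, min_dim = 2L)
  d <- dim(img)
  if (resize && (d[1] > 256 || d[2] > 256))
    img <- downsample_nearest(img, 256, 256)
  mean(local_chromaticity_difference(rgb_to_chromalum(img)))
}

#' Histogram of a local-difference heatmap
#'
#' @param hm H x W heatmap matrix (from [local_chromaticity_difference]).
#' @param n_bins Number of equal-width bins spanning \[0, max(hm)\].
#' @return List with `edges` (length `n_bins + 1`), `counts` (summing to the
#'   pixel count) and `mean` (the heatmap average, the image metric when the
#'   heatmap came from the full chain).
#' @export
heatmap_histogram <- function(hm, n_bins) {
  stopifnot(is.matrix(hm), n_bins >= 1)
  top <- max(hm)
  if (top <= 0) top <- 1  # all-zero heatmap: all mass in the first bin
  edges <- seq(0, top, length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(hm, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  list(edges = edges, counts = counts, mean = mean(hm))
}
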