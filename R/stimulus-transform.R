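# Chromatic rotations and pseudo-rotations in the (u', v') plane.
#
# A transform maps each pixel's chromaticity c to
#   pivot + s * R(theta) * (c - pivot)
# while leaving the luminance plane untouched. A pure rotation (s = 1)
# preserves all pairwise u'v' distances and hence the chromaticity-
# difference metric; radial scaling (s != 1, a "pseudo-rotation") rescales
# the metric by exactly s at field level, which is what lets one base image
# be pushed to several target metric levels at constant luminance edge
# energy.

#' Chromatic transform specification
#'
#' @param theta Rotation angle in radians, in \[0, 2*pi).
#' @param s Radial scale factor about the pivot, finite and >= 0.
#' @param pivot Length-2 (u', v') center of rotation/scaling; defaults to
#'   the D65 white point.
#' @return Object of class `transform_spec`.
#' @export
transform_spec <- function(theta, s, pivot = d65_chromaticity()) {
  pivot <- as.numeric(pivot)
  if (!is.finite(theta) || theta < 0 || theta >= 2 * pi)
    stop("theta must lie in [0, 2*pi)", call. = FALSE)
  if (!is.finite(s) || s < 0) stop("s must be finite and >= 0", call. = FALSE)
  if (length(pivot) != 2 || any(pivot < 0) || any(pivot > 0.7))
    stop("pivot must be a (u', v') point within [0, 0.7]^2", call. = FALSE)
  structure(list(theta = theta, s = s, pivot = pivot), class = "transform_spec")
}

# Apply a spec to the chromaticity planes of a chromalum object.
transform_chroma_field <- function(cl, spec) {
  stopifnot(inherits(cl, "chromalum"), inherits(spec, "transform_spec"))
  du <- cl$u_prime - spec$pivot[1]
  dv <- cl$v_prime - spec$pivot[2]
  co <- cos(spec$theta); si <- sin(spec$theta)
  chromalum(spec$pivot[1] + spec$s * (co * du - si * dv),
            spec$pivot[2] + spec$s * (si * du + co * dv),
            cl$lum)
}

#' Apply a luminance-preserving chromatic transform to an sRGB image
#'
#' Converts to (u', v', L), rotates/scales the chromaticity of every pixel
#' about the spec's pivot, and converts back to sRGB. Pixels pushed outside
#' the sRGB gamut are projected back toward the pivot at constant
#' luminance, so the luminance plane of the output matches the input
#' exactly up to encoding quantization.
#'
#' @param img H x W x 3 sRGB array.
#' @param spec A [transform_spec].
#' @return Transformed sRGB array with attribute `clipped_fraction`.
#' @export
apply_chromatic_transform <- function(img, spec) {
  cl <- rgb_to_chromalum(img)
  chromalum_to_rgb(transform_chroma_field(cl, spec), pivot = spec$pivot)
}

#' Deterministic bank of chromatic transforms
#'
#' Builds a theta x s grid of [transform_spec]s, truncated to `n`. The scale
#' grid is snapped so that s = 1 is exactly representable, guaranteeing the
#' identity transform (theta = 0, s = 1) is in the bank. Defaults give the
#' 350-transform bank (35 angles x 10 scales) used for triple construction.
#'
#' @param n Number of specs to return; `theta_steps * s_steps` must be >= n.
#' @param theta_steps Number of equally spaced angles in \[0, 2*pi).
#' @param s_range Length-2 range of scale factors.
#' @param s_steps Number of equally spaced scales across `s_range`.
#' @param pivot Shared (u', v') pivot.
#' @return List of `n` unique [transform_spec]s including the identity.
#' @export
generate_transform_bank <- function(n = 350, theta_steps = 35,
                                    s_range = c(0.15, 2.2), s_steps = 10,
                                    pivot = d65_chromaticity()) {
  if (length(s_range) != 2 || s_range[2] <= s_range[1])
    stop("s_range must be an increasing (lo, hi) pair", call. = FALSE)
  if (theta_steps * s_steps < n)
    stop("grid smaller than requested bank size", call. = FALSE)
  thetas <- seq(0, 2 * pi, length.out = theta_steps + 1)[seq_len(theta_steps)]
  svals <- seq(s_range[1], s_range[2], length.out = s_steps)
  if (!any(svals == 1) && s_range[1] <= 1 && s_range[2] >= 1)
    svals[which.min(abs(svals - 1))] <- 1
  grid <- expand.grid(s = svals, theta = thetas)  # theta = 0 block first
  grid <- grid[seq_len(n), , drop = FALSE]
  if (!any(grid$theta == 0 & grid$s == 1))
    grid[n, ] <- list(s = 1, theta = 0)
  lapply(seq_len(n), function(i)
    transform_spec(grid$theta[i], grid$s[i], pivot))
}

#' Maximum luminance deviation between two images
#'
#' Converts both images to (u', v', L) and reports the largest absolute
#' per-pixel luminance difference — the check that a chromatic transform
#' really preserved the luminance content.
#'
#' @param a,b sRGB arrays of identical dimensions.
#' @return Max absolute luminance difference (0 for identical images).
#' @export
verify_luminance_preservation <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("dimension mismatch", call. = FALSE)
  max(abs(rgb_to_chromalum(a)$lum - rgb_to_chromalum(b)$lum))
}

#' Build luminance-matched triples at three metric levels
#'
#' For each base image, applies every transform in the bank, computes the
#' average chromaticity difference of each result, and picks for each of
#' the three target levels the transform whose achieved metric is closest
#' to the target. Images for which any level misses its target by more than
#' `tolerance` are skipped with a logged reason; only complete triples are
#' returned. Default targets are the low / medium / high metric levels
#' (0.0035, 0.0115, 0.0190) used in the matched-triples experiment design.
#'
#' @param images Named list of sRGB arrays (names become `base_id`s).
#' @param level_targets Strictly increasing length-3 metric targets.
#' @param tolerance Maximum allowed |achieved - target|.
#' @param bank List of [transform_spec]s (see [generate_transform_bank]).
#' @param resize Passed to [average_chromaticity_difference].
#' @return List of triples; each has `base_id`, `members` (list of three
#'   sRGB arrays named low/medium/high), `metric_values`, `specs`,
#'   `clipped_fraction` and `max_lum_dev`. Attribute `skipped` records the
#'   images that admitted no complete triple and why.
#' @export
build_triples <- function(images, level_targets = c(0.0035, 0.0115, 0.0190),
                          tolerance = 0.002, bank = generate_transform_bank(),
                          resize = TRUE) {
  if (length(bank) == 0) stop("empty transform bank", call. = FALSE)
  if (length(level_targets) != 3 || any(diff(level_targets) <= 0))
    stop("level_targets must be three strictly increasing values", call. = FALSE)
  if (is.null(names(images)))
    names(images) <- sprintf("img%03d", seq_along(images))
  level_names <- c("low", "medium", "high")
  triples <- list()
  skipped <- character(0)
  for (id in names(images)) {
    img <- images[[id]]
    outs <- lapply(bank, function(sp) apply_chromatic_transform(img, sp))
    mets <- vapply(outs, average_chromaticity_difference, numeric(1),
                   resize = resize)
    pick <- vapply(level_targets, function(t) which.min(abs(mets - t)),
                   integer(1))
    err <- abs(mets[pick] - level_targets)
    if (any(err > tolerance)) {
      skipped[id] <- sprintf(
        "levels (%s) unreachable: best |achieved-target| = %s",
        paste(level_names[err > tolerance], collapse = ","),
        paste(signif(err[err > tolerance], 3), collapse = ","))
      next
    }
    if (any(diff(mets[pick]) <= 0)) {
      skipped[id] <- "achieved metrics not strictly increasing across levels"
      next
    }
    members <- outs[pick]
    names(members) <- level_names
    triples[[id]] <- list(
      base_id = id,
      members = members,
      metric_values = stats::setNames(mets[pick], level_names),
      specs = stats::setNames(bank[pick], level_names),
      clipped_fraction = stats::setNames(
        vapply(members, function(m) attr(m, "clipped_fraction"), numeric(1)),
        level_names),
      max_lum_dev = max(vapply(members, verify_luminance_preservation,
                               numeric(1), b = img)))
  }
  if (length(triples) == 0)
    stop("no image yielded a complete triple", call. = FALSE)
  if (length(skipped))
    message(sprintf("skipped %d image(s): %s", length(skipped),
                    paste(names(skipped), collapse = ", ")))
  attr(triples, "skipped") <- skipped
  triples
}

#' Flatten triples into a manifest table
#'
#' @param triples Output of [build_triples].
#' @return Data frame with one row per triple member: base_id, level,
#'   theta, s, metric, clipped_fraction, max_lum_dev.
#' @export
triple_manifest <- function(triples) {
  rows <- lapply(triples, function(tr) {
    data.frame(
      base_id = tr$base_id,
      level = names(tr$metric_values),
      theta = vapply(tr$specs, `[[`, numeric(1), "theta"),
      s = vapply(tr$specs, `[[`, numeric(1), "s"),
      metric = as.numeric(tr$metric_values),
      clipped_fraction = as.numeric(tr$clipped_fraction),
      max_lum_dev = tr$max_lum_dev,
      row.names = NULL)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
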