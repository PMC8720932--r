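# Color space plumbing: sRGB <-> linear RGB <-> CIE XYZ <-> (u', v', L).
#
# Conventions used throughout the package:
#   * working space is sRGB with D65 white (IEC 61966-2-1 primaries and
#     transfer function); images are H x W x 3 arrays of gamma-encoded
#     values in [0, 1];
#   * the reference white has luminance Y = 1, so the luminance plane of
#     any sRGB-derived image lies in [0, 1];
#   * chromaticity lives in the CIE 1976 UCS (u', v') plane, where
#     Euclidean distance approximates perceived chromatic difference
#     independently of luminance.

# sRGB (D65) linear RGB -> XYZ, IEC 61966-2-1.
.SRGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)

.XYZ_TO_SRGB <- solve(.SRGB_TO_XYZ)

# Denominators X + 15Y + 3Z below this are treated as black (0/0 in u'v').
.BLACK_DENOM_EPS <- 1e-9

#' D65 white-point chromaticity
#'
#' Chromaticity coordinates of the sRGB reference white (D65) in the
#' CIE 1976 UCS plane, obtained by pushing linear RGB (1, 1, 1) through the
#' sRGB matrix and the u'v' projection.
#'
#' @return Named numeric vector with elements `u_prime` and `v_prime`.
#' @export
d65_chromaticity <- function() {
  w <- as.numeric(.SRGB_TO_XYZ %*% c(1, 1, 1))
  den <- w[1] + 15 * w[2] + 3 * w[3]
  c(u_prime = 4 * w[1] / den, v_prime = 9 * w[2] / den)
}

assert_rgb_image <- function(img, min_dim = 1L) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an H x W x 3 array of sRGB values", call. = FALSE)
  if (!all(is.finite(img)))
    stop("image contains non-finite values", call. = FALSE)
  if (min(img) < 0 || max(img) > 1)
    stop("sRGB values must lie in [0, 1]", call. = FALSE)
  if (dim(img)[1] < min_dim || dim(img)[2] < min_dim)
    stop(sprintf("image must be at least %d x %d", min_dim, min_dim),
         call. = FALSE)
  invisible(img)
}

#' sRGB electro-optical transfer (decode to linear RGB)
#'
#' Applies the piecewise IEC 61966-2-1 transfer componentwise: values at or
#' below 0.04045 are divided by 12.92, larger values follow
#' ((v + 0.055)/1.055)^2.4.
#'
#' @param x Numeric array/vector of gamma-encoded values in \[0, 1\].
#' @return Object of the same shape with linear-light values in \[0, 1\].
#' @export
decode_srgb <- function(x) {
  if (!all(is.finite(x)) || min(x) < 0 || max(x) > 1)
    stop("sRGB values must be finite and in [0, 1]", call. = FALSE)
  out <- ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
  if (is.array(x)) dim(out) <- dim(x)
  out
}

#' Inverse sRGB transfer (encode linear RGB)
#'
#' @param x Numeric array/vector of linear-light values in \[0, 1\].
#' @return Gamma-encoded values in \[0, 1\].
#' @export
encode_srgb <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  out <- ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
  out <- pmin(pmax(out, 0), 1)
  if (is.array(x)) dim(out) <- dim(x)
  out
}

linear_rgb_to_xyz <- function(r, g, b) {
  M <- .SRGB_TO_XYZ
  list(X = M[1, 1] * r + M[1, 2] * g + M[1, 3] * b,
       Y = M[2, 1] * r + M[2, 2] * g + M[2, 3] * b,
       Z = M[3, 1] * r + M[3, 2] * g + M[3, 3] * b)
}

xyz_to_linear_rgb <- function(X, Y, Z) {
  M <- .XYZ_TO_SRGB
  list(r = M[1, 1] * X + M[1, 2] * Y + M[1, 3] * Z,
       g = M[2, 1] * X + M[2, 2] * Y + M[2, 3] * Z,
       b = M[3, 1] * X + M[3, 2] * Y + M[3, 3] * Z)
}

#' Construct a chromaticity-luminance image
#'
#' Bundles per-pixel (u', v') chromaticity planes and a luminance plane into
#' the container used by all chromatic computation in the package.
#'
#' @param u_prime,v_prime,lum H x W numeric matrices; `lum` on the Y scale
#'   with reference white at 1.
#' @return Object of class `chromalum`.
#' @export
chromalum <- function(u_prime, v_prime, lum) {
  stopifnot(is.matrix(u_prime), is.matrix(v_prime), is.matrix(lum),
            all(dim(u_prime) == dim(v_prime)), all(dim(u_prime) == dim(lum)))
  if (!all(is.finite(u_prime)) || !all(is.finite(v_prime)))
    stop("non-finite chromaticities", call. = FALSE)
  if (any(lum < 0)) stop("negative luminance", call. = FALSE)
  structure(list(u_prime = u_prime, v_prime = v_prime, lum = lum),
            class = "chromalum")
}

#' @export
dim.chromalum <- function(x) dim(x$u_prime)

#' @export
print.chromalum <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<chromalum %d x %d>  u' in [%.4f, %.4f], v' in [%.4f, %.4f], lum in [%.4f, %.4f]\n",
              d[1], d[2], min(x$u_prime), max(x$u_prime),
              min(x$v_prime), max(x$v_prime), min(x$lum), max(x$lum)))
  invisible(x)
}

#' Convert an sRGB image to chromaticity-luminance representation
#'
#' Linearizes the image, applies the sRGB(D65) RGB to XYZ matrix, then
#' projects to the CIE 1976 UCS plane: u' = 4X/(X + 15Y + 3Z),
#' v' = 9Y/(X + 15Y + 3Z). Luminance is Y with reference white at 1.
#' Pixels at (or numerically indistinguishable from) black, where u'v' is
#' 0/0, are assigned the D65 white-point chromaticity so they cannot create
#' spurious chromatic differences against their neighbors.
#'
#' @param img H x W x 3 array of gamma-encoded sRGB values in \[0, 1\].
#' @return A [chromalum] object.
#' @export
rgb_to_chromalum <- function(img) {
  assert_rgb_image(img)
  lin <- decode_srgb(img)
  xyz <- linear_rgb_to_xyz(lin[, , 1], lin[, , 2], lin[, , 3])
  den <- xyz$X + 15 * xyz$Y + 3 * xyz$Z
  dark <- den < .BLACK_DENOM_EPS
  den[dark] <- 1  # placeholder, overwritten below
  up <- 4 * xyz$X / den
  vp <- 9 * xyz$Y / den
  w <- d65_chromaticity()
  up[dark] <- w[["u_prime"]]
  vp[dark] <- w[["v_prime"]]
  lum <- xyz$Y
  lum[lum < 0] <- 0
  chromalum(as.matrix(up), as.matrix(vp), as.matrix(lum))
}

#' Convert chromaticity-luminance back to sRGB, preserving luminance
#'
#' Inverts (u', v', L) to XYZ and linear RGB, then gamma-encodes. Pixels
#' whose requested chromaticity falls outside the sRGB gamut at their
#' luminance are projected back toward `pivot` (default D65 white) along the
#' chromatic vector, at fixed luminance, by binary search on the shrink
#' factor until all three linear channels are representable. Luminance is
#' therefore preserved exactly in continuous arithmetic; only chroma is
#' compressed.
#'
#' @param cl A [chromalum] object.
#' @param pivot Chromaticity the out-of-gamut projection shrinks toward;
#'   numeric length-2 (u', v').
#' @return H x W x 3 sRGB array with attribute `clipped_fraction`, the share
#'   of pixels that needed gamut projection.
#' @export
chromalum_to_rgb <- function(cl, pivot = d65_chromaticity()) {
  stopifnot(inherits(cl, "chromalum"))
  pivot <- as.numeric(pivot)
  up <- cl$u_prime; vp <- cl$v_prime; L <- cl$lum
  if (any(L < 0)) stop("negative luminance", call. = FALSE)
  if (any(L > 1 + 1e-9))
    stop("luminance above the reference white is not representable in sRGB",
         call. = FALSE)
  L <- pmin(L, 1)

  lin_from_chroma <- function(u, v) {
    v <- pmax(v, 1e-12)
    X <- L * (9 * u) / (4 * v)
    Z <- L * (12 - 3 * u - 20 * v) / (4 * v)
    xyz_to_linear_rgb(X, L, Z)
  }
  in_gamut <- function(rgb, eps = 1e-9) {
    rgb$r >= -eps & rgb$r <= 1 + eps &
    rgb$g >= -eps & rgb$g <= 1 + eps &
    rgb$b >= -eps & rgb$b <= 1 + eps
  }

  rgb <- lin_from_chroma(up, vp)
  ok <- in_gamut(rgb)
  clipped <- !ok & L > 0
  if (any(clipped)) {
    du <- up - pivot[1]; dv <- vp - pivot[2]
    # shrink factor t in [0, 1]: t = 0 is the pivot (always in gamut for
    # L <= 1 when pivot is the white point), t = 1 the requested chroma
    lo <- ifelse(clipped, 0, 1)
    hi <- ifelse(clipped, 1, 1)
    for (i in seq_len(40)) {
      mid <- (lo + hi) / 2
      cand <- lin_from_chroma(pivot[1] + mid * du, pivot[2] + mid * dv)
      good <- in_gamut(cand)
      lo <- ifelse(clipped & good, mid, lo)
      hi <- ifelse(clipped & !good, mid, hi)
    }
    rgb <- lin_from_chroma(pivot[1] + lo * du, pivot[2] + lo * dv)
  }
  # zero-luminance pixels are black regardless of chroma
  z <- L <= 0
  rgb$r[z] <- 0; rgb$g[z] <- 0; rgb$b[z] <- 0
  out <- array(0, dim = c(nrow(up), ncol(up), 3))
  out[, , 1] <- encode_srgb(rgb$r)
  out[, , 2] <- encode_srgb(rgb$g)
  out[, , 3] <- encode_srgb(rgb$b)
  attr(out, "clipped_fraction") <- mean(clipped)
  out
}

#' Nearest-neighbor resize
#'
#' Resamples an image to `out_h` x `out_w` by copying, for each output
#' pixel, the input pixel at index `floor((dst + 0.5) * in/out)` (0-based,
#' half-pixel-center convention, clamped to the valid range). No new pixel
#' values are invented, and the aspect ratio is not preserved when the
#' target shape differs from the source shape.
#'
#' @param img H x W x 3 array (or H x W matrix).
#' @param out_h,out_w Positive integer target dimensions.
#' @return Resized array of the same kind as the input.
#' @export
downsample_nearest <- function(img, out_h, out_w) {
  if (out_h < 1 || out_w < 1) stop("target size must be positive", call. = FALSE)
  d <- dim(img)
  in_h <- d[1]; in_w <- d[2]
  ri <- pmin(pmax(floor((seq_len(out_h) - 0.5) * in_h / out_h) + 1, 1), in_h)
  ci <- pmin(pmax(floor((seq_len(out_w) - 0.5) * in_w / out_w) + 1, 1), in_w)
  if (length(d) == 3L) img[ri, ci, , drop = FALSE] else img[ri, ci, drop = FALSE]
}

#' Read a raster image as an sRGB array
#'
#' Supports 8- and 16-bit PNG and TIFF; values are returned normalized to
#' \[0, 1\]. Grayscale images are expanded to three identical channels; an
#' alpha channel, if present, is dropped with a warning.
#'
#' @param path File path; format inferred from the extension.
#' @return H x W x 3 numeric array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = stop("JPEG input is not supported in this build; convert to PNG or TIFF",
                call. = FALSE),
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE))
  if (is.matrix(raw)) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] == 2L)  # gray + alpha
    raw <- array(rep(raw[, , 1], 3), dim = c(dim(raw)[1:2], 3))
  if (dim(raw)[3] >= 4L) {
    warning("alpha channel dropped")
    raw <- raw[, , 1:3, drop = FALSE]
  }
  pmin(pmax(raw, 0), 1)
}

#' Write an sRGB array to PNG or TIFF
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param path Output path; format inferred from the extension.
#' @export
write_image <- function(img, path) {
  assert_rgb_image(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path),
    stop(sprintf("unsupported output format '%s'", ext), call. = FALSE))
  invisible(path)
}
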