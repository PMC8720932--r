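# Synthetic inputs with known ground truth: two-color test patterns whose
# metric has a closed form, fruit-against-foliage scenes whose chromatic
# edges are localized on known outlines, corpora whose metric distribution
# matches a target mean/SD, and simulated observers drawn from the same
# mixed-effects structure the inferential layer fits.

# --- deterministic patterns -------------------------------------------------

#' Two-color test pattern
#'
#' Checkerboards, stripes and half-field images built from two sRGB
#' colors. With 1-pixel cells, interior pixels of a checkerboard differ
#' from 4 of their 8 neighbors (metric -> d/2 for large images, d the u'v'
#' distance between the two colors) and interior pixels of vertical
#' stripes from 6 of 8 (local value 6d/8) — the closed forms used as
#' metric oracles.
#'
#' @param color_a,color_b sRGB triples in \[0, 1\].
#' @param layout One of "checkerboard", "stripes" (vertical), "halves"
#'   (left/right).
#' @param size Image side in pixels (>= 2).
#' @param cell Cell/stripe width in pixels.
#' @return `size` x `size` x 3 sRGB array.
#' @export
make_two_color_image <- function(color_a, color_b,
                                 layout = c("checkerboard", "stripes", "halves"),
                                 size = 256, cell = 1) {
  layout <- match.arg(layout)
  stopifnot(size >= 2, cell >= 1)
  i <- (seq_len(size) - 1) %/% cell
  mask <- switch(layout,
    checkerboard = outer(i, i, function(a, b) (a + b) %% 2 == 1),
    stripes = matrix(rep(i %% 2 == 1, each = size), size, size),
    halves = matrix(rep(seq_len(size) > size / 2, each = size), size, size))
  img <- array(0, dim = c(size, size, 3))
  for (k in 1:3) img[, , k] <- ifelse(mask, color_b[k], color_a[k])
  img
}

# 1/f luminance texture in [lo, hi], seeded. Built in the Fourier domain:
# white-noise phases with an exactly 1/f^alpha amplitude envelope.
one_over_f_texture <- function(size, alpha = 1, lo = 0.25, hi = 0.75,
                               seed = 1L) {
  z <- withr::with_seed(seed, matrix(stats::rnorm(size^2), size, size))
  Fz <- stats::fft(z)
  f <- pmin(0:(size - 1), size - (0:(size - 1)))
  r <- sqrt(outer(f^2, f^2, "+"))
  env <- ifelse(r > 0, r^(-alpha), 0)
  tex <- Re(stats::fft(Fz / pmax(Mod(Fz), 1e-12) * env, inverse = TRUE)) / size^2
  rng <- range(tex)
  lo + (tex - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Synthetic fruit-against-foliage scene
#'
#' A background at one chromaticity carrying a 1/f luminance texture, with
#' `n_dots` disks of a contrasting chromaticity ("fruit") at seeded random
#' positions. Chromatic difference is zero everywhere except across dot
#' outlines, so the local-difference heatmap peaks exactly on the outlines
#' — the configuration that produces the highest metric values found in
#' natural scenes.
#'
#' @param bg_chroma,dot_chroma (u', v') chromaticities; defaults are a
#'   foliage green and a ripe-fruit red derived from in-gamut sRGB colors.
#' @param n_dots Number of disks (0 gives a chromatically uniform image).
#' @param radius Disk radius in pixels.
#' @param size Image side in pixels.
#' @param alpha Spectral slope of the luminance texture.
#' @param seed Integer seed for texture and dot placement.
#' @return sRGB array with attribute `dot_centers` (n_dots x 2 matrix).
#' @export
make_fruit_scene <- function(bg_chroma = NULL, dot_chroma = NULL,
                             n_dots = 12, radius = 10, size = 256,
                             alpha = 1, seed = 1L) {
  if (is.null(bg_chroma)) bg_chroma <- srgb_chromaticity(c(0.25, 0.45, 0.15))
  if (is.null(dot_chroma)) dot_chroma <- srgb_chromaticity(c(0.75, 0.15, 0.12))
  if (n_dots > 0 && (radius >= size / 2))
    stop("dots do not fit in the image", call. = FALSE)
  lum <- one_over_f_texture(size, alpha = alpha, lo = 0.15, hi = 0.45,
                            seed = seed)
  up <- matrix(bg_chroma[1], size, size)
  vp <- matrix(bg_chroma[2], size, size)
  centers <- matrix(numeric(0), 0, 2)
  if (n_dots > 0) {
    centers <- withr::with_seed(seed + 1L, cbind(
      sample((radius + 1):(size - radius), n_dots, replace = TRUE),
      sample((radius + 1):(size - radius), n_dots, replace = TRUE)))
    ix <- matrix(seq_len(size), size, size)
    iy <- matrix(seq_len(size), size, size, byrow = TRUE)
    for (k in seq_len(n_dots)) {
      m <- (ix - centers[k, 1])^2 + (iy - centers[k, 2])^2 <= radius^2
      up[m] <- dot_chroma[1]
      vp[m] <- dot_chroma[2]
    }
  }
  out <- chromalum_to_rgb(chromalum(up, vp, lum))
  attr(out, "dot_centers") <- centers
  out
}

#' Chromaticity of a single sRGB color
#'
#' @param rgb sRGB triple in \[0, 1\].
#' @return (u', v') coordinates.
#' @export
srgb_chromaticity <- function(rgb) {
  img <- array(rep(rgb, each = 4), dim = c(2, 2, 3))
  cl <- rgb_to_chromalum(img)
  c(u_prime = cl$u_prime[1, 1], v_prime = cl$v_prime[1, 1])
}

# --- synthetic natural corpus ----------------------------------------------

# One corpus image: smooth chromatic noise around the white point with the
# chromatic spread rescaled so the image's average chromaticity difference
# equals `target` exactly at field level (the metric scales linearly with
# chromatic spread about any pivot), then rendered to sRGB.
corpus_image <- function(size, target, seed) {
  w <- d65_chromaticity()
  base <- withr::with_seed(seed, {
    k <- max(4L, size %/% 8L)
    list(u = matrix(stats::rnorm(k^2), k, k),
         v = matrix(stats::rnorm(k^2), k, k),
         lum_seed = sample.int(1e6, 1))
  })
  # upsample coarse noise to full size: smooth, natural-ish chromatic field
  u0 <- downsample_nearest(base$u, size, size)
  v0 <- downsample_nearest(base$v, size, size)
  cl0 <- chromalum(w[1] + 0.002 * u0, w[2] + 0.002 * v0,
                   matrix(0.5, size, size))
  m0 <- mean(local_chromaticity_difference(cl0))
  sc <- target / m0
  lum <- one_over_f_texture(size, lo = 0.3, hi = 0.7, seed = base$lum_seed)
  cl <- chromalum(w[1] + sc * 0.002 * u0, w[2] + sc * 0.002 * v0, lum)
  chromalum_to_rgb(cl)
}

#' Generate a synthetic natural-scene corpus
#'
#' Produces `n_images` chromatic-noise images whose realized metric
#' distribution matches a target mean and SD (defaults 0.0056 and 0.0023,
#' the scale of calibrated natural-scene collections). Per-image metric
#' targets are drawn from a truncated normal and each image's chromatic
#' spread is rescaled so its field-level metric hits its target exactly;
#' the small residual discrepancy after sRGB rendering comes only from
#' gamut clipping and is negligible at these spreads.
#'
#' @param n_images Number of images (>= 2).
#' @param target_mu,target_sigma Target mean and SD of the metric
#'   distribution.
#' @param size Image side in pixels.
#' @param seed Integer seed.
#' @return Named list of sRGB arrays with attribute `targets` (the drawn
#'   per-image metric targets).
#' @export
make_synthetic_corpus <- function(n_images, target_mu = 0.0056,
                                  target_sigma = 0.0023, size = 64,
                                  seed = 1L) {
  stopifnot(n_images >= 2, target_mu > 0)
  targets <- withr::with_seed(seed, {
    t <- stats::rnorm(n_images, target_mu, target_sigma)
    while (any(t < target_mu / 10))
      t[t < target_mu / 10] <- stats::rnorm(sum(t < target_mu / 10),
                                            target_mu, target_sigma)
    t
  })
  imgs <- lapply(seq_len(n_images), function(i)
    corpus_image(size, targets[i], seed = seed + i))
  names(imgs) <- sprintf("scene%04d", seq_len(n_images))
  attr(imgs, "targets") <- targets
  imgs
}

# --- simulated observers ----------------------------------------------------

#' Generative observer model for discomfort ratings
#'
#' Parameters of the latent linear model behind simulated ratings: each
#' observer's intercept and slope are drawn from a bivariate normal around
#' (`intercept`, `beta`), a Gaussian residual is added, and the latent
#' value is rounded and clamped to the 1-5 rating scale.
#'
#' @param beta Population slope, in rating units per standardized metric
#'   unit.
#' @param intercept Grand mean rating.
#' @param sd_intercept,sd_slope Between-observer SDs (>= 0).
#' @param rho_is Intercept-slope correlation in \[-1, 1\].
#' @param sd_noise Residual SD.
#' @return Object of class `observer_model`.
#' @export
observer_model <- function(beta = 0.3, intercept = 2.5, sd_intercept = 0.5,
                           sd_slope = 0.15, rho_is = 0, sd_noise = 0.8) {
  stopifnot(sd_intercept >= 0, sd_slope >= 0, sd_noise >= 0,
            rho_is >= -1, rho_is <= 1)
  structure(list(beta = beta, intercept = intercept,
                 sd_intercept = sd_intercept, sd_slope = sd_slope,
                 rho_is = rho_is, sd_noise = sd_noise),
            class = "observer_model")
}

#' Simulate a discomfort ratings table
#'
#' For each observer o, draws (intercept_o, slope_o) from the bivariate
#' normal implied by the model, computes the latent rating
#' intercept_o + slope_o * z(metric) + noise for every image (z is the
#' standardized metric), and discretizes by rounding and clamping to
#' 1..5.
#'
#' @param metrics Per-image metric values (length = number of images).
#' @param model An [observer_model].
#' @param n_observers Number of simulated observers.
#' @param seed Integer seed.
#' @return Data frame with columns observer_id, image_id, rating, metric —
#'   the schema [fit_discomfort_lmm] consumes.
#' @export
simulate_ratings <- function(metrics, model = observer_model(),
                             n_observers = 50, seed = 1L) {
  stopifnot(inherits(model, "observer_model"), length(metrics) >= 2)
  n_img <- length(metrics)
  z <- if (stats::sd(metrics) > 0)
    (metrics - mean(metrics)) / stats::sd(metrics) else rep(0, n_img)
  image_id <- if (!is.null(names(metrics))) names(metrics)
              else sprintf("img%03d", seq_len(n_img))
  withr::with_seed(seed, {
    a1 <- stats::rnorm(n_observers)
    a2 <- stats::rnorm(n_observers)
    int_o <- model$intercept + model$sd_intercept * a1
    slope_o <- model$beta + model$sd_slope *
      (model$rho_is * a1 + sqrt(1 - model$rho_is^2) * a2)
    latent <- rep(int_o, each = n_img) + rep(slope_o, each = n_img) * z +
      stats::rnorm(n_observers * n_img, 0, model$sd_noise)
    data.frame(
      observer_id = rep(sprintf("obs%03d", seq_len(n_observers)), each = n_img),
      image_id = rep(image_id, times = n_observers),
      rating = as.integer(pmin(5, pmax(1, round(latent)))),
      metric = rep(as.numeric(metrics), times = n_observers))
  })
}
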