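# Luminance-domain metrics. Natural scenes have Fourier amplitude spectra
# that fall off roughly as 1/f^alpha (alpha ~ 0.5-1.5); the departure
# statistic here measures how far a luminance plane strays from that
# regularity, as the RMS residual of a log-log linear fit of radially
# averaged amplitude against spatial frequency. This is a documented
# approximation of the construct "deviation from 1/f^alpha", not a
# reproduction of any particular published contrast-weighted variant.

#' Radially averaged Fourier amplitude spectrum
#'
#' Takes the 2-D DFT of the mean-subtracted luminance plane and averages
#' amplitudes within integer radial-frequency bins (cycles/image), DC
#' excluded, up to the Nyquist bin of the smaller dimension.
#'
#' @param lum H x W luminance matrix, H, W >= 8.
#' @return List of class `radial_spectrum` with strictly increasing `freqs`
#'   and the mean `amps` per bin.
#' @export
radial_amplitude_spectrum <- function(lum) {
  stopifnot(is.matrix(lum))
  H <- nrow(lum); W <- ncol(lum)
  if (H < 8 || W < 8) stop("luminance plane must be at least 8 x 8", call. = FALSE)
  z <- lum - mean(lum)
  if (all(z == 0)) stop("zero spectral energy", call. = FALSE)
  A <- Mod(stats::fft(z))
  fi <- pmin(0:(H - 1), H - (0:(H - 1)))
  fj <- pmin(0:(W - 1), W - (0:(W - 1)))
  r <- sqrt(outer(fi^2, fj^2, "+"))
  nyq <- floor(min(H, W) / 2)
  bin <- round(r)
  keep <- bin >= 1 & bin <= nyq
  amps <- as.numeric(tapply(A[keep], bin[keep], mean))
  freqs <- sort(unique(bin[keep]))
  structure(list(freqs = freqs, amps = amps), class = "radial_spectrum")
}

#' Departure from a 1/f^alpha amplitude spectrum
#'
#' Fits log(amplitude) = c - alpha * log(frequency) by least squares over
#' radial frequencies from `f_min` (default 2 cycles/image, skipping the DC
#' and first bins where windowing artifacts concentrate) to Nyquist, and
#' summarizes deviation as the root-mean-square residual in log-amplitude
#' units. Invariant to rescaling luminance by a positive constant (the
#' intercept absorbs the shift).
#'
#' @param lum H x W luminance matrix.
#' @param f_min Lowest radial frequency (cycles/image) entering the fit.
#' @return List with `departure` (RMS log residual, >= 0), `alpha` (fitted
#'   spectral slope) and `intercept`.
#' @export
departure_from_one_over_f <- function(lum, f_min = 2) {
  sp <- radial_amplitude_spectrum(lum)
  keep <- sp$freqs >= f_min & sp$amps > 0
  if (sum(keep) < 3) stop("fewer than 3 radial bins available for the fit",
                          call. = FALSE)
  lf <- log(sp$freqs[keep]); la <- log(sp$amps[keep])
  fit <- stats::lm.fit(cbind(1, -lf), la)
  list(departure = sqrt(mean(fit$residuals^2)),
       alpha = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]))
}

#' Luminance edge energy
#'
#' The same local-difference statistic as the color metric, applied to the
#' scalar luminance plane: the mean over pixels of the mean absolute
#' luminance difference to existing 8-connected neighbors (corners 3,
#' borders 5, interior 8). Zero iff luminance is constant. Chromatic
#' transforms from [apply_chromatic_transform] leave it unchanged because
#' the luminance plane is untouched.
#'
#' @param lum H x W luminance matrix, or a [chromalum] object (its `lum`
#'   plane is used).
#' @return Non-negative scalar.
#' @export
luminance_edge_energy <- function(lum) {
  if (inherits(lum, "chromalum")) lum <- lum$lum
  stopifnot(is.matrix(lum))
  mean(local_field_difference(list(lum)))
}
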