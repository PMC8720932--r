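# Shared fixtures and independent oracles.

# Brute-force local chromaticity difference: explicit double loop over all
# pixels and their 8-neighborhoods. Deliberately naive — the independent
# oracle for the vectorized implementation.
brute_local_difference <- function(u, v) {
  H <- nrow(u); W <- ncol(u)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0; n <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      acc <- acc + sqrt((u[i, j] - u[ii, jj])^2 + (v[i, j] - v[ii, jj])^2)
      n <- n + 1
    }
    out[i, j] <- acc / n
  }
  out
}

# Random in-gamut chromaticity field around the white point.
random_chroma_field <- function(H, W, spread = 0.02, seed = 1L) {
  withr::with_seed(seed, {
    w <- d65_chromaticity()
    chromalum(matrix(w[1] + spread * stats::rnorm(H * W), H, W),
              matrix(w[2] + spread * stats::rnorm(H * W), H, W),
              matrix(stats::runif(H * W, 0.2, 0.8), H, W))
  })
}

# sRGB rendering of a moderate chromatic spread around the white point:
# scale factors up to ~2 stay inside the gamut, so pseudo-rotations can
# reach low/medium/high metric targets without clipping.
moderate_gamut_image <- function(size = 32, spread = 0.008, seed = 1L) {
  chromalum_to_rgb(random_chroma_field(size, size, spread = spread,
                                       seed = seed))
}

# Small colorful sRGB fixture with wide in-gamut chromatic spread.
fixture_image <- function(size = 32, seed = 1L) {
  withr::with_seed(seed, {
    k <- size %/% 4
    base <- array(stats::runif(k * k * 3, 0.1, 0.9), dim = c(k, k, 3))
    downsample_nearest(base, size, size)
  })
}
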