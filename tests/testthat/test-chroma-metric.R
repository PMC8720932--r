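test_that("pair_distance is a metric on hand-checked cases", {
  expect_equal(pair_distance(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(pair_distance(c(0.20, 0.45), c(0.25, 0.50)),
               sqrt(0.05^2 + 0.05^2))
  withr::with_seed(21, {
    for (i in 1:50) {
      p <- runif(2); q <- runif(2); r <- runif(2)
      expect_equal(pair_distance(p, q), pair_distance(q, p))
      expect_lte(pair_distance(p, r),
                 pair_distance(p, q) + pair_distance(q, r) + 1e-12)
    }
  })
})

test_that("heatmap matches the brute-force 8-neighborhood oracle", {
  withr::with_seed(31, {
    for (i in 1:20) {
      H <- sample(2:16, 1); W <- sample(2:16, 1)
      cl <- random_chroma_field(H, W, seed = 100 + i)
      expect_equal(local_chromaticity_difference(cl),
                   brute_local_difference(cl$u_prime, cl$v_prime),
                   tolerance = 1e-12)
    }
  })
})

test_that("border neighbor counts are 3 / 5 / 8", {
  # 2x2 field, left column chromaticity a, right column b at distance d:
  # each pixel has 3 neighbors, one same-chromaticity and two different,
  # so every local value is 2d/3
  a <- c(0.20, 0.45); b <- c(0.25, 0.48)
  d <- pair_distance(a, b)
  cl <- chromalum(matrix(c(a[1], a[1], b[1], b[1]), 2, 2),
                  matrix(c(a[2], a[2], b[2], b[2]), 2, 2),
                  matrix(0.5, 2, 2))
  hm <- local_chromaticity_difference(cl)
  expect_equal(as.numeric(hm), rep(2 * d / 3, 4), tolerance = 1e-12)

  # corner of a field where the corner pixel differs from everything else:
  # its local value is the mean of exactly 3 distances
  cl2 <- random_chroma_field(5, 5, seed = 7)
  hm2 <- local_chromaticity_difference(cl2)
  ref <- brute_local_difference(cl2$u_prime, cl2$v_prime)
  expect_equal(hm2[1, 1], ref[1, 1], tolerance = 1e-12)

  expect_error(local_chromaticity_difference(
    chromalum(matrix(0.2, 1, 5), matrix(0.4, 1, 5), matrix(0.5, 1, 5))),
    "2 x 2")
})

test_that("metric is zero iff chromaticity is constant", {
  u <- array(rep(c(0.8, 0.3, 0.1), each = 32 * 32), dim = c(32, 32, 3))
  expect_equal(average_chromaticity_difference(u), 0)

  # luminance texture on a constant chromaticity: per-pixel positive
  # scaling of one linear-RGB color
  withr::with_seed(41, {
    base_lin <- c(0.6, 0.35, 0.15)
    s <- matrix(runif(24 * 24, 0.1, 1), 24, 24)
    img <- array(0, dim = c(24, 24, 3))
    for (k in 1:3) img[, , k] <- encode_srgb(base_lin[k] * s)
  })
  expect_lt(average_chromaticity_difference(img), 1e-6)

  # and any chromatic variation makes it positive
  expect_gt(average_chromaticity_difference(fixture_image(16)), 0)
})

test_that("metric is invariant to permuting luminance at fixed chromaticity", {
  cl <- random_chroma_field(12, 12, seed = 55)
  m1 <- average_chromaticity_difference(cl)
  cl2 <- chromalum(cl$u_prime, cl$v_prime,
                   matrix(withr::with_seed(56, sample(cl$lum)), 12, 12))
  expect_identical(m1, average_chromaticity_difference(cl2))
})

test_that("large images are resized to 256 before the metric, unless disabled", {
  # a 512 image whose odd rows/columns (the ones nearest-neighbor keeps)
  # are uniform: resized metric is 0, unresized is not
  img <- array(0.5, dim = c(512, 512, 3))
  odd <- seq(1, 512, by = 2)
  img[odd, , 1] <- 0.9  # only odd rows differ; NN keeps even rows
  expect_equal(average_chromaticity_difference(img), 0)
  expect_gt(average_chromaticity_difference(img, resize = FALSE), 0)
  # small inputs are never resized
  small <- fixture_image(32, seed = 6)
  expect_equal(average_chromaticity_difference(small),
               mean(local_chromaticity_difference(rgb_to_chromalum(small))))
})

test_that("heatmap histogram conserves counts and respects proportions", {
  hm0 <- matrix(0, 7, 9)
  h0 <- heatmap_histogram(hm0, 5)
  expect_equal(h0$counts, c(63, 0, 0, 0, 0))

  withr::with_seed(61, {
    hm <- matrix(runif(50 * 40), 50, 40)
    h <- heatmap_histogram(hm, 13)
    expect_equal(sum(h$counts), 2000)
    expect_equal(h$mean, mean(hm))
  })

  # two-value heatmap with known proportions
  hm2 <- matrix(c(rep(0.1, 30), rep(0.9, 10)), 4, 10)
  h2 <- heatmap_histogram(hm2, 4)
  expect_equal(h2$counts, c(30, 0, 0, 10))
})
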