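test_that("identity transform reproduces the input", {
  img <- fixture_image(24, seed = 2)
  out <- apply_chromatic_transform(img, transform_spec(0, 1))
  expect_lt(max(abs(out - img)), 1 / 255)
})

test_that("pure rotations preserve the metric, scaling rescales it", {
  cl <- random_chroma_field(16, 16, spread = 0.01, seed = 12)
  m0 <- average_chromaticity_difference(cl)
  withr::with_seed(13, {
    for (i in 1:10) {
      piv <- c(runif(1, 0.1, 0.3), runif(1, 0.3, 0.5))
      th <- runif(1, 0, 2 * pi - 1e-9)
      s <- runif(1, 0.2, 2)
      rot <- chromastress:::transform_chroma_field(cl, transform_spec(th, 1, piv))
      expect_equal(average_chromaticity_difference(rot), m0,
                   tolerance = 1e-12)
      scl <- chromastress:::transform_chroma_field(cl, transform_spec(0, s, piv))
      expect_equal(average_chromaticity_difference(scl), s * m0,
                   tolerance = 1e-9)
    }
  })
})

test_that("s = 0 collapses chromaticity to the pivot", {
  img <- fixture_image(16, seed = 4)
  out <- apply_chromatic_transform(img, transform_spec(0.3, 0))
  expect_lt(average_chromaticity_difference(out), 1e-6)
})

test_that("transform spec validation rejects bad parameters", {
  expect_error(transform_spec(-0.1, 1), "theta")
  expect_error(transform_spec(0, -1), "s must")
  expect_error(transform_spec(0, 1, pivot = c(0.9, 0.4)), "pivot")
})

test_that("default bank has 350 unique specs including the identity", {
  bank <- generate_transform_bank()
  expect_length(bank, 350)
  keys <- vapply(bank, function(s) paste(s$theta, s$s), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(any(vapply(bank, function(s) s$theta == 0 && s$s == 1,
                         logical(1))))
  expect_error(generate_transform_bank(n = 50, theta_steps = 4, s_steps = 4),
               "grid smaller")
  expect_error(generate_transform_bank(s_range = c(2, 1)), "increasing")
})

test_that("luminance is preserved across random bank transforms", {
  img <- fixture_image(20, seed = 8)
  bank <- generate_transform_bank(n = 24, theta_steps = 6, s_steps = 4)
  ee0 <- luminance_edge_energy(rgb_to_chromalum(img))
  for (sp in bank) {
    out <- apply_chromatic_transform(img, sp)
    expect_lt(verify_luminance_preservation(img, out), 2 / 255)
    expect_lt(abs(luminance_edge_energy(rgb_to_chromalum(out)) - ee0) /
                ee0, 0.01)
  }
  # negative control: a brightened copy is caught
  brighter <- pmin(img + 0.2, 1)
  expect_gt(verify_luminance_preservation(img, brighter), 0.05)
  expect_error(verify_luminance_preservation(img, fixture_image(8)),
               "dimension")
})

test_that("build_triples hits targets on a moderate-gamut fixture", {
  img <- moderate_gamut_image(32, seed = 10)
  m0 <- average_chromaticity_difference(img)
  targets <- c(0.3, 1, 1.7) * m0
  bank <- generate_transform_bank(n = 40, theta_steps = 5, s_steps = 8,
                                  s_range = c(0.1, 2))
  trs <- build_triples(list(base = img), level_targets = targets,
                       tolerance = 0.1 * m0, bank = bank)
  expect_length(trs, 1)
  tr <- trs$base
  expect_true(all(diff(tr$metric_values) > 0))
  expect_lt(tr$max_lum_dev, 2 / 255)
  expect_true(all(abs(tr$metric_values - targets) <= 0.1 * m0))

  man <- triple_manifest(trs)
  expect_equal(nrow(man), 3)
  expect_equal(man$level, c("low", "medium", "high"))

  # determinism: same inputs, same result bit for bit
  trs2 <- build_triples(list(base = img), level_targets = targets,
                        tolerance = 0.1 * m0, bank = bank)
  expect_identical(trs$base$metric_values, trs2$base$metric_values)
})

test_that("grayscale input admits no triple and fails cleanly", {
  gray <- array(rep(matrix(withr::with_seed(14, runif(16 * 16)), 16, 16), 3),
                dim = c(16, 16, 3))
  bank <- generate_transform_bank(n = 12, theta_steps = 4, s_steps = 3)
  expect_error(
    suppressMessages(build_triples(list(g = gray),
                                   level_targets = c(0.001, 0.01, 0.02),
                                   tolerance = 1e-4, bank = bank)),
    "no image yielded")
})
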