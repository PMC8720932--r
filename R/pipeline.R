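# End-to-end orchestration of the three analyses: rating experiments
# (metrics -> mixed models -> correlations), the natural-scene comparison
# (corpus distribution -> rectified z -> shift curve -> extreme patches),
# and matched-triple generation. All randomness is seeded through function
# arguments; outputs are plain data frames / lists, optionally written as
# CSV/JSON next to a run log.

write_outputs <- function(report, out_dir, seed) {
  if (is.null(out_dir)) return(invisible(report))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$files))
    utils::write.csv(report$files[[nm]],
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  if (!is.null(report$json))
    jsonlite::write_json(report$json, file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("chromastress %s", as.character(utils::packageVersion("chromastress"))),
    sprintf("seed: %d", seed),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
    file.path(out_dir, "run_log.txt"))
  invisible(report)
}

#' Per-image metric table
#'
#' Computes the average chromaticity difference and the luminance-domain
#' statistics (spectral slope alpha, departure from 1/f^alpha, luminance
#' edge energy) for a set of images.
#'
#' @param images Named list of sRGB arrays.
#' @param resize Passed to [average_chromaticity_difference].
#' @return Data frame: image_id, chroma_metric, alpha, departure,
#'   edge_energy.
#' @export
compute_image_metrics <- function(images, resize = TRUE) {
  if (is.null(names(images)))
    names(images) <- sprintf("img%03d", seq_along(images))
  rows <- lapply(names(images), function(id) {
    img <- images[[id]]
    cl <- rgb_to_chromalum(img)
    sp <- tryCatch(departure_from_one_over_f(cl$lum),
                   error = function(e) list(departure = NA_real_,
                                            alpha = NA_real_))
    data.frame(image_id = id,
               chroma_metric = average_chromaticity_difference(img,
                                                               resize = resize),
               alpha = sp$alpha, departure = sp$departure,
               edge_energy = luminance_edge_energy(cl))
  })
  do.call(rbind, rows)
}

#' Rating-experiment analysis
#'
#' Full analysis of one rating experiment: per-image metrics, invariant-
#' observer exclusion, the chroma-only, spectral-only and both-covariate
#' mixed models with likelihood-ratio comparisons, and bootstrap Spearman
#' correlations of mean ratings against each metric. If a second stimulus
#' set's metrics are supplied, the two metric distributions are compared
#' with a two-sample KS test.
#'
#' @param images Named list of sRGB arrays.
#' @param ratings Data frame (observer_id, image_id, rating) whose
#'   image_id values match `names(images)`.
#' @param set2_metrics Optional numeric vector of a second set's metric
#'   values for the KS comparison.
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List: `metrics`, `excluded`, `fits` (null/chroma/spectral/both),
#'   `lrt` (chroma vs null, both vs chroma, both vs spectral),
#'   `correlations`, and `ks` (or NULL).
#' @export
run_experiment_analysis <- function(images, ratings, set2_metrics = NULL,
                                    B = 1000, seed = 1L, out_dir = NULL) {
  metrics <- compute_image_metrics(images)
  excl <- exclude_invariant_observers(ratings)
  dat <- merge(excl$ratings, metrics, by = "image_id")
  have_spectral <- !anyNA(metrics$departure)
  fits <- list(null = fit_discomfort_lmm(dat, character(0)),
               chroma = fit_discomfort_lmm(dat, "chroma_metric"))
  lrt <- list(chroma_vs_null = likelihood_ratio_test(fits$null, fits$chroma))
  if (have_spectral) {
    fits$spectral <- fit_discomfort_lmm(dat, "departure")
    fits$both <- fit_discomfort_lmm(dat, c("chroma_metric", "departure"))
    lrt$both_vs_chroma <- likelihood_ratio_test(fits$chroma, fits$both)
    lrt$both_vs_spectral <- likelihood_ratio_test(fits$spectral, fits$both)
  }
  mean_ratings <- tapply(dat$rating, dat$image_id, mean)
  mm <- metrics[match(names(mean_ratings), metrics$image_id), ]
  cors <- rbind(
    data.frame(metric = "chroma_metric",
               as.data.frame(spearman_bootstrap(mm$chroma_metric,
                 as.numeric(mean_ratings), B = B, seed = seed)[1:3])),
    if (have_spectral)
      data.frame(metric = "departure",
                 as.data.frame(spearman_bootstrap(mm$departure,
                   as.numeric(mean_ratings), B = B, seed = seed + 1L)[1:3])))
  ks <- if (!is.null(set2_metrics))
    ks_two_sample(metrics$chroma_metric, set2_metrics)
  report <- list(metrics = metrics, excluded = excl$excluded, fits = fits,
                 lrt = lrt, correlations = cors, ks = ks,
                 mean_ratings = as.numeric(mean_ratings))
  report$files <- list(metrics = metrics, correlations = cors)
  report$json <- list(
    lrt = lrt,
    aic = lapply(fits, `[[`, "AIC"),
    slopes = lapply(fits["chroma"], function(f) f$fixed_effects))
  write_outputs(report, out_dir, seed)
  report[setdiff(names(report), c("files", "json"))]
}

#' Natural-scene comparison analysis
#'
#' Builds the reference metric distribution from a corpus, computes
#' rectified z-scores of the stimuli against it, traces the shift-
#' correlation curve, and (optionally) ranks random patches sampled from
#' the corpus images.
#'
#' @param corpus_metrics Numeric vector of corpus metric values (e.g. from
#'   [compute_image_metrics] on a corpus, or a synthetic corpus).
#' @param stim_metrics Per-stimulus metric values.
#' @param mean_ratings Per-stimulus mean discomfort ratings.
#' @param shifts Shift grid (default +/- 3 sigma in 25 steps).
#' @param B Bootstrap replicates per shift.
#' @param seed Integer seed.
#' @param patch_images Optional named list of images to sample patches
#'   from.
#' @param n_patches,patch_size Patch sampling parameters.
#' @param out_dir Optional output directory.
#' @return List: `dist`, `rectified_z`, `shift_curve`, `rho_raw` (plain
#'   Spearman of metrics vs ratings), `rho_rectified`, `rectified_vs_raw_p`
#'   (bootstrap difference test), and `extreme_patches` (or NULL).
#' @export
run_nature_comparison <- function(corpus_metrics, stim_metrics, mean_ratings,
                                  shifts = NULL, B = 1000, seed = 1L,
                                  patch_images = NULL, n_patches = 25,
                                  patch_size = 64, out_dir = NULL) {
  dist <- corpus_distribution(corpus_metrics)
  rz <- rectified_zscores(stim_metrics, dist)
  curve <- shift_correlation_analysis(stim_metrics, mean_ratings, dist,
                                      shifts = shifts, B = B, seed = seed)
  rho_raw <- spearman_bootstrap(stim_metrics, mean_ratings, B = B,
                                seed = seed + 1000L)
  rho_rect <- if (stats::sd(rz) > 0)
    spearman_bootstrap(rz, mean_ratings, B = B, seed = seed + 2000L)
  else list(rho = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
  diff_p <- if (stats::sd(rz) > 0)
    spearman_difference_test(mean_ratings, stim_metrics, rz, B = B,
                             seed = seed + 3000L)$p
  else NA_real_
  patches <- NULL
  if (!is.null(patch_images)) {
    tabs <- lapply(names(patch_images), function(id)
      sample_patches(patch_images[[id]], n = n_patches, size = patch_size,
                     seed = seed + match(id, names(patch_images)),
                     source_id = id))
    patches <- rank_extreme_patches(do.call(rbind, tabs),
                                    k = min(10, n_patches))
  }
  report <- list(dist = dist, rectified_z = rz, shift_curve = curve,
                 rho_raw = rho_raw[1:3], rho_rectified = rho_rect[1:3],
                 rectified_vs_raw_p = diff_p, extreme_patches = patches)
  report$files <- list(shift_curve = as.data.frame(curve))
  write_outputs(report, out_dir, seed)
  report[setdiff(names(report), c("files", "json"))]
}

#' Matched-triple generation
#'
#' Applies the transform bank to each source image, assembles low/medium/
#' high triples at the target metric levels, verifies luminance
#' preservation, and returns the manifest.
#'
#' @param images Named list of sRGB arrays.
#' @param level_targets,tolerance,bank Passed to [build_triples].
#' @param n_triples Optional number of triples to sample from the complete
#'   ones (seeded); default keeps all.
#' @param seed Integer seed (used only when `n_triples` is set).
#' @param out_dir Optional output directory (manifest.csv + member PNGs).
#' @return List: `triples`, `manifest`.
#' @export
run_triple_generation <- function(images,
                                  level_targets = c(0.0035, 0.0115, 0.0190),
                                  tolerance = 0.002,
                                  bank = generate_transform_bank(),
                                  n_triples = NULL, seed = 1L,
                                  out_dir = NULL) {
  triples <- build_triples(images, level_targets = level_targets,
                           tolerance = tolerance, bank = bank)
  if (!is.null(n_triples) && n_triples < length(triples)) {
    keep <- withr::with_seed(seed,
      sample(names(triples), n_triples))
    triples <- triples[keep]
  }
  manifest <- triple_manifest(triples)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    for (tr in triples) for (lv in names(tr$members))
      write_image(tr$members[[lv]],
                  file.path(out_dir, sprintf("%s_%s.png", tr$base_id, lv)))
  }
  list(triples = triples, manifest = manifest)
}
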