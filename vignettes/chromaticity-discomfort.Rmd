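---
title: "Chromaticity differences, natural-scene statistics, and visual discomfort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromaticity differences, natural-scene statistics, and visual discomfort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromastress)
```

## The scientific problem

Some static images are aversive to look at: they produce discomfort,
perceptual distortions, and unusually strong cortical responses. A
long-standing account ties this to efficient coding — the visual system is
adapted to the statistical regularities of natural scenes, and stimuli that
deviate strongly from those regularities are encoded inefficiently and
uncomfortably. For luminance this is well established: natural scenes have
Fourier amplitude spectra close to $1/f^{\alpha}$, and departure from that
regularity predicts discomfort. `chromastress` implements the chromatic side
of the story: a parameter-free image metric of local chromatic contrast, the
machinery to compare it against natural-scene statistics, stimulus
transformations that manipulate it while holding luminance fixed, and the
mixed-effects inferential layer for relating it to discomfort ratings.

## The color metric

The metric works in the CIE 1976 UCS chromaticity plane $(u', v')$, where
Euclidean distance approximates perceived chromatic difference independently
of luminance. The processing chain for an sRGB image is:

1. resize to $256 \times 256$ with nearest-neighbor sampling (no new colors
   are invented; skipped when the input is already at most $256 \times 256$);
2. linearize with the IEC 61966-2-1 transfer function, convert to CIE XYZ
   with the sRGB/D65 matrix, and project to $(u', v')$:
   $u' = 4X/(X + 15Y + 3Z)$, $v' = 9Y/(X + 15Y + 3Z)$;
3. for each pixel $px$, average the distance
   $d(px, px_i) = \sqrt{(u'_{px} - u'_{px_i})^2 + (v'_{px} - v'_{px_i})^2}$
   over its existing 8-connected neighbors $px_i$ ($N = 3$ in corners,
   $N = 5$ on borders, $N = 8$ in the interior), giving a local-difference
   heatmap;
4. average the heatmap over all pixels.

The result is a single dimensionless $u'v'$ distance, zero exactly when the
chromaticity field is constant — luminance texture alone contributes
nothing. The image average is the unweighted mean of per-pixel values, so
border pairs carry slightly different weight than interior pairs; this is
the definition, not an approximation. Two analytic anchors used throughout
the tests: a large two-color checkerboard with 1-pixel cells converges to
$d/2$ (interior pixels differ from 4 of 8 neighbors), and 1-pixel vertical
stripes have interior local value $6d/8$, where $d$ is the chromaticity
distance between the two colors.

Two numerical conventions needed fixing where the chain is undefined or
underdetermined:

* **Black pixels.** $u'v'$ is 0/0 at black. Pixels with
  $X + 15Y + 3Z < 10^{-9}$ are assigned the D65 white-point chromaticity,
  so dark pixels cannot fabricate chromatic edges against their neighbors.
  An alternative (propagating NA and dropping those pairs) would change the
  neighbor counts; the white-point convention keeps the metric total.
* **Nearest-neighbor rule.** The index map is
  $\mathrm{src} = \lfloor (\mathrm{dst} + 0.5)\,\mathrm{in}/\mathrm{out} \rfloor$
  (half-pixel centers, clamped). Aspect ratio is deliberately *not*
  preserved: oversized scenes of any shape are mapped onto the
  $256 \times 256$ grid, matching how heterogeneous scene databases are
  processed. Pre-cut patches are computed at native size via
  `resize = FALSE`.

## Luminance-domain statistics

`departure_from_one_over_f()` summarizes how far a luminance plane strays
from the natural $1/f^{\alpha}$ regularity: the radially averaged Fourier
amplitude spectrum (integer bins in cycles/image, DC excluded) is fit as
$\log A = c - \alpha \log f$ by least squares over frequencies from 2
cycles/image to Nyquist, and the departure is the RMS residual in
log-amplitude units. This is a deliberately simple, documented statistic for
the construct "deviation from $1/f^{\alpha}$"; it is not a reproduction of
any particular contrast-sensitivity-weighted discomfort metric, and model
effects computed with such metrics elsewhere are not comparable
numerically. The low-frequency cutoff at 2 cycles/image and the absence of
windowing are the defaults; both are conventional and the fit is invariant
to positive rescaling of luminance.

`luminance_edge_energy()` applies the same 8-neighborhood local-difference
statistic as the color metric to the scalar luminance plane. It is the
quantity the chromatic transforms hold constant.

## Luminance-preserving chromatic transforms

A transform maps each pixel's chromaticity as
$c \mapsto p + s\,R(\theta)(c - p)$ about a pivot $p$ (default D65 white),
leaving luminance untouched. A pure rotation ($s = 1$) preserves all
pairwise $u'v'$ distances and hence the metric exactly; combining rotation
with radial scaling ($s \neq 1$, a *pseudo-rotation*) rescales the metric by
exactly $s$ at field level. That linearity is the lever for pushing one base
image to several metric levels: the default bank is a deterministic grid of
35 angles $\times$ 10 scales ($s \in [0.15, 2.2]$, snapped so $s = 1$ is on
the grid) = 350 transforms including the identity.

On inversion to sRGB, chromaticities pushed outside the gamut are projected
back toward the pivot along the chromatic vector at fixed luminance, by
binary search on the shrink factor. This preserves luminance analytically
(the projection moves only $X$ and $Z$) and preserves hue direction; its
cost is that achieved metric values fall slightly below $s \times$ the base
metric when clipping occurs, which is why `build_triples()` selects
transforms by *achieved* metric rather than by nominal scale, and annotates
each triple member with its clipped-pixel fraction.

Triples target the low/medium/high metric levels 0.0035, 0.0115 and 0.0190
by default — the lower end, mean and upper end of a typical
high-chromatic-contrast stimulus set — with a default matching tolerance of
0.002, between the within-level spreads such designs report (SD
0.0009–0.0018). Images that cannot reach a level within tolerance are
skipped with a logged reason rather than force-fit.

## Natural-scene reference and rectified deviation

A corpus of scene images yields a metric distribution summarized by its raw
mean $\mu$ and sample SD $\sigma$ (a Gaussian KDE with Silverman bandwidth
is attached for plotting but never used for inference). Stimuli are scored
by the rectified z-score $\max(0, (x - \mu)/\sigma)$: only chromatic
contrast *exceeding* natural levels counts, encoding the hypothesis that
subdued color arrangements do not cause discomfort.

The shift analysis stress-tests that reference point: the distribution is
translated rigidly by $\delta$ (mean shifted, $\sigma$ unchanged), rectified
scores are recomputed, and their Spearman correlation with mean discomfort
is traced as a function of $\delta$ with bootstrap percentile CIs. Two exact
properties anchor the curve: at shifts low enough that nothing is
rectified, the ranks equal the raw-metric ranks and the curve equals the
plain Spearman correlation exactly; at shifts beyond the largest stimulus
metric every score is zero and the correlation is undefined — recorded as
`NA`, never silently as 0.

## The inferential layer

Ratings are ordinal codes 1–5 treated as numeric in a Gaussian linear mixed
model — the pragmatic convention for this design; a cumulative-link model is
out of scope. Observers with zero rating variance are excluded before
fitting. The default random-effects structure is a correlated random
intercept and random slope per observer for each numeric covariate, so
adding one covariate to the null model adds 3 parameters (fixed slope,
slope variance, intercept–slope covariance) and one-covariate
likelihood-ratio tests have df = 3. Covariates are z-scored *across images*
(one value per image, regardless of how many observers rated it), with
raw-scale slopes also reported, since slope magnitudes are otherwise
scale-dependent. All fits use maximum likelihood, never REML, so
log-likelihoods are comparable across fixed-effect structures.

Tukey contrasts between metric levels use the single-step multiplicity
adjustment on the joint normal distribution of the contrasts
(`multcomp::glht` on the `lme4` fit). Bootstrap Spearman CIs are
percentile-type over paired item resamples (images, not observers), and the
difference test between two correlations sharing the same items doubles the
smaller tail probability of the resampled difference crossing zero, capped
at 1. All resampling is seeded explicitly.

## What the synthetic generators emulate — and what they do not

`make_synthetic_corpus()` produces chromatic-noise fields around the white
point whose realized metric distribution matches a target mean and SD
(defaults 0.0056 and 0.0023, the scale of calibrated natural-scene
collections, under which about 97% of the distribution falls below 0.010).
Calibration is exact rather than lookup-based: the metric is exactly linear
in chromatic spread about a pivot, so each image's spread is rescaled so
its field-level metric equals its drawn target; residual discrepancy after
sRGB rendering comes only from gamut clipping and is negligible at natural
spreads. Per-image targets are drawn from a normal truncated below at
$\mu/10$.

`simulate_ratings()` draws each observer's intercept and slope from a
bivariate normal and discretizes the latent Gaussian response by rounding
and clamping to 1–5 — the simplest mechanism consistent with fitting a
Gaussian LMM to ordinal codes. Defaults (grand mean 2.5, slope 0.3 per
standardized metric unit, intercept SD 0.5, slope SD 0.15, residual SD 0.8)
give rating distributions and between-observer slope spreads of the size
seen in online discomfort-rating experiments.

These generators share the *statistics* the pipeline consumes with real
data, not the *content*: synthetic corpora have no objects, no fruit, no
sky–foliage boundaries, and their chromatic covariance is white rather than
scene-like; rating simulations have no response styles, no scale-use
differences beyond the random intercept, no display heterogeneity beyond
what the residual absorbs. Passing tests therefore demonstrate that the
chain measures, manipulates and recovers what it claims under its own
model; they say nothing about whether real discomfort follows that model.
`make_fruit_scene()` sits in between: chromatically contrasting disks on a
$1/f$-textured background reproduce the one natural configuration known to
reach stimulus-like metric values (scattered colorful items against a
contrasting ground), with chromatic difference concentrated exactly on the
item outlines.

## Validation scale and numerical choices

The shipped validation uses problem sizes chosen to exercise every code
path at desk scale: metric oracles on fields up to $16 \times 16$ against a
brute-force double loop (agreement to $10^{-12}$); pattern anchors on a
$256 \times 256$ checkerboard (within 1% of $d/2$, the finite-border excess
being about 0.3% at that size); the full 350-transform bank on
$32 \times 32$ fixtures (luminance deviation below $2/255$, edge energy
within 1%); slope recovery over 100 replicates of a 30-image corpus rated
by 40 simulated observers (CI coverage at least 90%); LRT size over 200
null replicates (rejection rate in $[0.02, 0.10]$); bootstrap CI coverage
over 500 bivariate-normal replicates at $n = 50$ ($95\% \pm 3\%$).
`scripts/acceptance.R` re-runs the pipeline end to end at study scale (a
200-image corpus, two 50-image stimulus sets, 59 simulated observers) from
a single seed.

Other conventions: computations are double precision throughout with
display rounded to 4 decimals; the gamut binary search runs 40 iterations
(resolution $\sim 10^{-12}$ in the shrink factor); extreme-patch ranking
breaks metric ties by (source, top, left) so rankings are reproducible;
`generate_transform_bank()` and `build_triples()` are fully deterministic,
with optional triple subsampling exposed behind an explicit seed.

## Known limitations

* $u'v'$ distance is only approximately perceptually uniform; no CIEDE2000
  or cone-contrast variant is provided.
* The gamut projection compresses saturation for strongly scaled
  transforms; heavily clipped triple members (fraction above 10%) should be
  filtered by the user via the manifest's `clipped_fraction`.
* The departure statistic is a construct-level stand-in; its numerical
  values are not comparable with contrast-weighted discomfort metrics from
  the luminance literature.
* Ordinal ratings are modeled as Gaussian; with strongly skewed rating
  distributions the linear model's CIs are approximate.
* ICC profiles, chromatic adaptation and HDR input are out of scope; inputs
  are assumed ordinary sRGB.
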