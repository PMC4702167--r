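---
title: "Morphometric staging of Drosophila egg chambers from DAPI images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric staging of Drosophila egg chambers from DAPI images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drosophila oogenesis proceeds through fourteen morphologically defined
stages. Each egg chamber contains sixteen germline cells — one oocyte and
fifteen nurse cells — wrapped in a follicle-cell epithelium, and its stage
is traditionally called by eye from morphology. That call is subjective,
varies between labs, and breaks down exactly where it matters most: when a
genetic perturbation removes the biomarker a staging protocol relies on.
`eggstage` stages chambers from the DAPI channel alone. Since DAPI marks
only nuclei, every feature is derived from nuclear positions and
intensities: chamber size, elongation, the DAPI-sparse posterior oocyte,
the uniformity of the follicle-cell epithelium, and two stage-specific
nuclear signals. Stages 2-12 are modeled; stage 1 (germarium-adjacent,
hard to delimit) and stage 13+ (degenerating nurse nuclei) are out of
scope, and stages 10A/10B are merged as 10 for model fitting and split
afterwards by the centripetal-migration detector.

## The pipeline

```{r, eval = FALSE}
library(eggstage)
img <- read_chamber_image("chamber.tif", pixel_size = 0.31)
fv  <- extract_features(img)
```

`extract_features()` chains the following steps; every intermediate is
available for audit in the returned object.

**Segmentation.** The input is a single cropped midsagittal cross section
containing one chamber. The image is binarized at 20% of Otsu's threshold
— deliberately low so that the dim cytoplasmic background of the chamber
joins the foreground and the chamber becomes one solid region. An average
filter (default 15 px window, replicate borders) then bridges any
remaining gaps while leaving small off-chamber noise disconnected; plain
Otsu re-thresholding and 8-connected largest-component extraction isolate
the chamber; holes are filled and the mask is applied to the original
intensities. Chan-Vese active contours, initialized from a regular grid of
small circles and restricted to the masked chamber, then segment the
nuclei: the two-phase piecewise-constant model separates bright nuclei
from the dim intra-chamber background. The chamber itself is modeled as
the convex hull of the segmented nuclei and its size is the hull area in
square micrometres (hull pixel count times the pixel area).

**Geometry.** Principal component analysis of the hull-interior pixel
coordinates gives the major/minor axes; the chamber aspect ratio is the
ratio of the standard deviations of the projections, which is far less
sensitive to local boundary irregularities and tilt than bounding-box
lengths. The major axis is oriented into a posterior-anterior direction by
counting nuclei pixels inside a radially shrunken boundary (the small
follicle-cell nuclei stay outside the shrunken region, the large nurse
cells inside): the anterior is the side with more nurse-cell material.

**Oocyte size.** The middle axis is sampled at 30 equally spaced points
from the posterior end; between consecutive points, a band of hull pixels
perpendicular to the axis is scored by its fraction of interior
(nurse-cell) nuclei pixels; the oocyte boundary is the posterior-most band
reaching 10%, and the oocyte fraction is the share of hull pixels
posterior to it. The band foreground is the *interior* nuclei mask, not
all nuclei: the epithelium covers the oocyte too, and counting the rim
would trip the first band of every chamber.

**Follicle-cell distribution.** Nuclei components lying entirely outside a
(more strongly) shrunken boundary are the follicle cells. The plane around
the centroid is split into 12 equal sectors starting at the anterior end;
each sector's density is its follicle pixel count divided by the chamber
boundary length inside the sector. Uniformity is scored as the
triangular-discrimination distance
$\Delta(p, q) = \sum_i (p_i - q_i)^2 / (p_i + q_i)$
between the normalized density vector and the uniform distribution
(0 iff equal, maximal value 2 on disjoint supports). Anterior stretching
of the epithelium at stage 9 raises this distance, which is what separates
stages 8 and 9.

**Stage-specific detectors.** At stage 4, polytene chromosomes make nurse
nuclei look like clusters of discrete blobs: a watershed transform of the
nuclear intensity relief, with maxima shallower than a 0.07 intensity
depth merged, counts fragments per nucleus; a chamber is blob-positive at
a median of 3 or more. At stage 10B, centripetal follicle cells migrate
inward along the nurse/oocyte boundary: a band of width 0.8 standard
deviations (along the major axis) anchored at the detected oocyte
boundary is scanned for nuclei components lying entirely inside it (nurse
cells straddle the band and are excluded); candidates whose centroid lies
within 0.15 minor-axis standard deviations of the hull boundary are
centripetal cells, and two or more call the chamber 10B.

**Staging statistics.** Chamber growth is exponential, so the log chamber
area is linear in stage; `fit_stage_linear()` reports the regression with
its R^2 and 95% confidence band. The classifier is a cumulative-link
(proportional-odds) ordinal regression fitted per feature,
$P(\text{stage} > k \mid x) = \operatorname{logit}^{-1}(\beta x - \alpha_k)$,
maximized by BFGS with an analytic gradient on the standardized feature.
Cutoffs between consecutive stages are $\alpha_k / \beta$ (the feature
value where the exceedance probability crosses 1/2); a cutoff is reported
as unavailable when its intercept gap falls below a tenth of the median
gap, which reproduces the situation where two late stages are
indistinguishable in size. `classify_stage()` uses the log-size model by
default — size is the most stable feature — and can fuse the per-feature
models by log-space averaging. The stage-8/9 boundary uses a different
rule: fit a Gaussian to each group's Delta-distances and cut at the
intersection of the two densities between the means (the
likelihood-ratio boundary; with equal SDs, the midpoint), alongside a
two-sample t-test (pooled variance by default, Welch optional).

## Tunable parameters

All knobs live in one flat list, `chamber_params()`, and can also be read
from a `key = value` config file. The ones that matter:

| parameter | default | meaning |
|---|---|---|
| `otsu_scale` | 0.2 | initial threshold as a fraction of Otsu's |
| `filter_window` | 15 px | average-filter window; must bridge nucleus gaps without annexing off-chamber noise |
| `cv_mu` | 0.15 | Chan-Vese boundary-length weight |
| `cv_max_iter` | 400 | level-set iteration cap |
| `cv_init_radius`, `cv_init_spacing` | 3.5, 10 px | initialization circle grid |
| `shrink_orient`, `shrink_follicle` | 0.85, 0.80 | radial shrink factors for orientation / follicle separation |
| `n_axis_points` | 30 | middle-axis samples |
| `oocyte_frac_threshold` | 0.10 | band foreground fraction at the oocyte boundary |
| `n_sectors` | 12 | follicle-distribution sectors |
| `centripetal_bandwidth_sds` | 0.8 | detection band width in SDs of the major axis |

Two defaults deserve their rationale. The Chan-Vese length weight is
0.15 rather than the textbook 0.25 because follicle-cell nuclei span only
a few pixels at typical calibrations; with unit-range intensities a
heavier length penalty can erase a small nucleus outright (its data gain
is proportional to its area, the penalty to its perimeter). The
initialization grid is dense (radius 3.5 px, spacing 10 px) because a
level set cannot nucleate new components: every nucleus must overlap the
initial interface or it is unreachable.

## Numerical choices

The level-set evolution is an explicit scheme with the regularized delta
of width 1 and time step 2. Three guards make it robust. First, the
initial level-set amplitude is clamped to [-0.5, 0.5] and the evolving
one to [-2, 2], so the regularized delta stays appreciable everywhere and
any pixel remains revisitable. Second, the curvature term is regularized
(denominator offset 0.01, clamp at |kappa| = 10), since central
differences on flat plateaus otherwise produce divisions by near-zero.
Third, the two region means are anchored for the first 40 sweeps to an
Otsu split of the evolution domain: when the nuclei occupy a small
minority of the region of interest, the grid initialization gives two
nearly equal means, and unanchored dynamics can converge to an arbitrary
split of the background. The evolution is also restricted to the filled
chamber mask, which makes the two-phase split unambiguous — nuclei
against intra-chamber background — instead of chamber against black
exterior. Convergence is declared when fewer than a fraction 1e-5 of
pixels change sign for five consecutive sweeps, but only after the
interface has actually moved (at least 0.5% cumulative sign changes), so
the slow initial phase cannot masquerade as convergence.

Otsu's threshold is computed on a fixed 256-bin histogram of [0, 1] with
exhaustive between-class-variance maximization and ties broken toward the
lower threshold; on large images the accumulators are floating point (the
bin-count products overflow 32-bit integers beyond ~46k pixels).
Intensities are normalized by the inferred bit depth (8/12/16-bit) on
construction, so thresholds are calibration-independent. Convex hulls are
rasterized by half-plane tests on pixel centers ("inside or on"); a pixel
is a unit square for area purposes. Components use 8-connectivity with
ties broken in raster-scan order. Degenerate inputs (constant images,
collinear foregrounds, empty masks, exact orientation ties, an oocyte
threshold never reached, zero follicle components) are flagged or raise
errors rather than producing silent guesses.

## The synthetic-data generator

There is no public corpus of labeled egg-chamber cross sections, so the
package ships a generator whose defaults *are* its study conditions — it
is first-class, tested code, not a fixture. `chamber_spec()` draws one
chamber's morphology at a target stage: log area linear in stage (slope
0.38 per stage, about log(1500) square micrometres at stage 2, Gaussian
noise SD 0.15 — chosen so rendered sizes are realistic, with
stage-5 chambers near 2-3 x 10^3 and stage-8 near 10^4 square
micrometres), aspect ratio drifting from ~1 toward ~3 at stage 12, oocyte
fraction 0 before stage 6 and rising from ~0.12 to ~0.70 with a
late-stage acceleration (nurse-cell dumping), Delta-distance groups near
0.12 (through stage 8) and 0.30 (stage 9 on) with SD 0.05, polytene
texture at stage 4, anterior thinning of the epithelium from stage 9.
`render_chamber()` turns a spec into an image: an ellipse at random
orientation carrying a diffuse cytoplasmic glow (7% of nuclear
intensity), a rim of small follicle nuclei placed by arc-length quantiles
(one per ~8 micrometres of perimeter, radius ~2.5 micrometres), a
polydisperse packing of large nurse nuclei that tiles the non-oocyte
interior to ~75% coverage with a row of cells abutting the oocyte
boundary, an empty posterior oocyte region, off-chamber distractor blobs,
and Gaussian pixel noise. Nuclei have Gaussian intensity profiles, so the
active contours face a genuine boundary-finding task. Ground truth
(masks, hull area, axis ratio, orientation, oocyte fraction, sector
distribution) is recorded before noise; the recorded aspect ratio is
measured from the truth hull raster so that it describes the rendered
object even when anterior thinning deforms the hull.

What the generator does *not* emulate: point-spread blur and shot noise,
out-of-focus light from neighboring z-planes, chromatic or intensity
vignetting, touching chambers, partial chambers at the image border, and
the full within-stage biological variance of real ovarioles. Passing
tests therefore demonstrate that the pipeline implements its contracts
correctly on images with the stated geometric and statistical structure —
not that it is validated on real microscope output.

## Design decisions and known limitations

- The posterior-anterior orientation rule (more interior-nuclei pixels on
  the anterior side) is reliable once the oocyte occupies roughly a fifth
  of the chamber. Below that — oocyte fractions near 0.1, i.e. stage 6 —
  the nurse-pixel asymmetry is comparable to packing noise and the
  orientation genuinely flips in a minority of chambers; the orientation
  tie/flip risk at early stages is a property of the morphology, not of
  the implementation. Size-based staging is unaffected.
- The oocyte boundary inherits the 30-band granularity: one band is
  ~3.5% of the chamber length, which bounds the achievable precision of
  the area fraction at roughly +-0.03 for mid-stage geometries.
- Watershed fragment counting uses an intensity-depth tolerance (0.07)
  roughly three times the noise-induced relief and half the
  chromosome-blob relief of the generator; on real images this knob and
  the blob-positive threshold (median >= 3 fragments) should be
  re-inspected visually before trusting the stage-4 call.
- The centripetal detector reports *any* rim-adjacent cell lying fully in
  the band. On crowded rims, ordinary follicle cells near the oocyte
  boundary can satisfy this; the detector is therefore a flag to be read
  together with the stage-10 size call, and the quantitative guarantees
  are stated for constructed scenes with a clear band.
- The cumulative logit is the canonical model for "probability that a
  sample comes from a stage later than k"; a probit link is available as
  an option.
- The two-sample t-test pools its variance by default; Welch is an
  option.
- The "largest region" is measured before hole filling.
- Model fitting merges 10A/10B into stage 10; the centripetal detector
  refines the call afterwards. Stages 1 and 13-14 are out of scope.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` re-runs the whole
pipeline from scratch — rendering chambers, extracting features, training
and evaluating the staging models — and writes the measured quantities
(segmentation and geometry error, orientation accuracy, oocyte error,
detector separation rates, regression R^2 values, the stage-8/9 cutoff
and p-value at small group sizes (11 and 9 chambers), ordinal-recovery
error, and end-to-end staging accuracy) as JSON. Problem sizes are 33
chambers for geometry, 12 for the oocyte rule, 40 paired renders for the
polytene detector, 15 chambers per stage for regressions, and 2 x 165
chambers for the train/test staging loop. The testthat suite asserts the
same properties at fixed seeds with the tolerances stated in the tests.
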