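---
title: "Wide-baseline drone stereo: models, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wide-baseline drone stereo: models, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dronestereo)
```

## The measurement problem

Plant breeders need canopy heights for thousands of plants, at millimetre
resolution, over whole fields. Drone photogrammetry normally answers this
with structure-from-motion over hundreds of overlapping photographs, which
is slow, fails unpredictably, and resolves heights only at the
centimetre scale. `dronestereo` implements the alternative this package is
built around: treat **two consecutive nadir photographs** from a single
drone-mounted camera as a stereo pair whose baseline — the physical
distance between the two exposures — is measured by RTK-GNSS. Because the
drone can separate the exposures by a metre or more (far beyond any
physical stereo rig), the disparity of a point at distance $l$,

$$d = \frac{f\,b}{l},$$

is large, and the depth step represented by one disparity level,

$$\Delta d = l_d - l_{d+1} = \frac{f b}{d} - \frac{f b}{d+1} = \frac{l_d}{d+1},$$

is small: millimetres at a few metres of altitude. A plant of ground
disparity $d_g$ and canopy disparity $d_p$ then has height

$$p_h = \frac{f b}{d_g} - \frac{f b}{d_p}.$$

The price of the free-flying baseline is that the pair is uncalibrated:
the camera rotates slightly between the two exposures, so every pair needs
its own rectification, computed in flight. That in-flight calibration is
the heart of the package.

## Geodesy

Baselines come from pairs of RTK fixes (decimal degrees). For sub-metre to
few-metre separations the haversine great-circle form on a mean-radius
sphere (6 371 000 m, configurable) is used:

$$b = 2 r \arcsin\sqrt{\sin^2 L_{a3} + \cos L_{a1} \cos L_{a2} \sin^2 L_{o3}},
\qquad L_{a3} = \tfrac{L_{a1}-L_{a2}}{2},\; L_{o3} = \tfrac{L_{o1}-L_{o2}}{2}.$$

The $\arcsin$ is deliberate: the half-angle radicand is the haversine of
the central angle, and inverting it with $\arccos$ — as one sometimes sees
written — would return nearly $\pi r$ for nearby points. At these
separations the spherical model agrees with a local planar approximation
to better than $10^{-6}$ relative error, and the dominant error source is
instead the printed precision of the log (8 decimals of latitude
$\approx$ 1 mm, 7 decimals of longitude $\approx$ 9 mm), which is why
recomputed distances carry up to about 2 cm of rounding slack on
multi-metre pairs. Ellipsoidal geodesics and altitude-aware 3-D baselines
are out of scope.

## ZNCC block matching

Dense correspondence uses zero-mean normalized cross-correlation over
square windows (default $15\times15$, i.e. `window_radius = 7`). ZNCC is
invariant to positive affine intensity changes, which matters because the
two photographs are exposed seconds apart under field illumination. Soil
and canopy carry enough micro-texture for it; windows with zero intensity
variance have no defined score and are marked invalid.

Design choices:

* **Integer disparities.** The disparity map is quantised to whole levels;
  the per-level resolution is the quantity the method is designed around,
  and the worked examples (disparity readings such as 1573 and 1374) are
  integer levels. Sub-pixel refinement exists inside the calibration
  matcher (see below) but the dense map is integer.
* **Predicted search centre.** The search range defaults to 128 levels
  centred on $f b / Z$ from the GNSS baseline and nominal altitude, so a
  long baseline does not force a long search.
* **Overlap gate.** The search must leave more than half the image width
  of overlap; otherwise the pair is refused with a distinct error class —
  in the field this is the signal to re-shoot immediately, which is cheap
  precisely because only two images are involved.
* **Overlap region only.** Columns whose admissible search range is
  truncated cannot contain the true disparity and are left invalid rather
  than matched against a wrong subset.
* **Left–right consistency.** A second matching pass from right to left
  invalidates pixels whose two matches disagree by more than one level.
  This is the standard treatment of occlusion: pixels visible in only one
  image otherwise produce confident nonsense exactly where plants meet
  ground. Those pixels render black in the exported 16-bit map.
* **Ties** break toward the smallest disparity, making maps reproducible
  byte-for-byte.

## Two-phase in-flight calibration

Calibration aligns the right image to the left so that corresponding
points share a row. It assumes the ground is locally planar and that the
gimbal keeps all rotations below about 2 degrees.

**Phase 1** detects corners (Harris operator on box-filtered gradient
products) in the left image, matches them in the right by ZNCC — with the
horizontal search bounded by the GNSS-predicted disparity — and fits a
similarity transform. The rotation/scale part is applied to the right
image so horizontal structures run roughly along the flight direction.

**Phase 2** works on *line pairs*. For scanlines $y = C_i$ in the left
image, matched ground points in the right image trace lines
$y = a_i x + b_i$ (least squares, with two outlier-rejection passes at
2.5 MAD — the first error-elimination stage). Closed forms then read the
three rotations off the line geometry:

* $\beta$ (about the y axis) makes slopes grow linearly with intercepts:
  $\beta = \tan^{-1}\!\big(f\,(a_i - a_j)/(b_i - b_j)\big)$; with more
  than two lines the package regresses slopes on intercepts, which is the
  least-squares combination of all pairs.
* $\gamma$ (about the optical axis) is the common slope left afterwards:
  $\gamma = \tan^{-1}(\bar a_i)$.
* $\alpha$ (about the x axis) bends the intercept spacing. The spacing
  formula
  $\alpha = \tan^{-1}\!\big(-f (b_i + b_k - 2 b_j)/(b_i b_j + b_j b_k + b_k b_i)\big)$
  is exact only for a triple symmetric about the principal point, where it
  measures **twice** the tilt of an exact pinhole camera; `solve_alpha()`
  therefore combines only centre-symmetric triples. Inside the calibration
  loop the package instead fits the full second-difference model — the
  intercepts of a tilted camera satisfy $b = C + f\tan\alpha + C^2\tan\alpha/f$
  to first order, so the quadratic regression coefficient of $b$ on the
  known rows $C$ gives $\tan\alpha$ with unit gain for arbitrary row
  placement, including after rows have been dropped.

The vertical shift $\Delta y$ equalises the weight balance (interpreted as
the means) of intercepts and rows, and the altitude scale $\Delta z$ maps
the shifted intercepts onto the rows in least squares over **all**
matching points, not just the line summaries. Depths from the current
disparities give a least-squares ground plane $z = ax + by + c$; because
matched points that landed on plants sit well off that plane, the plane
fit runs two MAD-rejection passes so only ground support remains.

Because the left image is itself slightly tilted, one pass of the closed
forms overfits; the loop therefore re-estimates residual corrections from
the current geometry (the overfit amounts), composes them into the running
rotation, and repeats. A candidate step is accepted only if the sum of
squared scanline errors does not increase; an increasing step is retried
at half size, and if that still increases the loop has reached the noise
floor and stops. The SSE trace is consequently non-increasing, and the
loop typically converges in 2–4 iterations (threshold: improvement below
0.01 px², at most 20 iterations). After convergence a second elimination
stage drops points inconsistent with the consensus transform (2.5 MAD)
and refines once. The left-camera tilt is read off the ground plane,
$\beta_b = \tan^{-1}(a)$, $\alpha_b = \tan^{-1}(-b \cos\beta_b)$, and the
right image is warped by the single composed homography (all steps —
similarity, rotation, shift, scale — are homographies in centred pixel
coordinates, so rectification is a single resampling, done with
Catmull-Rom bicubic interpolation to preserve the texture the matcher
depends on). For the same reason the phase-1 correction is applied to the
matched point coordinates analytically rather than by resampling the
image before phase 2: estimating from a resampled image imprints
interpolation bias on the recovered angles.

Parameters that matter:

* `band_halfwidth` ($S_R$, default 20 px): the vertical search band around
  each scanline. It must cover the worst expected vertical displacement,
  roughly $f\tan\beta_{max} + |\Delta y|_{max}$; the validation conditions
  below command up to $\pm1.5°$ and $\pm8$ px and therefore use 32 px.
  Too small a band clips matches at its edge and biases the x-rotation.
* `n_rows` (default 9) and `stride` (default 8 px): more rows stabilise
  the rotation estimates; the validation uses 11 rows.
* `plane_rms_max` (default 0.05 m): the planarity gate. Scenes whose
  robust ground-plane fit still leaves more RMS than this are flagged
  `non_planar_scene` and reported as unconverged rather than silently
  mis-calibrated.

### Sub-pixel matching inside calibration

The calibration matcher refines each integer ZNCC peak by parabolic
interpolation. Naive whole-pixel parabola fitting suffers pixel locking —
a systematic pull toward integer positions whose phase varies with the
true fractional offset. Since an x-rotation makes that fractional offset
vary quadratically across rows, pixel locking aliases directly into
$\alpha$; the package therefore samples the score at half-pixel steps on
bilinearly interpolated windows before fitting the parabola, which
reduces the locking amplitude several-fold. The dense disparity map is
unaffected (it stays integer by design).

## Height measurement

`measure_plant()` takes a plant rectangle, reads the canopy disparity as
the 99.5th percentile of valid disparities inside it and the ground
disparity as the 0.5th percentile over a surrounding ground frame, and
applies the height formula. Percentiles (rather than the raw max/min of
the worked examples, which remain available via `robust = FALSE`) guard
against single-pixel outliers. The ground frame deliberately skips a
`ground_gap` (default 15 px) around the plant rectangle: the occlusion
fringe and the matching windows that straddle the canopy edge live there,
and including them biases the ground disparity. Root-position
localisation on uneven ground and automatic plant segmentation are out of
scope — regions are supplied by the user (or by the synthetic truth in
the tests).

## Growth ratios without baselines

For repeated observations of the same plot, the ratio of a plant's height
between two days reduces to disparities alone. If the ground has not
changed, the later map can be scaled so its ground disparity matches the
earlier one (`scale_to_common_ground()`), and the height ratio becomes

$$r = \frac{1 - d_g(t_2)/d_p(t_2)}{1 - d_g(t_1)/d_p(t_1)},$$

with both baselines cancelling. Two readings of the printed relation are
possible because the published denominator repeats the same ground term
twice; the package implements the only reading consistent with the height
formula, $1/d_g - 1/d_p$. The sensitivity of $r$ to a single disparity
level is $1/(d_p - d_g)$ — about 0.28 % for a 363-level span — which is
the resolution at which growth can be tracked once one plant has been
measured by hand. The package also keeps Earth radius and growth ratio as
distinct names throughout, since both are conventionally written $r$.
Chaining calibrations across more than two images of a flight
(to extend the growth comparison beyond a single frame) is explicitly not
implemented; its error accumulation is an open problem.

## The synthetic generator: what it emulates and what it does not

Every stage is validated against `render_stereo_pair()`, a ray-casting
renderer with exact ground truth. It emulates the features the method
actually depends on:

* a near-flat ground plane with band-limited, seeded lattice noise
  (octaves at 8, 4, 2 and 1 cm with slowly decaying weights, so soil-like
  high-frequency grain gives ZNCC local variance everywhere);
* plant proxies as textured boxes of known height (their tops carry their
  own texture, so canopy pixels are matchable);
* two pinhole cameras at 4–20 m altitude separated by a 0.3–1.5 m
  horizontal baseline, with commanded perturbations — right-camera
  rotations $\beta, \gamma, \alpha$ relative to the left camera, a left
  tilt relative to nadir, a vertical image shift and an altitude change —
  all below 2°, as a gimbal guarantees;
* hidden-surface removal, so occlusion bands appear where they do in real
  pairs;
* RTK fixes placed so the haversine distance reproduces the commanded
  baseline, rounded to the log's printed precision;
* rendering at 2×2 supersampling with box downsampling, so aliasing does
  not bias ZNCC;
* optional low-frequency terrain undulation, used to verify that the
  planarity gate rejects what it should.

It does **not** emulate radiometric realism (shadows, BRDF, exposure
drift beyond affine), wind or downwash motion blur, rolling shutter, lens
distortion, or real canopy geometry (a box is matchable everywhere; a
real plant is not). Passing the synthetic suite therefore demonstrates
the geometry, the estimators and the pipeline plumbing — not field
accuracy, which in real conditions is limited by centimetre-level GNSS
fixes and by where one calls the ground under a real plant.

## Validation conditions and problem sizes

The test suite and the acceptance script run the close-range field
geometry — 4.1 m altitude, 0.81 m baseline — at desk scale: 480×360 px
images with a 550 px focal length (about 1/11 of the 5472-px sensor the
method targets). This gives a ground disparity of ~109 levels, a
per-level height resolution of ~35 mm for the plants used, and keeps a
full render–calibrate–match cycle under two seconds, so the suite can
afford 20 seeded calibration recoveries (accepted at max absolute angle
error < 0.15° and $\Delta y$ error < 1.5 px) and 10 end-to-end height
measurements (accepted within 2 per-level resolution steps of truth).
Matching correctness is pinned by a brute-force triple-loop oracle on
60×64 crops, which the compiled matcher must equal pixel-for-pixel.

## Numerical choices and degenerate inputs

* Equal best ZNCC scores break toward the smallest disparity; equal-score
  2-D matches break toward the smallest offset.
* Zero-variance windows, degenerate line geometry (all intercepts equal,
  all spacing denominators zero, zero row spread) and collinear plane
  support raise typed errors rather than returning numbers.
* The calibration loop accepts only SSE-non-increasing steps; convergence
  at the noise floor is reported as success, exhaustion of 20 iterations
  with ongoing improvement as `no_sse_convergence`.
* Angles beyond 0.2 rad are outside the wide-baseline nadir regime and
  flag `implausible_angles`.
* All randomness in the synthetic generator is either hash-based (texture,
  no RNG state touched) or locally seeded and restored (intensity noise),
  so identical inputs give byte-identical outputs.

## Known limitations

* The growth module compares single pairs of epochs; multi-image chaining
  across a flight is future work and not attempted.
* Δz is applied as a central image scaling, the simplest reading of an
  altitude change between exposures; re-projection through the plane
  would differ at the third order for these angles.
* The "weight balance" alignment of intercepts and rows is interpreted as
  equality of their means — the simplest reading; alternatives (medians,
  support-weighted means) were not pursued.
* Calibration assumes enough ground texture: fewer than 4 corner matches
  in phase 1 or fewer than 3 surviving scanlines in phase 2 abort with a
  calibration error, which the pipeline surfaces as its re-shoot signal.
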