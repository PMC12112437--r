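---
title: "Methods: OST registration, artifact removal and the eye phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OST registration, artifact removal and the eye phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocular)
```

# The measurement problem

Ocular surface temperature (OST) is read from a radiometric infrared (IR)
camera, but the anatomy that defines *where* to read it — cornea, sclera,
eyelids — is segmented far more reliably in a synchronized visible-light
(VIS) stream. The package's job is the bridge: register the two pixel
spaces per frame, carry the VIS-space segmentation into the IR frame, and
summarise temperatures over the mapped regions while removing the two
artifact classes that dominate ocular thermography, cold eyelash pixels
and blink frames.

All coordinates in the package are 0-based with `x` = column increasing
rightward, `y` = row increasing downward, and pixel centres at integer
coordinates. This convention is stated once here and enforced everywhere
(file formats, trackers, transforms).

# Registration model

The VIS-to-IR mapping is modelled as a 2-D **affine transform** (6
degrees of freedom). Affine is the weakest model determined exactly by
three point pairs, which is precisely how the per-frame transform is
estimated in the fiducial-registration protocol below; perspective
effects between two rigidly co-mounted cameras at clinical working
distances are far below the control-point noise floor, and a projective
model would no longer be identifiable from three pairs.

`estimate_affine()` interpolates exactly through three non-collinear
pairs and otherwise returns the least-squares fit (QR on the `[x y 1]`
design matrix). `register_frame()` deliberately uses *only* the three
designated pairs even when more are available, so the remaining pairs
stay untouched as held-out fiducials for error assessment.

Two ways of carrying the frame-0 control points through the sequence are
provided (`follow_cps()`):

* **static** — the frame-0 set is used for every frame. Immune to
  tracking drift; correct whenever subject motion over the (short)
  sequence is small.
* **flow** — a translational patch tracker per point: normalized
  cross-correlation of a 21 x 21 patch over integer offsets within a
  10 px search radius, refined to sub-pixel precision by a 1-D quadratic
  fit through the correlation peak along each axis (patch size and
  radius are configurable). Numerical details that matter:
  * a numerically perfect correlation peak (>= 1 - 1e-9) is *not*
    refined — for an exact integer-offset match the quadratic fit would
    only import the asymmetry of the neighbouring scores and make the
    tracker walk on a motionless scene;
  * the sub-pixel offset is clamped to half a pixel;
  * a point whose reference patch leaves the image, or whose best match
    presses against an image-clipped edge of the search window (the
    point is exiting the frame), is frozen at its last in-bounds
    location and flagged, keeping point-count invariants intact;
  * frames flagged as blinks by the landmark screen are *held*: no point
    is updated through them and the next update matches against the last
    open frame. A closed lid replaces the appearance around every
    eye-feature point at once; updating through it would teleport the
    tracks and the error would persist after the lid reopens, which is
    exactly the failure mode observed when the hold is disabled.

Masks are mapped into IR space (`map_mask()`) by pulling each IR pixel
centre back through the inverse transform and taking the label of the
nearest VIS pixel centre. Labels are categorical, so nearest-neighbour
lookup is the only admissible resampling — interpolating label values
would invent tissue classes. Nearest-neighbour rounding uses
round-half-up rather than banker's rounding so that the lookup does not
depend on coordinate parity. Out-of-source pixels map to background (0).

# Registration quality metrics

* `cp_rmse()` — root-mean-square Euclidean distance between predicted and
  ground-truth control-point positions, pooled over all frames and points
  of one image space; one number per space per scenario.
* `fre_frame()` — fiducial registration error: with eight (or more) CP
  pairs, fit the transform from the three designated pairs, push the
  held-out moving points through it, and average their distances to the
  fixed counterparts. `mean_fre()` averages per-frame FREs and reports
  the sample (n - 1) standard deviation; the SD definition is a package
  choice since only a mean +/- SD summary format is conventional.

`simulate_registration_scenarios()` reproduces, on synthetic tracks, the
qualitative quality ordering that motivates static control points and
fiducial markers (EyeTag-style skin markers near the canthi):

* *static*: frame-0 manual placement noise (default 1.5 px per
  coordinate and space, independent between spaces) held fixed — the
  inter-space inconsistency of one manual placement is the FRE floor;
* *free flow*: placement noise plus an independent Gaussian random-walk
  drift per space (default 1 px/frame), the accumulation behaviour of
  feature tracking without stable references;
* *anchored flow*: every control point on a high-contrast marker; the
  tracker locks on, modelled as zero drift with a reduced placement
  noise (default 0.3 px — markers are easier to click than diffuse eye
  features).

The simulation uses control-point geometry at 640 x 480, a realistic
camera resolution: FRE divides residuals by the conditioning of the
transform triangle, and on a toy-sized frame the triangle is so flat
that heavily drifted triples occasionally approach collinearity and the
fitted affine extrapolates wildly. The expected ordering — anchored flow
< static < free flow — is asserted by the test suite over 50 replicate
seeds of 200-frame sequences with each gap required to exceed three
Monte-Carlo standard errors; the corresponding magnitudes are recomputed
by `scripts/acceptance.R`, not quoted here.

# Eyelash artifact removal

Eyelashes crossing the ocular surface appear as markedly cooler pixels
inside the cornea/sclera ROIs. Assuming an approximately normal
temperature distribution across a ROI, `outlier_bounds()` computes
`mu +/- k sigma` and `remove_eyelashes()` drops pixels outside the
bounds. Choices that are deliberate, documented and configurable:

* **k = 2** by default (the conventional two-sided two-sigma rule);
* **sigma is the population SD** (divide by n). At ROI sizes of hundreds
  to thousands of pixels the difference from the sample SD is far below
  sensor noise; the definition is fixed so results are bit-reproducible;
* **bounds are per label**: cornea and sclera baselines differ by a
  degree or more, so pooling them would both inflate sigma and bias mu;
  a temperature typical of sclera can be an outlier within the cornea
  while being retained in the sclera;
* **pixels exactly at a bound are retained** (only pixels *outside* the
  bounds are artifacts); a uniform ROI therefore loses nothing;
* **single pass**: bounds derive from the original ROI pixels only.
  Re-running on the retained set would recompute tighter bounds and
  remove more — iterated trimming converges to a different (and not
  obviously better calibrated) estimator, and one application is the
  documented procedure. Idempotence is intentionally *not* claimed.
* ROI labels with fewer than two pixels are skipped with a warning
  (sigma is degenerate there).

Under pure Gaussian noise the rule removes a fraction of clean pixels
approaching `2 * pnorm(-2)` (about 4.55 %); the suite checks this within
+/- 0.005 on a 1e5-pixel ROI. The removed fraction is the price of the
rule, not a defect: it trims symmetric tails and leaves the ROI mean
essentially unchanged, while cold eyelash pixels sit far below the lower
bound and are removed with full recall on the phantom.

Normality of real ROI temperatures is assumed, not tested, by the
removal rule — the package applies no normality pre-test, and the
removal runs on IR-space ROIs after mask mapping (the stage order of the
pipeline).

# Blink exclusion

The Eye Aspect Ratio over six eyelid landmarks P1..P6 (P1/P4 the
horizontal corners; P2/P3 upper lid, matched by P6/P5 on the lower lid):

EAR = (|P2 - P6| + |P3 - P5|) / (2 |P1 - P4|)

is dimensionless, similarity- and reflection-invariant, and collapses
towards zero as the lid closes. Frames with EAR strictly below the
threshold (default **0.3**) are excluded; a frame exactly at the
threshold is kept ("falls below" is read strictly, and the boundary is
documented so the choice is auditable). When masks are available, a
frame whose mapped cornea label is empty is also excluded, with reason
`no_cornea` — the legacy rule kept as a backstop; the EAR reason takes
precedence when both fire. Landmarks are inputs (from the phantom or an
external detector); automatic landmark detection is out of scope.

Excluded frames are *emitted* in the profile as rows with empty
statistics and a reason, never silently dropped, so downstream
time-series analysis sees explicit gaps.

# The eye phantom

`phantom_config()` / `generate_sequence()` produce synchronized IR/VIS
sequences with complete ground truth. What it emulates — and the
defaults, chosen once as the package's study conditions:

* **geometry**: concentric ellipses in VIS space (cornea inside a
  scleral annulus); the open-eye landmark aspect gives EAR = 0.5 on a
  square frame. Simplest shape that exercises labels and landmarks;
  realism of contours is irrelevant to the statistics under test.
* **temperatures**: surface range 32–36 °C (the typical OST band); a
  smooth radial gradient (0.3 °C amplitude) from the corneal centre on
  each label — cornea about 34.8–35.1 °C, sclera about 33.0–33.3 °C —
  plus i.i.d. Gaussian noise (default sd 0.2 °C, commensurate with
  modern radiometric sensors); skin background 2 °C below the eye range.
* **cross-modality link**: a known VIS-to-IR affine (default mild
  scale/shear/offset). IR frames are rendered by pulling IR pixel
  centres back through its inverse, so the VIS frames are exactly the IR
  geometry warped by the inverse transform.
* **markers**: two high-contrast blobs just beyond the inner and outer
  canthus, the stable manual-selection aids; control points are the two
  markers plus six feature points on the mid-annulus ellipse (eight CP
  pairs, the count the FRE protocol expects).
* **eyelashes**: a fraction (default 5 %) of each ROI label's pixels set
  to the label's clean mean plus a cold offset (default -10 °C). Using
  the label mean rather than the pixel's own value makes the config
  invariant provable in closed form: the artifact value sits strictly
  below the contaminated ROI's lower 2-sigma bound whenever the fraction
  is below 0.2 and the offset magnitude is at least `4 * noise_sd + 2`.
  At a fraction of exactly 0.2 the contaminated sigma inflates to the
  point where the bound reaches the artifact value — which is why
  fractions above 0.2 are rejected outright: the "eyelashes are
  outliers" premise itself fails there.
* **blinks**: on scripted frames the eye is covered top-down by
  `closure_fraction` (default 0.85 — a partial closure, deliberately not
  total) and vertical landmark distances scale by one minus the closure,
  putting the EAR firmly below 0.3 while leaving a small corneal sliver
  visible.
* **determinism**: one integer seed feeds a single generator; identical
  configs give bit-identical sequences.

What it does **not** emulate: photorealistic appearance, camera noise
models (fixed-pattern, vignetting), radiometric calibration error,
genuine head/eye motion (sequences are static apart from blinks — drift
is simulated separately on the CP tracks by `simulate_cp_drift()`, a
per-space 2-D Gaussian random walk), and eyelashes with spatial
structure (injected pixels are scattered, real lashes are curvilinear).
Passing tests therefore demonstrate the correctness and calibration of
the algorithms under the stated statistical assumptions, not clinical
performance on real recordings.

# Pipeline and I/O conventions

`run_pipeline()` fixes the stage order: CP following, per-frame
transform, mask mapping, blink detection, eyelash removal, ROI
statistics, profile output. Blink screening (landmark-only) runs before
tracking so held frames never corrupt the tracks, and blink frames skip
all temperature stages. In static mode the whole run is a pure function
of the inputs — two runs produce byte-identical outputs.

Sequence directories hold IR frames as plain CSV matrices of °C (a
repository convention — bit depth and radiometric encoding of source
cameras vary, and °C is the quantity of interest), 8-bit PNGs for VIS
and masks, and CSV tables for landmarks and control points. Temperatures
and profile statistics are written with 4 decimals (1e-4 °C, far below
sensor noise); readers validate hard: frame-numbering gaps, IR/VIS count
mismatches and non-finite temperature cells are errors naming the
offender, and temperatures outside 15–45 °C draw a plausibility warning.
Sequences are assumed synchronized index-to-index; synchronization
itself is upstream acquisition hardware's job.

# Problem sizes in the test suite

The suite runs phantoms of 48–64 px and 1–12 frames, a 256 px frame for
the mask-overlap check (Jaccard >= 0.98 against the ground-truth cornea,
where the residual is the one-pixel boundary band between the two
admissible discretisations of the ellipse), 1e5-pixel ROIs for the
Gaussian calibration, 1000 replicates for random-walk variance and
estimator unbiasedness, and 50 seeds x 200 frames for the scenario
ordering. These sizes were chosen so every targeted property is resolved
well beyond its tolerance by construction.

# Known limitations

* The flow tracker is translational: in-patch rotation or scale change
  degrades the correlation peak. For small patches on slowly moving eyes
  this is second-order, and the study design (static CPs, markers)
  exists precisely because frame-to-frame tracking accumulates error.
* Patch tracking on raw IR frames is fragile when transient cold
  structures (eyelashes) dominate the normalized contrast; on such data
  static mode or marker-anchored tracking is the appropriate
  configuration.
* The no-cornea backstop depends on the mapped mask, so a grossly wrong
  transform can mask a detection failure as a blink exclusion.
* Excluded-frame statistics are genuinely absent (not imputed);
  consumers must handle the gaps.
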