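---
title: "Unidimensional phenotypes from concurrent plant images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unidimensional phenotypes from concurrent plant images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocur)
```

## The measurement model

`phenocur` computes descriptors from sets of concurrent images of one plant
that vary along exactly one phenotyping axis — time, viewpoint, or imaging
modality — while the other axes are held fixed. Restricting concurrency to a
single axis keeps each descriptor interpretable: a temporal descriptor can
only reflect temporal change, not view- or modality-confounded variation.

### Temporal descriptors

The substrate is a time-ordered sequence of binary masks $S_1,\dots,S_n$
(fixed camera, shared dimensions; any mismatch is an error, never an
automatic resize). For each consecutive pair,

$$\mathrm{Change}^+(t) = \max(S_{t+1}-S_t,\,0), \qquad
  \mathrm{Change}^-(t) = \max(S_t-S_{t+1},\,0),$$

elementwise. These two masks are disjoint by construction and reconstruct
the later frame exactly: $S_{t+1} = (S_t \setminus \mathrm{Change}^-) \cup
\mathrm{Change}^+$. Both identities are tested on random mask pairs.

Change masks are decomposed into 8-connected components (pixels touching by
edge *or* corner). The labeler is a depth-first flood fill in compiled code
with ids assigned in raster-scan order of each component's first pixel, so
labelings are deterministic; the test suite checks the induced partition
against an independent breadth-first flood fill written in plain R.
From the components come `NChange±` (component count), `MaxChange±`
(largest component area, 0 when the mask is empty) and

$$\mathrm{Dispersion}^+(t) = \frac{1}{|\mathrm{CC}^+(t)|}
  \sum_{i} d\!\left(c_i,\, c_{\mathrm{nn}(i)}\right),$$

the mean Euclidean distance from each component centroid to its nearest
other centroid. Centroids are unweighted means of member-pixel (row, col)
coordinates, 0-based.

Two deliberate choices here:

* **Fewer than two components leaves Dispersion⁺ missing**, not zero. A
  nearest neighbour is undefined; reporting 0 would fabricate "perfect
  clustering" and bias plant-level means downward. Missing values propagate
  as absent through aggregation.
* **Nearest-neighbour, not all-pairs, distances.** The all-pairs mean is a
  plausible alternative summary of centroid scatter, but it grows with
  component count even at fixed spatial spread; the nearest-neighbour form
  is the one implemented throughout. Ties in the nearest neighbour cannot
  affect the value (tied distances are equal), so no tie-break policy is
  needed beyond deterministic ids.

### Perspective descriptors

For $n \ge 2$ same-time side views with tight-bounding-box widths $w_i$ and
heights $h_i$: $\mathrm{TAR}_{max} = W_{max}/h$, $\mathrm{TAR}_{min} =
W_{min}/h$, $\mathrm{TWR} = W_{min}/W_{max}$. In the idealised geometry the
height is identical in every side view; real silhouettes deviate by a few
pixels through occlusion and segmentation noise. We take $h = \max_i h_i$ —
the least-occluded estimate, which collapses to the shared height exactly
when the assumption holds — and report the observed height spread per time
point as a diagnostic. Because both TAR ratios share the same $h$, the
identity $\mathrm{TWR} = \mathrm{TAR}_{min}/\mathrm{TAR}_{max}$ holds to
floating-point precision and is asserted in the tests.

An empty silhouette in any view aborts that time point (recorded missing):
a zero ratio would be an arbitrary number, not a measurement. The
single-view baseline aspect ratio is height/width, the orientation under
which vertically dominant plants exceed 1.

### Modality descriptors

Two modality images of the same scene are cropped to their plant bounding
boxes, and both crops are resampled — bilinear interpolation via
`EBImage::resize` — to the dimensions of the smaller crop (the
lower-resolution modality). Resampled foreground masks are re-binarized at
0.5. No registration is performed: the platform geometry aligns the plant
across modalities, and alignment here is purely scale-based. Paired
intensities are read over the overlap of the two aligned masks
(overlap-only is the default; the modality foreground is intensity > 0
after ITU-R BT.601 luminance conversion of RGB input, threshold
configurable).

* **IC** is standard Pearson correlation $s_{xy}/(s_x s_y)$ with sample
  standard deviations. A constant channel leaves it undefined: the series
  reports `NA` for that time point rather than 0.
* **IMI** is $H(X)+H(Y)-H(X,Y)$ in bits. Histograms use 64 fixed
  equal-width bins covering the full 8-bit range — the width-4 intervals
  $[0,4),\dots,[252,256)$ — regardless of the observed intensity range, so
  entropies are comparable across time points; a uniform 0–255 image gives
  exactly $\log_2 64 = 6$ bits. $0\log 0$ is taken as 0, and all three
  entropies use the same binning, which guarantees $0 \le \mathrm{IMI} \le
  \min(H(X),H(Y))$ up to rounding.

The histogram MI estimator has the classic positive small-sample bias,
approximately $(B_x-1)(B_y-1)/(2n\ln 2)$ bits for independent channels —
about 0.29 bits at $n = 10^4$ overlap pixels with $64\times64$ bins. The
suite checks the implied behaviour (estimates for planted-independent
images decrease toward 0 as overlap grows) rather than pretending the bias
away; users comparing IMI across groups should keep overlap sizes
comparable, which the shared-bounding-box protocol does naturally.

## Group comparison protocol

The unit of biological replication is the plant. Each phenotype series is
collapsed to a per-plant temporal mean (missing values excluded from
numerator and denominator; an all-missing plant drops out with a warning),
and treatments are compared within species by Welch's unequal-variance
two-sample t-test with Welch–Satterthwaite degrees of freedom and two-sided
p-values. The implementation delegates to `stats::t.test(var.equal =
FALSE)`; the tests verify t, df and p against the closed-form Welch
formulas to 1e-9. Two degenerate conventions: two zero-variance groups with
equal means give $t = 0, p = 1$; with different means the statistic is
undefined and the comparison errors out rather than inventing a value. No
multiple-testing correction is applied — none is part of the protocol — but
the comparison reports how many tests were run so users can apply their
own.

Time points are never treated as independent replicates: aggregate first,
test second. This is a conservative design; transient treatment effects
that cancel over the season are attenuated, which is a property of the
protocol, not a bug in the code.

## The synthetic scene generator

The generator exists so that every descriptor has a planted, exactly known
truth. What it emulates, and how:

* **Temporal scenes** start from a static central blob (default 120 px in
  an 80×80 frame) and, between consecutive frames, add growth components
  and remove previously planted components whole. Every planted component
  keeps a ≥ 2-pixel Chebyshev gap from all other material — 8-connectivity
  can then never merge components, so planted counts, areas and centroids
  are recovered *exactly* (integer equality, asserted in the tests), and
  occupancy during placement includes just-removed pixels so a growth event
  can never cancel part of a decay event. Placement retries up to 500
  random anchors and then raises a placement error rather than degrading
  the guarantee.
* **Cohorts** default to 8 plants per treatment with 8 time points each,
  1–4 growth events per step with areas uniform on 15–45 px and 0–2 decay
  events — sizes chosen to mimic a modest greenhouse trial (6–8 replicates
  per condition, one to two weeks of daily imaging) at desk scale. Each
  plant's seed derives from a stable hash of its label folded with the
  cohort seed, so plants are independent replicates and cohorts are
  bit-reproducible. The drought treatment applies a planted suppression
  factor to growth-event areas (and the base blob); `suppression = 1`
  plants a true null.
* **View scenes** render each view as a solid rectangle with prescribed
  width and shared height, so bounding boxes recover the planted extents
  exactly.
* **Modality pairs** draw latent bivariate standard normal pairs with the
  target correlation over a shared disk foreground and map each channel
  through the normal CDF onto intensities 1–255 (background 0). The rank
  transform attenuates Pearson correlation slightly — $\frac{6}{\pi}
  \arcsin(\rho/2) \approx 0.786$ for a planted 0.8 — which, with quantization,
  motivates the ±0.05 recovery tolerance at ≥ 2000 overlap pixels. The
  degenerate couplings ±1 bypass sampling so downstream IC is exactly ±1.

What the phantoms do **not** emulate: real canopy texture, occlusion-driven
apparent decay, view-dependent self-shading, illumination drift, or
segmentation error. Passing tests therefore demonstrate that the
*computational pipeline* is exact and well calibrated on known ground
truth — they do not validate the biological interpretation of any
descriptor on real plants.

## Validation sizes and calibration

The suite and the acceptance script use problem sizes chosen to exercise
every code path at desk scale: 200 random 32×32 masks against the
flood-fill oracle, 200 random change-mask pairs for the conservation
identities, 20 scenes planting 1–10 components per step, 100 random view
sets, 20 seeds per planted correlation level, 100 random Welch cases
against the closed form, and 50 end-to-end cohorts each for null
calibration and for power under 0.3× suppression. With 8 vs 8 plants and a
0.3 suppression the planted effect on positive-change area is roughly ten
standard errors wide, so near-total rejection at α = 0.01 is the expected
outcome; under the null, the 50-cohort Kolmogorov–Smirnov distance to
uniformity sits near its n = 50 sampling scale (95th percentile ≈ 0.19),
so values around 0.1–0.2 indicate calibration, not miscalibration.

## Known limitations

* Decay and occlusion are indistinguishable in change masks by design;
  `Change⁻` conflates them.
* Dispersion⁺ is defined for the positive mask only; no negative-mask
  analogue is computed.
* The temporal pipeline reads one view (default 0°, configurable); it does
  not fuse views.
* IC/IMI depend on the foreground threshold when modality masks are not
  supplied; the default (intensity > 0) suits dark-background platform
  imagery.
* The manifest/directory reader handles PNG masks and single- or
  three-channel PNG modality images only.
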