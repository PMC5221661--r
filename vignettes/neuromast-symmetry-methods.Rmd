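---
title: "Methods: quantifying bilateral symmetry of cranial neuromast patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying bilateral symmetry of cranial neuromast patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromastsym)
```

## The problem

Superficial neuromasts — the mechanosensory organs of the fish lateral line —
form species- and population-characteristic patterns on the head. Comparing
the left and right sides of one individual gives a readout of developmental
precision: a perfectly symmetric animal would carry mirror-image patterns,
and the departure from that mirror relationship (fluctuating asymmetry)
carries biological signal. This is of particular interest in *Astyanax
mexicanus*, where independently derived cave populations show pronounced
cranial asymmetries relative to surface populations.

The protocol this package automates was originally manual: mark each
neuromast with a small dot, mirror one side, overlay the two dot fields using
the large canal neuromasts as orientation landmarks, nudge to the best visual
fit, erase the background, and score the two dot masks with a pixel-wise
Pearson correlation in a colocalization tool. The whole alignment is repeated
three times and the three R values averaged. Every stage of that protocol is
reproduced here as seeded, testable code.

## The symmetry index

For one individual with left pattern $L$ and right pattern $R$ (2-D point
sets with `superficial` and `canal` type labels):

1. **Mirror.** $R$ is reflected within its frame. The default is the
   left-right mirror $(x, y) \mapsto (w - x, y)$: overlaying contralateral
   lateral views requires a horizontal flip of the image content. The
   literal top-bottom flip is selectable (`axis = "horizontal_line"`),
   because the verbal description of a "180° flip across the horizontal
   axis" is ambiguous between the two.
2. **Landmark registration.** A closed-form least-squares rigid fit
   (centroid alignment + SVD of the cross-covariance, determinant-corrected
   so no additional reflection can enter) maps the mirrored right canal
   neuromasts onto the left ones. Canal points are used only here; they
   never enter the score. If no explicit correspondence is given, canal
   points are paired by rank order along the anteroposterior (x) axis.
   Uniform scaling is off by default (two sides of one specimen at one
   magnification are rigidly related) and available via `allow_scale`.
3. **Triplicate refinement.** Three independent "alignment attempts" start
   from the landmark fit perturbed by seeded Gaussian jitter (default SD 2
   px in translation and 2° in rotation about the pattern centroid),
   standing in for inter-attempt operator variability. Each attempt is
   refined by a score-maximizing local search (below) and contributes one R;
   the symmetry index is their mean.
4. **Rasterize and score.** Superficial points only are drawn as filled
   circles of `dot_radius` (default 3 px) on a shared blank canvas, and R is
   the Pearson product-moment correlation over *all* canvas pixels. For
   binary masks with on-fractions $p_A$, $p_B$ and joint on-fraction
   $p_{AB}$,
   $$R = \frac{p_{AB} - p_A p_B}{\sqrt{p_A(1-p_A)\,p_B(1-p_B)}},$$
   identically equal to the correlation of the two 0/1 pixel arrays.

Exact coincidence of the two dot masks gives $R = 1$; two disjoint masks on
a shared canvas give a small negative value.

### The refinement is a trust-region search — and why

The raster score is piecewise constant in the transform parameters, so naive
grid descent can neither reach the exact optimum nor terminate at it. The
refinement therefore runs two score-gated phases:

* **ICP polish.** Each transformed moving point is matched to its nearest
  fixed point and the closed-form fit is recomputed from those
  correspondences; the candidate is accepted only if the colocalization
  score does not decrease. For clean data this lands exactly on the optimum
  (which is how a perfect mirror scores 1.0 to machine precision).
* **Coordinate descent** over rotation (about the moving centroid) and
  translation, coarse-to-fine with step halving down to 0.25 px / 0.25°.

Both phases are confined to a trust region around the *canal-anchored
landmark fit* (radius $3\sigma_{\text{jitter}} + 1$ px and degrees). This is
deliberate: the manual protocol uses canal neuromasts as place markers and
only nudges the overlay locally, whereas an unbounded maximization of dot
overlap inflates the score of genuinely asymmetric patterns by overfitting
the alignment — in simulation the unbounded variant cannot score below
about 0.09 even for completely decorrelated sides, while the trust-region
variant decays toward its disjoint-mask baseline near 0.05.

### Canvas dependence

Because R is computed over every canvas pixel, its absolute value depends on
the canvas: more background pixels shrink $p_A$, $p_B$ and move the
disjoint-mask baseline. The default canvas is the union bounding box of both
superficial dot sets plus `dot_radius` padding (plus a jitter margin during
registration), and the canvas is echoed into every result file. Absolute R
values are therefore comparable *within* a consistent configuration, not
across arbitrary canvas choices — one reason published per-individual values
from other toolchains cannot be reproduced exactly without the original
image geometry.

### Numerical conventions

* Coordinates are 0-based, origin at the top-left pixel corner, x rightward,
  y downward. Rasterization samples the integer lattice: canvas pixel
  (row $i$, col $j$) sits at $(x_0 + j - 1,\; y_0 + i - 1)$, so a point at
  integer coordinates with `dot_radius = 2` turns on exactly 13 pixels.
* A pixel on the exact circle boundary counts as on, with a $10^{-7}$
  tolerance on the squared distance so membership cannot flip under
  $10^{-12}$-scale numerical noise in a registered coordinate.
* Points on a polygon edge count as inside (ROI counts are reproducible).
* Transforms are stored origin-centred as $x' = s\,R(\theta)\,M\,x + t$
  (mirror, then scale-rotation, then translation); composition and inversion
  are exact, and the landmark fit forbids $\det < 0$.
* Ties in the score during refinement are broken toward the incumbent, so
  refinement is deterministic and terminates.

## ROI morphometry

Regions of interest (the facial "Crescent" field, the third suborbital bone
SO3 and its fragments) are user-supplied polygons. Areas use the shoelace
formula, converted to mm² through the squared pixel scale; neuromast counts
use edge-inclusive ray casting; SO3 rows also report the number of
same-side fragment polygons. Overlapping ROIs are measured independently — a
point may legitimately count in both the Crescent and SO3 regions.
Left-right difference tables report signed and absolute differences without
attaching any statistical claim.

## Cohort statistics

Per-individual mean R values are compared across populations with a one-way
fixed-effects ANOVA ($SSB = \sum_i n_i(\bar x_i - \bar x)^2$,
$SSW = \sum_i (n_i - 1) s_i^2$), followed by post hoc two-sided
pooled-variance Student's t-tests on all pairs. Choices made where the
protocol is silent:

* Student's (pooled) t is the default because that is the named test; Welch
  is available behind `welch = TRUE`.
* No multiple-testing correction by default (none was reported);
  Bonferroni is available. This is stated prominently because six pairwise
  tests at $\alpha = 0.05$ carry a ~26% familywise error rate.
* Sample SDs use the $n - 1$ denominator.
* The one-way F depends on the data only through per-group (mean, sd, n),
  so `anova_summary()` reproduces `anova_raw()` exactly from summary tables;
  this identity is tested to $10^{-10}$.

Worth recording: the four-population summary table that ships as the default
cohort template (means 0.082/0.059/0.054/0.047, SDs 0.024/0.014/0.015/0.012,
$n = 30$ each) yields $F(3,116) \approx 24.15$, but under a pooled t-test
its two most different cave populations differ significantly
($t \approx 3.56$, $p \approx 7\times10^{-4}$). A "no cave-cave difference"
outcome is therefore *not* implied by those printed moments alone; in the
synthetic cohorts below it emerges only because the generative pipeline's
realized within-group spread exceeds the printed SDs.

## The synthetic world

The generator emulates the pipeline's inputs with known ground truth:

* **Template.** `n_superficial = 25` superficial points and `n_canal = 6`
  canal landmarks placed uniformly (minimum spacing 8 px) in a facial
  region polygon inside a 240 × 180 px frame at 0.01 mm/px — a realistic
  head-field size, landmark count and magnification for a juvenile tetra.
* **Asymmetry.** Each side observes the template (right side mirrored)
  through independent Gaussian jitter of SD $\sigma$; the right side may
  additionally lose points (dropout), gain unilateral extras (Poisson), and
  receive a random acquisition misalignment. $\sigma$ is the calibrated
  knob; dropout/gain/misalignment default to zero.
* **Images.** Spots render as isotropic Gaussians (amplitude 100,
  background, seeded read noise); SNR 10 means amplitude / noise SD = 10.
* **Cohorts.** A calibration curve $E[\text{mean R}](\sigma)$ is estimated
  by Monte-Carlo on a geometric $\sigma$ grid (0–64 px), isotonically
  projected, and inverted in log-log space (the curve decays approximately
  as a power law, making log-log interpolation nearly exact). Per-individual
  target scores are drawn from a normal whose variance is the target
  variance minus the pipeline's own between-replicate variance (clamped at
  zero), mapped through the inverse curve, and every individual then runs
  the full generate-and-score pipeline. Realized moments are reported next
  to targets.

What the generator does *not* emulate: clustering of real neuromasts along
canal lines, bone-growth-coupled repositioning, type misclassification, and
image segmentation error. A green cohort test therefore establishes that the
pipeline behaves correctly under the stated generative model — not that the
model captures every feature of real micrographs. Note also that the lowest
default cohort target (0.047) sits essentially at the generator's asymptotic
score floor (~0.05): realized means for that population land at the floor,
within the stated ±0.01 tolerance of the target.

## Known limitations

* Absolute R values are canvas- and dot-radius-dependent (see above);
  published values from other toolchains are reproducible only in range and
  ordering, not numerically.
* Rigid (optionally similarity) registration only; no deformable model.
* Spot detection does not classify canal vs superficial neuromasts — type
  labels come from the input table.
* Invariance of the index under a global rigid motion of both sides is
  exact for integer translations; rotations re-rasterize the dot masks and
  perturb R at the pixel-quantization level (the perfect-mirror case stays
  at 1.0 under any rigid motion).
* Image I/O is plain-text (ASCII PGM / CSV); binary TIFF/PNG ingestion is
  out of scope in this environment.
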