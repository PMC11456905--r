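---
title: "Functional-liver-sparing SABR planning: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-liver-sparing SABR planning: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverspare)
```

## The problem

Radiation-induced liver disease is the dose-limiting toxicity of liver
SABR, and the conventional safeguard — capping the mean dose to
liver-minus-GTV — treats the organ as functionally homogeneous. Real
livers are not: fibroinflammation, steatosis and prior chemotherapy leave
a patchwork of well- and poorly-functioning parenchyma. Iron-corrected T1
(cT1) mapping is a contrast-free quantitative MR technique whose values
rise with fibroinflammation, so low-cT1 tissue can serve as a surrogate
map of the *functional liver volume* (FLV). If the FLV can be segmented
reliably, the fluence optimiser can be asked to steer dose away from it —
trading dose into already-compromised tissue — without loosening target
coverage or organ-at-risk limits.

`liverspare` implements that whole chain as testable code, exercised
entirely on synthetic phantoms: phantom generation, FLV segmentation,
bulk-density pseudo-CT, a pencil-beam dose-influence matrix, fluence
optimisation with and without a parallel-organ FLV objective, DVH metric
extraction, and exact paired signed-rank comparison of the two plan arms.
Because no patient data are involved, every stage can be validated
against brute-force oracles, and the planning comparison becomes a
property of the method rather than an anecdote.

## The synthetic patient

`phantom_config()` / `generate_patient()` produce one seeded patient:

* **Grid.** Default 160 × 160 × 24 voxels at 1.1 × 1.1 × 8 mm — the
  in-plane resolution and slice thickness of an axial quantitative-MR
  liver stack.
* **Anatomy.** Ellipsoids and tubes: body, liver (~1200 cc), a spherical
  GTV placed reproducibly inside the margin-eroded liver, two lungs,
  a vertebral column with a spinal-canal tube, and a bowel-like
  structure. Organ-shape realism is a non-goal; what matters is that the
  geometry exercises density overrides, margins and dose trade-offs.
* **cT1 texture.** A spatially correlated Gaussian field
  (`make_correlated_field()`: white noise smoothed at the configured
  correlation length, default 25 mm, then standardised) is thresholded at
  its empirical quantile so that a chosen fraction of liver-in-FOV voxels
  is "functional". Functional voxels draw cT1 from a normal distribution
  centred at 700 ms, non-functional at 950 ms (40 ms spread), each
  truncated at the 800 ms threshold. The truncation makes the realised
  functional fraction equal the target up to quantile resolution, which
  turns the generator's main covariate into something a test can pin
  down exactly; the cost is a density discontinuity at 800 ms that real
  livers do not have.
* **Field of view.** The cT1 acquisition often does not cover the whole
  liver, so whole axial slices are removed from the superior end until
  the configured fraction of liver-bearing slices remains; superior
  coverage is what real acquisitions lose first.

What the phantom deliberately does **not** emulate: MR acquisition
physics (MOLLI, T2*, GRAPPA), registration error between the cT1 and
anatomical frames, respiratory motion, and within-patient cT1 gradients
beyond the two-component mixture. Tests passing on these phantoms show
the pipeline's mechanics are correct; they say nothing about cT1's
biological validity as a function marker.

## FLV segmentation

`segment_flv()` runs, in order: in-plane block-mean downsampling by 2
(1.1 mm → 2.2 mm; slices untouched), cropping to the bounding box of
liver∩FOV (the ROI is carried to the working grid by block majority),
strict thresholding at cT1 < 800 ms, then Gaussian smoothing of the
binary mask followed by re-thresholding at a median. The result is
mapped back to the acquisition grid by block replication and intersected
with liver∩FOV, and can be moved to the planning grid by
nearest-neighbour resampling so it stays binary.

Conventions that needed a decision:

* **σ units.** The smoothing width is 4 *voxels of the working grid* by
  default, applied in-plane only — the filter's job is to suppress
  grid-scale speckle so the optimiser cannot chase single-voxel islands,
  and that scale is a property of the grid, not of anatomy. Setting
  `sigma_units = "mm"` switches to an isotropic physical width applied
  along all three axes.
* **Scope-normalised smoothing.** The mask is smoothed as
  `G∗mask / G∗roi` (zero-padded truncated-kernel convolution in both
  numerator and denominator), i.e. a local functional *fraction*. A mask
  that fills the whole ROI is exactly 1 everywhere inside it, so the
  degenerate all-functional case reproduces liver∩FOV identically rather
  than being eroded by boundary effects.
* **Median scope.** "Threshold at the median" needs a voxel set. Taking
  the median over all ROI voxels fails outright (it is 0 whenever under
  half the ROI is functional, so nothing is removed). Taking it over
  voxels with strictly positive smoothed value fails more subtly: a
  truncated Gaussian at 6σ paints an enormous near-zero halo, the halo
  dominates that median, and a 3 mm speck *survives* — the opposite of
  the filter's purpose — while the kept region saturates near half the
  ROI regardless of how much tissue is functional. The default is
  therefore the median over the *raw thresholded mask* voxels: the cut
  then compares each region's smoothed support against the bulk of the
  functional tissue, removes small isolated regions exactly, and tracks
  the underlying functional fraction monotonically. Both alternatives
  remain selectable via `median_scope` for sensitivity analysis.
* **Keep `>=`, not `>`.** Ties at the median keep the all-functional
  case equal to the full ROI.
* **Mask vs image smoothing.** The binary mask is smoothed, not the cT1
  map; `smooth_target = "image"` provides the other reading.

On grids up to 32³ the entire chain is verified voxel-for-voxel against
a dense implementation built from explicit block means, shift-and-add
convolution with the truncated kernel, and an explicit median.

## Pseudo-CT and dose engine

Dose calculation on MR uses bulk relative electron density (rED)
overrides: lungs 0.328, vertebrae 1.153, everything else in the body
0.988, air 0. Overlaps resolve by priority (vertebrae, then lung, then
generic tissue) — specific structures beat the generic remainder.

The dose engine is a deliberately simple, linear, density-aware pencil
beam. Twelve equispaced parallel-ray beams span the gantry arc from 168°
to 24° through posterior — the arc that keeps entrance dose off
contralateral organs. For beamlet *b* (5 mm grid over the target's
transverse projection plus a 10 mm margin) and voxel *v*:

$$D_{vb} = \exp(-\mu_{\mathrm{eff}}\, d_{\mathrm{rad}}(v, \mathrm{beam}_b))
  \cdot \exp\!\left(-\tfrac{r_{vb}^2}{2\sigma_\ell^2}\right)$$

with radiological depth \(d_{\mathrm{rad}}\) computed by exact
voxel-traversal ray tracing through the rED map (compiled code), lateral
distance \(r\) from the beamlet axis, and defaults
\(\mu_{\mathrm{eff}} = 0.005\,\mathrm{mm}^{-1}\),
\(\sigma_\ell = 3\) mm. Entries below \(10^{-4}\) of their column maximum
are truncated to keep the matrix sparse. These kernel constants are toy
values: the package's scientific claims are *relative* comparisons of two
plans computed with the identical engine, which survive any reasonable
kernel. Scatter, beam divergence, deliverability and magnetic-field
effects are out of scope.

## Plan optimisation

The composite objective is a weighted sum of one-sided quadratic
penalties — PTV underdose below the prescription, PTV overdose above
1.25 × prescription, organ-at-risk excesses above their `mean` or
`max_dvh_cc` levels, and liver-minus-GTV mean above the tier cap — plus,
in the sparing arm, a parallel-organ term on the FLV:

$$\mathrm{damage}(d) = \frac{1}{n}\sum_v \frac{1}{1 + (d_\mathrm{ref}/d_v)^k},
\qquad d_\mathrm{ref} = 15\ \mathrm{Gy},\ k = 3.$$

Each voxel's response is logistic in log-dose, 0.5 at the reference
dose, so the gradient is spread across the whole dose range: the
optimiser gains as much from shaving low dose off a large volume as high
dose off a small one, which is what a parallel-architecture organ model
should reward. The concrete functional form and its defaults are this
package's instantiation — commercial systems do not publish theirs — and
all three constants are configurable.

The solver is projected gradient descent on non-negative fluence with a
Barzilai-Borwein step proposal and backtracking that only ever accepts a
decrease, so the objective trace is non-increasing by construction and
the whole procedure is deterministic for a fixed initial fluence
(uniform 1 by default). A zero-weight parallel term takes a code path
identical to the standard objective, making the standard/sparing pair
exactly comparable.

Around the solver sit three clinical conventions:

* **Margins.** PTV = GTV + 5 mm, PRV = OAR + 5 mm, isotropic Euclidean
  dilations.
* **Prescription tiers.** Plans are attempted from the highest
  prescription down, keeping the first whose achieved liver-minus-GTV
  mean meets that tier's cap; defaults (50 Gy under 13 Gy, else 40 Gy
  under 15 Gy) are stand-ins for a five-fraction protocol whose exact
  tables are not public, and are fully overridable.
* **Sparing weight titration.** `auto_sparing_weight()` raises the FLV
  weight over a geometric ladder (×2 per rung from 50) and keeps the
  last plan whose PTV D95 stays at or above the optimal tolerance
  (default 95 % of prescription), mimicking a planner tightening the
  constraint until coverage starts to give. If even the first rung
  fails, the standard plan is returned flagged.

For the matched-coverage check, the standard plan is rescaled by a
single factor so its PTV D95 equals the sparing plan's; by linearity of
dose in fluence, every DVH metric scales with it.

## Metrics and statistics

D*p*% is computed on sorted voxel doses (no binning): the observed dose
at the lower (1 − *p*/100) quantile position, so D100 % is the minimum
voxel dose and the D95 % of a uniform dose is that dose. D*y*cc
interpolates the cumulative-volume curve linearly between sorted voxels.
V10Gy is emitted in both directions (volume at-or-above and volume
below) because the liver criterion in UK SABR practice is a *minimum*
volume below threshold; which direction a protocol reads is
configuration, not code. The functional ratio is rounded half away from
zero to an integer percent.

The paired Wilcoxon signed-rank test drops zero differences, midranks
ties, and for n ≤ 20 computes the two-sided p from the exact null over
all 2ⁿ sign assignments (evaluated by the generating-function recursion,
which enumerates the same distribution) as
2 · min(P(W ≤ w), P(W ≥ w)) capped at 1 — with ten uniformly improved
patients this floors at 2/2¹⁰ = 0.00195…, printed as 0.0020. Above
n = 20 a tie-corrected normal approximation is used and flagged. No
multiplicity correction is applied; each metric is tested at α = 0.05 on
its own.

## Problem sizes and numerical choices

The shipped tests and the cohort study run at sizes chosen to keep a
full check of every property comfortable on a single CPU: phantoms of
160 × 160 × 24 voxels, a 64 × 64 × 24 planning grid, 10 patients with
functional-fraction targets spread over 0.2-0.85 (the range of
functional ratios a mixed metastasis/HCC cohort shows), solver budget
100 iterations at relative tolerance 10⁻⁷. Oracle-equivalence checks use
32³ grids where dense convolution is exact and fast. Degenerate inputs
are pinned by tests: empty masks error or propagate emptiness, an
all-800 ms map segments to nothing (the threshold is strict), zero
fluence gives zero dose, an all-zero difference vector returns p = 1
with a degeneracy flag.

## Known limitations

* The FLV ratio produced by median re-thresholding on these smooth
  synthetic textures underestimates the generator's functional fraction
  (roughly halving it); real cT1 maps, with organ-scale solid regions,
  sit closer to the raw thresholded volume. The ratio column of the
  cohort table should be read with that in mind.
* The pencil-beam kernel has no scatter or build-up; absolute doses are
  not clinically meaningful, only paired comparisons are.
* Prescription tiers and dosimetric criteria are configurable stand-ins,
  not a published protocol.
* The parallel-damage form is one reasonable choice in a family; results
  that depend on its curvature (rather than its monotonicity) should be
  re-checked under other `d_ref_gy` / `k_power` settings.
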