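# liverspare

Functional-liver-sparing SABR planning from contrast-free quantitative T1
maps, as a fully synthetic, fully testable R pipeline.

## The problem

Stereotactic ablative body radiotherapy (SABR) of liver tumours is limited
by radiation-induced liver disease, conventionally managed by capping the
mean dose to liver-minus-GTV as if liver function were spatially uniform.
It is not. Iron-corrected T1 (cT1) mapping is a contrast-free quantitative
MR biomarker of fibroinflammation: tissue with cT1 below ~800 ms can be
read as *functional liver volume* (FLV), and the fluence optimiser can be
asked to push dose out of it — into already-compromised tissue — without
loosening target coverage or organ-at-risk constraints.

`liverspare` implements that workflow end to end on seeded synthetic
phantoms, so every stage is verifiable without patient data:

1. **phantom** — seeded patients: correlated cT1 texture with a
   controllable functional fraction, liver/GTV/OAR/lung/vertebrae masks,
   and a cT1 field of view that truncates the superior liver;
2. **segmentation** — the FLV chain: in-plane downsampling (1.1 → 2.2 mm),
   crop to liver∩FOV, strict cT1 < 800 ms threshold, Gaussian smoothing
   (σ = 4 voxels) with median re-thresholding to remove small regions;
3. **pseudoct** — bulk electron-density overrides (lung 0.328,
   vertebrae 1.153, tissue 0.988 rED) for dose calculation on MR;
4. **dose** — a sparse pencil-beam dose-influence matrix over twelve
   equispaced beams on the 168°→24° posterior gantry arc, with exact
   voxel-traversal radiological depth (compiled ray tracer):
   `D[v,b] = exp(−μ·d_rad) · exp(−r² / 2σ²)`;
5. **optimize** — projected-gradient fluence optimisation of one-sided
   quadratic objectives, a prescription-tier ladder capped by liver mean
   dose, and a *parallel-organ* FLV objective
   `mean_v 1 / (1 + (d_ref/d_v)^k)` whose weight is titrated upward until
   PTV D95 would fall below tolerance;
6. **metrics** — DVHs and the dosimetric panel (D95 %, D99 %, D0.03cc,
   D0.5cc, mean dose, V10Gy in both directions, Table-1-style volume
   bookkeeping);
7. **stats** — exact paired Wilcoxon signed-rank tests (full 2ⁿ null for
   n ≤ 20) and median (IQR) cohort summaries;
8. **cohort orchestration** — `run_cohort()` runs
   simulate → segment → pseudo-CT → plan(standard) → plan(sparing) →
   metrics → compare for an n-patient cohort, reproducibly from one seed.

## Worked example

```r
library(liverspare)

pat <- generate_patient(phantom_config(seed = 1, functional_fraction_target = 0.5))
pat
#> <synthetic_patient> seed 1
#>   liver 1203 cc, GTV 13.7 cc, liver-in-FOV 1041 cc
#>   realised functional fraction 0.500 (target 0.50)

segment_flv(pat$ct1_map, pat$structures$masks$liver, pat$structures$masks$fov)
#> <flv_result>
#>   liver-in-FOV 1040.9 cc; raw threshold 511.6 cc; FLV 255.9 cc (25% of ROI)
```

Half the liver-in-FOV is functional by construction; thresholding
recovers 511.6 cc of it and the smoothing/median step keeps the 255.9 cc
that forms contiguous functional tissue (the median cut erodes region
rims and speckle — see the methods vignette for why and by how much).

A small cohort comparison (three phantoms, coarse grids; the defaults run
ten phantoms at full size):

```r
cfg <- run_config(n_patients = 3,
                  phantom = phantom_config(grid_shape = c(96, 96, 16),
                                           spacing_mm = c(2.2, 2.2, 8),
                                           gtv_radius_mm = 12),
                  planning_shape = c(32, 32, 16))
res <- run_cohort(cfg)
res
#> <liverspare_cohort> 3 patients (config 49113963)
#>   functional ratios 10-41%; sparing applied for 3/3 patients
#>   FLV mean dose: standard 14.04 Gy vs sparing 7.37 Gy (p = 0.25), mean reduction 7.19 Gy
```

Every patient's FLV-sparing plan lowered the FLV mean dose while PTV D95
stayed at or above the 95 % optimal tolerance; with three patients the
exact two-sided signed-rank p cannot go below 2/2³ = 0.25, which is what
the report shows. `res$table1` holds the per-patient volume bookkeeping
(liver, GTV, liver-in-FOV, FLV, ratio, prescription) and `res$report` the
per-metric median (IQR) of both arms with exact p-values; with the
default ten-patient cohort a uniform improvement floors the FLV p-value
at 2/2¹⁰ = 0.0020.

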