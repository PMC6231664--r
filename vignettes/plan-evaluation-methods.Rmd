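---
title: "Methods: DVH analysis, radiobiological scoring and cohort comparison of plan variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DVH analysis, radiobiological scoring and cohort comparison of plan variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmatqa)
```

## The problem

When a treatment planning system recalculates the same prostate VMAT plan
with a different dose-calculation algorithm or a different calculation grid,
the plan itself (fields, MU, anatomy) is unchanged — only the *predicted*
dose distribution moves. The clinically interesting question is whether the
movement is large enough to change plan-quality conclusions: target
coverage, dose homogeneity and conformity, organ-at-risk load, and the
derived tumor control / complication probabilities. This package implements
that evaluation pipeline for cohorts of patients, each carrying one plan per
(algorithm, grid) variant, with a paired nonparametric comparison across
variants.

The setting it is tuned for is a 78 Gy / 39-fraction prostate VMAT cohort
with an endorectal balloon: the balloon inflates the rectum with ~70 cm³ of
air, and the air cavity (partially overlapping the PTV margin) is exactly
where convolution/superposition-type algorithms ("AAA-like") and Boltzmann
transport solvers ("AXB-like") disagree most.

## DVH model and conventions

A cumulative DVH is stored as dose points (Gy, strictly increasing from 0)
with volume fractions (starting at 1, non-increasing); the absolute
structure volume in cm³ travels alongside. All queries — D_x, V_x%, the
summary doses — interpolate the cumulative curve piecewise-linearly, and
ties on flat segments resolve to the lowest dose. Two ends need a
convention, since exported DVHs rarely state one:

* **minimum dose** = the highest dose still covering the full structure
  (the last point with fraction 1); `dose_at_volume(cdvh, 1)` follows the
  same convention;
* **maximum dose** = the lowest dose at which the covered fraction reaches
  zero (the curve end if it never does).

The **mean dose** is computed as the exact trapezoidal integral of the
cumulative curve. This is the zero-bin-width limit of the differential-DVH
sum Σ vᵢDᵢ; using the integral instead of a binned sum removes a half-bin
bias (point masses at 60/80 Gy average to 70.000, not 70.025).

Differential DVHs use arithmetic bin midpoints, with the drop of the
cumulative fraction across the bin as the bin mass; residual volume above
the curve end goes to the terminal bin, so masses always sum to 1. The
inverse conversion treats bin mass as concentrated at the centers (tail-sum
staircase); because dose points must be strictly increasing, each staircase
drop is represented by a 10⁻⁹ Gy segment. Round trips agree at every bin
edge to 10⁻⁹. One consequence worth knowing: the median of a two-point mass
distribution sits at the lower mass point under the ties-to-lowest rule
(any value between the two points is a valid median).

The default differential bin width is 0.1 Gy. For smooth, clinically-shaped
curves EUD is stable to < 0.1 % under halving the bin width (asserted by
test). The stability claim deliberately excludes curves with mass at
near-zero dose: with a negative volume-effect exponent the EUD is
*physically* dominated by the coldest subvolume, and no binning makes that
insensitive.

## Target indices and the deviation score

HI = (D2 − D98)/D50, CI = V_RI/TV and CN = (TV_RI/TV)·(TV_RI/V_RI) are
computed from the PTV curve plus a body-contour DVH (or a directly supplied
reference-isodose volume, e.g. from a dose grid). The reference isodose
level defaults to 95 % of prescription: the planning aim in this setting is
to cover 95 % of the PTV with 95 % of the prescription dose, and typical CI
values near 1.0–1.1 are consistent with that level. CI returns 0 for an
empty reference isodose, while CN rejects it — the first is a legitimate
"no coverage" score, the second is 0/0.

Plan variants are scored against a reference variant by
|Ref − Eval|/Ref × 100 on the cohort-mean summary doses. The default
reference is the Boltzmann-type algorithm at the finest grid — the
combination with the best a-priori accuracy claim — and is configurable. If
a reference cohort mean is exactly zero the deviation is reported as 0 when
the evaluated mean is also zero (the plans agree) and NA otherwise.

## Radiobiological model

EUD is the generalized (power) mean (Σ vᵢDᵢᵃ)^(1/a), computed max-scaled
for numerical stability and verified against a naive power-sum oracle to
10⁻¹⁰ relative error. `a` is the volume-effect exponent: large positive for
serial organs (rectum 8.33, femoral heads 13), small positive for parallel
ones (bladder 2), negative for tumors (prostate −13), where cold spots
dominate. A zero-dose bin with genuine mass under a < 0 is rejected rather
than clamped: a truly unirradiated tumor subvolume means TCP = 0, and
silently hiding it would mask data problems. Bins carrying < 10⁻⁹ of the
volume are dropped first, so empty histogram bins are harmless. a = 0 (the
geometric-mean limit) is excluded; no shipped parameter set uses it.

TCP and NTCP are logistic sigmoids in EUD with half-point TCD50/TD50 and
slope γ50 (the normalized slope at the half point — checked analytically in
the tests). The shipped registry is a literature five-organ prostate set;
it round-trips through plain CSV so users can substitute their own.

**EQD2 before EUD.** The registry carries α/β values, and the package
applies the linear-quadratic EQD2 correction
D → D(α/β + D/n)/(α/β + 2) to every bin before EUD *by default*. At exactly
2 Gy per fraction the correction is the identity, so the 78 Gy / 39-fraction
prescription is a fixed point and the correction only matters off-plateau —
which is precisely where organs at risk live. Because published analyses
are not always explicit about whether EUD was taken on physical or
EQD2-corrected dose, `apply_eqd2 = FALSE` reproduces the literal
physical-dose reading; both paths are tested, and no claim is made about
which one any particular published table used.

## Dose grids

Dose grids are axis-aligned voxel-center arrays (origin/spacing in mm, no
direction cosines — synthetic-phantom scope, not DICOM). Resampling is
trilinear; voxels outside the source support become *missing*, never zero,
and masked statistics exclude missing voxels while reporting the excluded
fraction, so grid-boundary effects cannot masquerade as dose differences.
Subtraction requires matching frames (or explicit resampling). DVHs
extracted from a grid + mask agree with brute-force voxel counting at every
bin edge by construction, and with the masked voxel mean to half a bin
width. The text container prints 17 significant digits, making write→read
round trips bit-exact.

## Wilcoxon signed-rank testing

The cohort comparison uses the paired Wilcoxon signed-rank test. Zero
differences are dropped before ranking (the classical convention, and what
the mainstream SPSS implementation does); Pratt's rank-then-drop variant is
available behind a flag. Ties get midranks. For n ≤ 25 the two-sided
p-value is **exact**: the distribution of W⁺ over all 2ⁿ sign assignments
is built by the shift algorithm over doubled midranks, which is
mathematically identical to full enumeration (the test suite proves
equality against a brute-force 2ⁿ oracle for n ≤ 10, randomized, including
ties and zeros). Above the cutoff a normal approximation with tie-aware
variance (Σrᵢ²/4) and continuity correction is used. An all-zero difference
vector yields a flagged degenerate result with p = 1 rather than an error,
so null cohorts produce readable tables. No multiple-testing correction is
applied by default — mirroring how such single-study tables are usually
reported — and a Holm option exists with the obvious caveat that DVH
metrics are strongly correlated.

## The synthetic cohort: what it emulates, and what a green test means

No patient data ship with the package; the generator produces a cohort with
the *statistical structure* the analysis assumes, not with anatomical
realism. Effects are injected directly in DVH space — the dose-calculation
algorithms themselves are out of scope and are represented only by their
documented signatures:

* **PTV**: a two-piece Gaussian plateau (centre ≈ 79.6 Gy, edge ≈ 0.8 Gy)
  plus a bounded hotspot tail and a *cold component* on 60–73.5 Gy holding
  the fraction of PTV volume overlapping the rectal air cavity (default
  3.4 %, matching a published AXB-like V95 of ≈ 96.6 %).
* **Algorithm effect on coverage**: AAA-like variants move
  `aaa_air_coverage_boost` percentage points (default 2.4, the published
  V95 gap) from the cold component to the plateau — AAA-like algorithms
  over-predict dose in air, reporting better coverage. With noise off the
  V95 difference equals the setting exactly, which the tests exploit.
* **Grid effect**: the falloff side of the plateau widens by
  `grid_falloff_blur` Gy per mm of grid beyond 1 mm (defaults AAA 0.8,
  AXB 0.1) — volumetric averaging erodes coverage without creating
  hotspots, reproducing the published ≈ 1.2 % V95 loss from 1 to 3 mm and
  ≈ 1.25 Gy mean-dose drop from 1 to 5 mm for the AAA-like algorithm while
  keeping D_max grid-stable.
* **Rectum**: low-dose bulk plus a PTV-overlap shoulder (~12 % of volume
  near 70–81 Gy). AAA-like variants shift the whole curve right by
  `rectum_dose_shift` percent of prescription (default 2.87, the published
  mean-dose gap). The uniform shift makes the injected mean-dose offset
  exact; the published effect is concentrated in the mid-dose region, so
  per-metric magnitudes other than the mean are emulation, not
  reproduction.
* **Bladder / femoral heads**: bounded low/mid-dose curves with only
  per-patient and per-variant jitter; their published algorithm differences
  are < 1 % and are not modelled.
* **Body**: PTV plus a near-prescription spill (~9.5 % of TV) plus
  low-dose normal tissue, giving CI ≈ 1.05–1.07 at the 95 % isodose.

Per-patient variability scales were chosen once to make the cohort SDs land
near published values (V95 SD ≈ 0.6–0.8) and are labelled assumptions: the
underlying per-patient data were never deposited, so these SDs are
plausibility calibrations, not estimates. Randomness is split by counter:
each (seed, patient, variant) gets its own derived stream, so adding
patients never changes existing ones, and generation restores the caller's
RNG state.

A green end-to-end test therefore establishes that the *pipeline* recovers
the signs of the calibrated effects with correct paired inference at
n = 20 — not that the generator reproduces any published cohort's numbers.
Magnitude agreement with published tables is qualitative by construction.

The companion 3D phantom builds the same story in voxel space (body
cylinder, PTV ellipsoid, rectum with a ~70 cm³ air ellipsoid overlapping
the PTV margin): AAA-like variants add a dose bump strictly inside the air
cavity, grid size widens the sigmoid falloff, so algorithm differences
concentrate in the cavity and grid differences in the falloff shell — both
verified against the masks that placed them there.

## Numerical choices and degenerate inputs

* Cumulative fractions may not increase by more than 10⁻¹² (constructor)
  or 10⁻⁶ (text parser, which then clamps by running minimum); larger
  violations are rejected with the offending index.
* Doses are stored in Gy; percent-of-prescription is presentation only.
  Probabilities are unit-interval internally, percent with 2 decimals in
  display columns; every emitted table keeps full-precision columns beside
  display columns.
* p-values below 0.01 display as "< .01"; raw values are always retained.
* Degenerate inputs fail loudly: single-point DVHs in `dvh_summary`, empty
  masks, zero target volumes, tumor/normal parameter mix-ups, unbalanced
  cohorts (listing every missing patient-variant pair) — all are rejections
  with diagnostics, not silent repairs.

## Known limitations

* No DICOM-RT import; the grid container is a synthetic-scope text format.
* No direction cosines / oblique frames in the grid module.
* The logistic EUD model is the only dose-response family implemented (no
  LKB NTCP, no Poisson TCP, no repopulation), and parameters are taken as
  given, never fitted.
* The TD50 "within a specific time interval" qualifier of published
  tolerance tables is carried as documentation only.
* Whether published rectal DVHs include the balloon air volume is
  unresolved in the source literature; the DVH container carries an
  optional `air_excluded` flag but the generator takes no position.
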