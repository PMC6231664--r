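# vmatqa — dosimetric and radiobiological evaluation of radiotherapy plan variants

`vmatqa` is an R package for medical physicists comparing competing
external-beam radiotherapy plan variants — typically the same prostate VMAT
plan recalculated with different dose-calculation algorithms (a
convolution/superposition algorithm, "AAA", vs a linear Boltzmann transport
solver, "AXB") and different calculation grid sizes (1–5 mm). From
per-structure dose-volume histograms (DVHs), and optionally 3D dose grids,
it computes the standard plan-evaluation battery and runs the paired cohort
statistics needed to decide whether an algorithm/grid combination changes
plan quality.

## What it computes

**DVH core.** Cumulative ↔ differential DVH conversion, D_x and V_x%
queries by linear interpolation, and summary doses (min / max / mean /
median).

**Target-dose indices.**

- Homogeneity index: HI = (D2 − D98) / D50 (0 = perfectly homogeneous)
- Conformity index: CI = V_RI / TV (reference-isodose volume over target
  volume; 1 is ideal)
- Conformation number: CN = (TV_RI / TV) · (TV_RI / V_RI) ∈ [0, 1]
- Percent deviation from a reference plan: |Ref − Eval| / Ref × 100, with
  the Boltzmann solver at the finest grid as the default reference

The reference isodose defaults to 95% of the prescription dose
(74.1 Gy for 78 Gy / 39 fractions), configurable.

**Radiobiology.** Equivalent uniform dose as the generalized power mean of
the differential DVH,

    EUD = (Σ_i v_i D_i^a)^(1/a),

with the logistic dose–response scores

    TCP  = 1 / (1 + (TCD50 / EUD)^(4 γ50))
    NTCP = 1 / (1 + (TD50  / EUD)^(4 γ50)),

an optional EQD2 fractionation correction
D → D (α/β + D/n) / (α/β + 2) applied before EUD (on by default), and a
built-in five-organ parameter registry (prostate target a = −13,
γ50 = 2.2, TCD50 = 67.5 Gy, α/β = 1.5 Gy; rectum 8.33 / 2.66 / 80 / 5.4;
bladder 2 / 3.63 / 80 / 7.5; femoral heads 13 / 2.7 / 65 / 3) that
round-trips to CSV for substituting literature parameter sets.

**Dose grids.** Axis-aligned 3D dose arrays with trilinear resampling
(out-of-support voxels become missing, never zero), voxel-wise signed
dose-difference maps, masked difference statistics, DVH extraction from a
grid + mask, and a bit-exact plain-text grid container.

**Cohort statistics.** Paired Wilcoxon signed-rank tests with exact
tie-aware p-values (shift-algorithm over midranks, identical to full 2^n
sign enumeration) for n ≤ 25 and a tie/continuity-corrected normal
approximation above, plus a contrast table across plan variants matching
the usual report layout (p shown as "< .01" below 0.01, raw values kept).

**Synthetic cohort.** A seeded generator emulating a 20-patient prostate
cohort — PTV with sigmoid falloff and a cold subvolume from the endorectal
balloon air cavity, serial-organ rectum with a PTV-overlap shoulder,
bladder, femoral heads, body — with configurable algorithm and grid
effects, so the full pipeline is testable end to end without patient data.

## Worked example

```r
library(vmatqa)

reg <- default_param_registry()

# a rectum receiving a homogeneous 80 Gy sits exactly at its TD50:
ddvh <- differential_dvh("Rectum", bin_centers = 80, fractional_volumes = 1)
ntcp(eud(ddvh, reg$Rectum$a), reg$Rectum)
#> [1] 0.5

# full synthetic-cohort analysis (20 patients x 6 plan variants)
cohort <- generate_cohort(cohort_spec(n_patients = 20, seed = 1))
report <- run_full_analysis(cohort, output_dir = "report")

subset(report$metrics, patient == "P01" & variant == "AXB1" &
         structure == "PTV" & metric %in% c("V95", "D_median", "HI"))
#>            patient algorithm grid_mm variant structure   metric      value
#> P01.AXB1.1     P01       AXB       1    AXB1       PTV      V95 96.6420746
#> P01.AXB1.2     P01       AXB       1    AXB1       PTV D_median 79.7030458
#> P01.AXB1.6     P01       AXB       1    AXB1       PTV       HI  0.1792298
```

`report/` then holds five tidy CSVs: the PTV summary (`table_ptv.csv`, cohort
mean (SD) of V95 / summary doses / HI / CI / CN per variant), the OAR summary
(`table_oar.csv`, doses as percent of prescription plus V30/V50/V70), percent
deviations against the AXB 1 mm reference (`table_deviation.csv`), TCP/NTCP
percentages (`table_radiobio.csv`) and the Wilcoxon contrast table
(`table_pvalues.csv`). With the default effect model the cohort reproduces
the qualitative findings such generators are calibrated to: AAA-like
variants show higher PTV V95 and TCP and higher rectal NTCP than AXB-like
ones (all p < .01 at n = 20), and AAA coverage falls with grid size.

A command-line front end is installed with the package:

```sh
Rscript inst/cli/vmatqa simulate --out cohort_dir --seed 1 --n-patients 20
Rscript inst/cli/vmatqa report --cohort cohort_dir --out report_dir
```

(exit codes: 0 success, 2 validation failure, 3 parse failure).

## Reference values

`inst/extdata/reference_summary_{ptv,oar,radiobio}.csv` ship cohort-level
summary values from a published 20-patient prostate VMAT study comparing
these algorithm/grid combinations (accessor:
`reference_cohort_summary()`). They are worked-example *inputs* — e.g. the
acceptance suite recomputes cross-table percent deviations from them — not
outputs the package claims to reproduce; the underlying patient DVHs were
never deposited.
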