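Package: vmatqa
Title: Dosimetric and Radiobiological Evaluation of Radiotherapy Plan Variants
Version: 0.1.0
Authors@R:
    person("vmatqa", "developers", email = "vmatqa@example.org", role = c("aut", "cre"))
Description: Tools for comparing competing external-beam radiotherapy plan
    variants (e.g. dose-calculation algorithm and grid-size combinations for
    prostate VMAT) from their dose-volume histograms and, optionally, 3D dose
    grids. Computes cumulative/differential DVH conversions and D_x / V_x%
    queries, target-dose indices (homogeneity index, conformity index,
    conformation number), reference-relative percent deviations,
    EQD2-corrected equivalent uniform dose with logistic TCP/NTCP
    dose-response scores, voxel-wise dose-difference maps, and paired
    Wilcoxon signed-rank cohort comparisons. A seeded synthetic-cohort
    generator emulates a 20-patient prostate cohort with an endorectal
    balloon air cavity so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
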