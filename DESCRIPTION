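Package: kneevbr
Title: Voxel-Based Relaxometry of Knee Articular Cartilage
Version: 0.1.0
Authors@R: person("VBR", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A tested pipeline for voxel-based relaxometry (VBR) of knee
    articular cartilage: per-voxel T1rho/T2 mono-exponential mapping from
    multi-echo magnitude volumes, rigid echo alignment and atlas-space
    resampling, voxel-wise covariate-adjusted group-difference maps and
    Pearson partial correlations with patient-reported outcomes (KOOS),
    compartment summaries (percentage of significant voxels, average
    percentage difference, average r and P), and cartilage thickness via
    per-slice Euclidean distance transform and skeletonization. Ships a
    seeded synthetic knee-phantom cohort generator with known effect sizes
    so every stage is testable without protected imaging data, plus
    minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
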