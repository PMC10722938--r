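---
title: "Voxel-based relaxometry of knee cartilage: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based relaxometry of knee cartilage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneevbr)
```

## The problem

Compositional quantitative MRI measures the T1rho and T2 relaxation times of
articular cartilage, which rise with proteoglycan depletion and collagen
disorganization before any morphological damage is visible. Voxel-based
relaxometry (VBR) compares these relaxation times voxel by voxel across a
cohort after every knee has been brought into a common atlas space, rather
than averaging over hand-drawn regions. `kneevbr` implements the full
analysis chain — mono-exponential map fitting, rigid echo alignment and
atlas resampling, voxel-wise covariate-adjusted statistics, compartment
summaries, and distance-transform cartilage thickness — together with a
seeded synthetic phantom cohort generator, so that every stage can be
validated end to end with known ground truth.

## The relaxation model

Each voxel's multi-echo magnitude signal is modeled as a mono-exponential
decay over the preparation time $t$ (spin-lock time for T1rho, preparation
echo time for T2):

$$S(t) = S_0 \, e^{-t/T} ,$$

fitted independently per voxel (no spatial regularization). Two estimators
are provided:

* **Log-linear** (`loglinear_fit()`): OLS of $\log S$ on $t$; closed form,
  exact on noiseless data. It is both the initializer and the independent
  oracle for the nonlinear fit.
* **Levenberg–Marquardt** (`fit_monoexponential()`): per-voxel nonlinear
  least squares, vectorized over all masked voxels with per-voxel damping
  and closed-form 2x2 steps.

Default echo schedules are the acquisition protocol's: 0/10/40/80 ms
(T1rho) and 0/12.87/25.69/51.39 ms (T2). The default fitting bounds
(1, 200) ms are a generous physiological envelope for cartilage at 3 T —
no bound is inherent to the model, and voxels that end on a bound are
excluded by `fit_quality_mask()` along with non-converged voxels and those
below the signal-space $R^2$ floor (default 0.8; per-voxel $R^2$ is
defined against the mean-signal null because the exclusion policy needs a
quality metric even though none is inherent to the model). Magnitudes
$\le 0$ are floored at a small epsilon for the log initializer only; the
LM objective always sees raw values.

## Registration

Within an acquisition, all echoes are rigidly aligned to the first
spin-lock/echo time by minimizing mean-squared error on mean-normalized
intensities (echoes differ by a global decay factor), with a 2-level
pyramid and a coarse integer-translation search to escape the plateaus of
piecewise-constant phantoms. MSE rather than mutual information is
deliberate: within-modality echo alignment is intensity-consistent.

Subject-to-atlas mapping is a pluggable contract. The synthetic default is
`identity` (phantoms are generated in atlas space; the mode verifies grid
agreement and passes values through bit-exactly). An `affine` mode
optimizes 12 parameters on MSE, initialized by intensity-centroid and
per-axis variance matching; the initializer deliberately avoids a full
eigen-decomposition because near-symmetric images make that ambiguous up
to reflection. Harder geometry (true deformable registration) belongs to
the `plugin` mode, which delegates to an external backend through a
NIfTI-in/NIfTI-out exchange. Values are interpolated trilinearly, labels
and masks by nearest neighbour.

## Voxel-wise statistics

Per voxel, the group analysis fits OLS of relaxation time on an intercept,
a binary abnormality indicator, and covariates (age, sex, BMI, acquisition
site as one-hot with the first level as reference; optional compartment
thickness). The group dichotomization is grade $\ge 1$ = "with
abnormality". The per-voxel p-value is the two-sided t-test on the group
coefficient, and the effect map is the *adjusted percentage difference*

$$\mathrm{APD} = 100 \cdot \frac{m_\text{without} - m_\text{with}}{m_\text{without}}$$

evaluated at the covariate means, so a **negative** APD means **higher**
relaxation times in abnormal knees. The denominator is the adjusted mean
of the without-abnormality (reference) group — the published convention
fixes only the sign, so the denominator is a documented package choice.

Outcome analyses use Pearson partial correlations: relaxation and outcome
are each residualized on the covariates and the residuals correlated, with
$t = r\sqrt{(n-k-2)/(1-r^2)}$, $k$ = number of covariate columns; with no
covariates this reduces to the plain Pearson correlation. Ordinal grades
used as outcomes are treated as numeric. All tests are two-sided.

Significance is thresholded at $p \le \alpha$ (default 0.05) and
significant voxels are grouped into connected components at
26-connectivity (minimum size 1). No correction across voxels or
contrasts is applied by default, matching the raw-threshold reporting
style of the source analyses; clusters are reported with size and mean p.
Compartment summaries report PSV (percent of compartment voxels
significant), APD or average r over significant voxels, and average p
(arithmetic mean over significant voxels). Display volumes use
$10 \log_{10}(1/p)$.

A permutation option (`voxelwise_group_permutation()`) relabels the group
indicator and recomputes the group t-statistic; it serves as a robustness
cross-check of the parametric p-values.

## Cartilage thickness

Thickness is computed per sagittal slice, exactly as the measurement it
emulates: 2D Euclidean distance transform of the compartment mask,
skeletonization (Zhang–Suen thinning), and sampling of the distance map
at skeleton points. Two numerical choices matter:

* The mask is refined 2x before the transform. On the original grid the
  discrete medial axis carries a half-voxel parity bias (even-width
  ribbons under-measure by a full voxel); after 2x refinement a straight
  ribbon of any integer voxel width is measured exactly.
* A medial-axis distance is a *half*-thickness; the reported
  `thickness_mm` is the doubled sample, and the raw sampled distance is
  exposed alongside it (`mean_distance_mm`) so the undoubled reading of
  the procedure is also reproducible.

Slices with fewer than 5 mask pixels are skipped; an empty compartment is
flagged undefined rather than raising. The compartment mean weights slices
by skeleton point counts. Default groupings are the three broad masks
(femoral = MFC + LFC + TRO, tibial = MT + LT, patellar = PAT); thickness
covariates may enter the statistical adjustment either as 3 per-knee
values or per slice — both granularities are accepted.

## The synthetic cohort: what it emulates, and what it does not

The generator produces, from one seed, a labeled atlas, per-knee
ground-truth relaxation fields, multi-echo magnitude volumes, and subject
records. Its defaults are the published cohort's marginals:

* Grade prevalences: bone marrow edema 62/11/2 of 75, patellar tendinosis
  28/32/14/1, quadriceps tendinosis 46/29 (exact count fractions).
* Covariates: age 18.69 ± 0.84 y, BMI 23.78 ± 2.56, 35/75 male, 3
  acquisition sites (uniform; the study spanned 3 institutions).
* KOOS subscales: Symptoms 87.72 ± 11.61, Pain 90.73 ± 9.55, ADL
  96.11 ± 5.26, Sport/Rec 84.32 ± 18.67, QOL 83.26 ± 19.78, with the
  standard instrument's item counts (7/9/17/5/4).
* Ground-truth compartment relaxation times are field-typical healthy 3 T
  values (40–45 ms T1rho, 30–35 ms T2); echo noise defaults to Gaussian
  SD 2 at $S_0 = 100$ (SNR 50), with a Rician option for realism
  (Gaussian keeps estimator-bias analysis clean, and no noise model is
  inherent to the pipeline).

Because KOOS scores are bounded at 100 and discretized to the item grid
(step $25/n_\text{items}$), a Gaussian draw clipped to [0, 100] would
undershoot the published mean and SD. The generator therefore draws a
latent Gaussian whose parameters are solved analytically from
censored-normal moment equations (including the discretization variance
$g^2/12$) so that the *observed* scored subscales hit the published
mean/SD. Items are decomposed from the total deficit score with the
remainder assigned to leading items — a documented synthetic convention;
real per-item response patterns are not modeled, so per-item correlation
analyses exercise plumbing, not response psychology.

Injected effects (`effect_spec()`) shift a contiguous sub-region of target
compartments in affected knees by
$-\text{true percentage difference}/100 \times$ reference mean — the same
sign convention as the APD — and can couple a KOOS subscale to the
regional mean relaxation deviation via `latent = baseline + slope * dev +
noise` (a negative slope: higher relaxation, worse outcome; the slope is
defined in the usual regression direction so that its sign equals the
sign of the induced correlation). When the noise SD is left automatic it
is chosen to preserve the subscale's marginal SD. The default coupling
strength used in the validation suite (−6 KOOS points per ms) produces
average partial correlations near −0.35 in coupled compartments,
matching the magnitude of the associations the analysis is designed to
detect. Between-subject biological variability is a single multiplicative
offset per subject, compartment and modality (default SD 2% of the
compartment mean).

Anatomy is deliberately idealized: six disjoint axial slabs in atlas
space, with curved-shell geometry available where curvature matters
(thickness validation). Phantoms carry no inter-subject deformation —
the study design analyzes in a single registered space — so a green
pipeline run validates fitting, statistics and bookkeeping, *not* the
quality of any deformable registration backend, B1/spin-lock physics, or
realistic cartilage morphology. Grade variables are sampled independently
(only marginals are published), and knees are treated as independent rows
even though players contribute two knees; a `player_id` column is exposed
for future clustered analyses.

## Numerical and testing choices

* **Determinism**: every generator takes a seed and restores the caller's
  RNG state; identical spec + seed reproduces every artifact bit-exactly.
* **Type-I calibration testing**: voxels within a compartment share the
  subject-level offset and are therefore correlated; a
  Kolmogorov–Smirnov test on all pooled voxels would reject uniformity
  for dependence reasons alone. The calibration check applies the KS test
  to an independent subsample (one voxel per compartment per seed) and
  separately verifies that mean PSV across 20 seeds sits in the 99%
  Monte-Carlo interval around 5%. With the between-subject offset set to
  zero (voxels then independent), the full-pool KS test passes as well.
* **Degenerate inputs**: zero residual variance reports p = 1 with a
  degeneracy flag; empty compartments and empty significance masks are
  flagged undefined, never errors; rank-deficient designs error naming
  the collinear columns; single-site cohorts drop the site covariate with
  a message.
* **Tolerances**: noiseless fits are exact to ~1e-15 relative (tested at
  1e-6/1e-8); the LM convergence tolerance is 1e-10 relative step.

## Known limitations

Single-component decay only (no stretched-exponential or multi-pool
models); no B1-corrected T1rho; no random-field cluster inference or
FWER control beyond an optional FDR switch; 2D per-slice thickness, not
3D normal-ray methods; the affine atlas mode assumes no gross rotation
(moment-based initialization); deformable registration is out of scope by
design and delegated to the plugin contract.
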