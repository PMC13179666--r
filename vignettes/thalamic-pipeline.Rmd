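---
title: "Thalamic connectivity and volume analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thalamic connectivity and volume analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalnet)
```

## The scientific problem

In pediatric focal epilepsy, the thalamus participates in seizure networks
well beyond the epileptogenic zone, and its nuclei are candidate targets
for neuromodulation. The analysis this package implements asks, per
thalamic subdivision (anterior, lateral, medial, pulvinar) and per
hemisphere relative to the seizure focus: do patients with temporal-lobe
(TLE), frontal-lobe (FLE), or posterior-quadrant epilepsy (PQE) deviate
from typically developing controls in (a) nucleus volume and (b)
functional-connectivity hubness, and do those deviations track clinical
features such as hippocampal sclerosis (HS), a history of focal-to-
bilateral tonic–clonic seizures (FBTCS), etiology, or postsurgical
seizure freedom?

The pipeline consumes three inputs per cohort: a metadata table (group,
age, sex, focus side, scanner batch, clinical labels, estimated total
intracranial volume, eTIV), one 122×122 Pearson connectivity matrix per
subject, and eight thalamic subdivision volumes per subject (4
subdivisions × 2 hemispheres, THOMAS-style segmentation output). Because
patient imaging cannot be shared, the package ships a synthetic cohort
generator that emulates these inputs with configurable planted effects;
every downstream stage is exercised and tested against it.

## The hubness statistic: node-strength AUC

Each subject's connectivity matrix is thresholded into a series of
nested graphs at densities 5%–50% in 1% steps. The construction starts
from a backbone that connects all 122 regions with 121 edges — a
maximum spanning tree on |r|, the unique 121-edge connected backbone
that retains the strongest-magnitude links — and then appends remaining
edges in descending |r|, treating positive and negative correlations of
equal magnitude as tied in rank while retaining the sign of the weight.
The number of edges at density ρ is `max(121, round(ρ·7381))` with
round-half-away-from-zero; ties in |r| are broken by ascending region
index so the series is fully deterministic.

Node strength at a density is the signed sum of retained incident
weights (an absolute-value variant sits behind a switch). The per-node
summary is the trapezoidal area under the strength-vs-density curve
(AUC) over ρ ∈ [0.05, 0.50]; a constant curve c integrates to 0.45·c,
which anchors the closed-form tests. The AUC makes the statistic robust
to the arbitrary choice of any single density.

Two conventions were genuinely open and are resolved as follows:
whether strength sums signed or absolute weights (signed is the default,
matching the standard strengths convention for signed networks; both
are implemented), and whether edge counts are floored or rounded at
each density (rounded half away from zero, never below the backbone).

## Scanner harmonization

Volumes and connectivity edges are acquired on two scanner generations,
so both are harmonized with a parametric empirical-Bayes location/scale
model (the standard ComBat formulation): per feature, data are
standardized by a pooled batch+covariate least-squares fit, per-batch
locations are shrunk toward a normal prior and per-batch variance
ratios toward an inverse-gamma prior (hyperparameters by method of
moments), and the covariate and grand-mean structure is restored after
de-batching. Age, sex, and a patient indicator are protected as
biological covariates — the patient indicator matters because only
patients were scanned on the newer system, so group is partially
confounded with batch. Connectivity matrices are harmonized on their
7381 upper-triangle edges and re-symmetrized; values pushed outside
(−1, 1) are counted and reported, never clipped silently.

Order of operations: harmonization is applied to raw volumes before
eTIV adjustment, and to edges before any graph construction, so that
scanner variance never propagates into derived statistics.

Two properties deserve honesty. First, harmonization is *not* exactly
idempotent: a second pass re-estimates the scale standardization from
the transformed data, so values move again by a quantity of the order
of the shrinkage/sampling residual (the tests bound this at a small
fraction of the first pass's correction, and verify that residual
between-batch variance fractions are near zero). Second, when the true
batch effect is identical across features — as in our simulations — the
empirical-Bayes prior variance is driven purely by sampling noise and
the shrinkage weight settles near 1/2, re-introducing half of each
feature's estimation noise; per-feature "improvement" fractions
therefore approach 100% only when the planted effect dominates that
noise. Real data, with heterogeneous batch effects across features, sit
closer to the no-shrinkage regime. The implementation is validated
against the reference `sva::ComBat` to ~1e-7 on matched inputs.

## Normative modeling and laterality

Volumes are adjusted for eTIV by the residual method — each feature is
regressed on eTIV in controls and the eTIV-predicted component removed
from everyone (a ratio variant is exposed behind a switch). Strength
AUCs and adjusted volumes are then converted to Z-scores against a
normative GLM (`value ~ age + sex`) fitted on **controls only** — the
W-score convention. Fitting on the pooled sample would absorb disease
effects into the reference; both modes exist, controls-only is the
default. Age enters linearly and sex as a binary indicator; with ~70
controls and a pediatric age range this is as much structure as the
reference cohort supports (no spline/GAMLSS-style growth curves).

Z-scoring is strictly hemisphere-matched: a right-sided feature is
scored against right-sided control values, which respects natural
anatomical and functional asymmetries. Only after Z-scoring are patient
values relabeled ipsilateral/contralateral to the seizure focus
(left-focus: left = ipsi; right-focus mirrored). Controls retain
left/right labels and are excluded from ipsi/contra tables. The
pipeline records a stage attribute (raw → harmonized → eTIV-adjusted →
Z) and refuses out-of-order application.

A statistical caveat stated here because the package's own null
calibration depends on it: one-sample t-tests of patient Z-scores
against zero treat the control reference as fixed. With a finite
control sample the reference itself is estimated, so these tests are
anticonservative in proportion to n_patients/n_controls. The package's
null-calibration checks therefore draw features from the population
reference (true mean 0, SD 1), which verifies the test machinery and
the generator rather than the control-estimation step — the same
convention the original analysis uses.

## The statistical battery

Mixed repeated-measures ANOVAs are computed via the multivariate
approach on orthonormal within-subject difference contrasts: Wilks' Λ
with Rao's F approximation, and Pillai's trace, reported side by side
(they coincide whenever the hypothesis has one degree of freedom, i.e.
in all two-group models). The error degrees of freedom of this approach
— e.g. (7, 198) for an 8-level within factor at N = 206, and (6, 264)
for the nuclei×group interaction under Pillai at N = 136 — are exactly
the conventions of the commercial software tables this engine mirrors.
The between-subjects effect is the univariate ANOVA of subject means;
the between design uses sum-to-zero coding so within main effects test
the unweighted grand mean. Partial η² is always `F·df1/(F·df1+df2)`.
The implementation is cross-checked against `car::Anova` (type III,
multivariate) to 1e-4 in the tests.

An interesting consequence of W-scoring worth knowing when reading the
two-group output: because controls have per-feature Z mean exactly zero
by construction, the unweighted grand mean equals half the patient
deviation, making the within main effect and the within×group
interaction *identical* tests. The pipeline reproduces this duplication
rather than hiding it.

Planned comparisons are one-sample t-tests of each patient group's Z
against zero (the control mean), paired t-tests of ipsi vs contra
within patients, and pooled-variance independent t-tests for edgewise
maps (Welch behind a switch). Cohen d is reported as a magnitude with
the sign carried by the mean. Bonferroni families default to m = 8 for
the one-sample family (4 subdivisions × 2 lateralities per measure per
group) and m = 4 for the paired family (subdivisions); these family
sizes are back-calculated from the relation between published
uncorrected statistics and corrected p-values and are config-overridable.
Correlation analyses (volume vs strength, and each vs epilepsy
duration) use a family equal to the number of subdivision×laterality
pairs per block.

Clinical subgroup contrasts (HS within TLE, FBTCS, status epilepticus,
acquired vs congenital etiology, postsurgical seizure freedom) rerun
the three-way mixed ANOVA on the relevant dichotomy, excluding subjects
with unknown labels per analysis rather than globally — which is why
analyzed N differs across rows of the subgroup table.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. Its defaults
are the study conditions: 81 TLE / 36 FLE / 19 PQE / 70 controls;
group-wise age means 13.1/11.8/13.2/13.4 years (SD ≈ 3), truncated to
the pediatric range 4–18 (the truncation bounds are our choice; the
source reports only means and SDs); sex ratios, focus-side ratios
(~3:1 left), HS/FBTCS/status-epilepticus/etiology/seizure-freedom label
frequencies, and epilepsy durations matching the cohort table; all
controls plus ~76% of patients on the 1.5T batch, the rest on 3T.

Volumes (mm³) are generated as subdivision means (anterior 140, lateral
1700, medial 950, pulvinar 1450 — representative THOMAS-scale values)
scaled proportionally by each subject's eTIV (mean 1.45×10⁶ mm³, SD
1.2×10⁵), with a +0.5%/year age trend, +3% male offset, +1% leftward
asymmetry, and Gaussian residual noise at 6% of the mean. Planted group
effects add d × (residual SD) on the side(s) mapped through the
subject's focus, so the pipeline's Z-scale estimate of d is unbiased by
construction, and the eTIV adjustment has something real to remove.

Connectivity is generated in Fisher-z space — population mean matrix +
i.i.d. upper-triangle noise (SD 0.12) + planted shifts — and
back-transformed with tanh, which guarantees entries in (−1, 1) without
clipping. No real control mean matrix is available, so the population
matrix is synthetic and labeled as such: a block structure with
hemispheric, homotopic, and lobe-community organisation plus
subdivision-specific profiles (anterior ↔ amygdala/hippocampus/frontal;
lateral ↔ sensorimotor/inferior frontal; medial ↔ insular/amygdala/
accumbens; pulvinar ↔ mesial temporal/occipital/posterior cingulate,
weak frontal) that echo the qualitative control profiles the analysis
reports. A deterministic low-rank ripple breaks magnitude ties.

Planted node-strength effects shift every edge incident to the target
subdivision — the cleanest way to map a scalar d onto the strength
statistic. The per-edge z-shift is calibrated internally as
d × SD(control AUC) / (∂AUC/∂shift), both quantities estimated by a
small Monte-Carlo of control draws at the configured noise level (80
draws by default, under a seed derived from the cohort seed). The
sensitivity uses paired differences — the same noise draw with and
without the shift — because density thresholding makes the AUC response
noticeably steeper under noise than at the noiseless mean matrix (a
~17% difference that would otherwise inflate every planted effect).
Acceptance runs recover planted d within roughly ±0.08 averaged over 20
seeds; most of the residual gap is a mild attenuation from the
scanner-effect injection/harmonization cycle, which multiplies and then
rescales the 3T patients' deviations.

The default planted-effect table encodes the per-group Z-deviations the
study reports (pulvinar hypoconnectivity in all groups, ipsilateral
anterior/lateral volume loss, contralateral medial enlargement). The
anterior-strength effect within TLE is split by pathology — +0.45 with
HS, −0.40 without, both hemispheres. The 0.85 gap was chosen once, by a
noncentrality argument, to put the nuclei×group interaction in the
partial η² ≈ 0.2 regime at the 28/53 HS split; recovered values land at
≈ 0.2–0.3.

Scanner effects are injected separately (`inject_batch_effects`):
additive offset + scale on deviations about the feature mean, applied
to the 3T batch — 0.1 residual-SD units additive and ×1.5 scale by
default — so harmonization is exercised against a known ground truth.

What the generator does *not* emulate, and hence what passing tests do
not show about real data: fMRI acquisition and preprocessing artifacts
(motion, physiological noise, distortion), spatially correlated
inter-subject variability (noise is i.i.d. across edges), non-Gaussian
volume distributions, age-dependent connectivity, lesion-driven
segmentation failure, and any coupling between volume and connectivity
beyond what is planted. Parameter recovery on this generator validates
the pipeline's estimators, not the biology.

## Numerical and degenerate-input choices

- Tie-break for equal |r|: ascending (i, j) index order; determinism
  over any claim about the original ordering.
- Edge counts: round half away from zero (R's default round-half-even
  would be surprising in report tables too, so printed tables round the
  same way).
- Zero-variance features in harmonization: passed through with a
  warning rather than crashing degenerate synthetic cases.
- A degenerate one-sample test (sd = 0) at exactly the null value
  returns t = 0, p = 1, d = 0; away from the null it is an error.
- eTIV adjustment with zero eTIV spread in controls: identity (nothing
  to regress out).
- Single-batch harmonization: location ≈ 0, scale ≈ 1 up to the
  n/(n−1) convention gap between the pooled and per-batch variance
  estimators.
- The laterality relabeling is idempotent; an already-relabeled table
  passes through unchanged.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at the
study's group sizes (206 subjects, 122×122 matrices) across 20 seeds
for parameter recovery, 1000 simulated features for one-sample null
calibration, 1000 simulated cohorts of N = 40 for ANOVA null
calibration, and 2×2500 subjects × 200 features for the harmonization
recovery scenario; these sizes give Monte-Carlo standard errors
comfortably inside the asserted tolerances.

## Known limitations

- The normative GLM is linear in age; genuine pediatric growth curves
  are nonlinear over 4–18 years.
- No permutation or mixed-effects (random-slope) inference; the battery
  mirrors the fixed-effects repeated-measures convention of the source
  analysis.
- Edgewise maps are reported with uncorrected p-values by design
  (exploratory), and no spatial statistics are attempted.
- The 122-region atlas shipped here is a stand-in with
  Harvard–Oxford-style names; region identities matter to the synthetic
  profiles, not to any quantitative claim.
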