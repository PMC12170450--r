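---
title: "Mapping self-generated speech deficits from resection masks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping self-generated speech deficits from resection masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After left-hemisphere resective neurosurgery, a small fraction of patients
present with a striking dissociation: fluent language when the task supplies
the content (naming, repetition, reading) but markedly reduced spontaneous,
self-generated speech, without apraxia of speech (AOS) and without a
proportionate overall aphasia. `lesionmap` implements the statistical chain
used to localize such a profile from per-subject binary resection masks in a
common 2 mm space and bedside aphasia batteries:

1. **Battery harmonization** — WAB and QAB subscores mapped into shared
   0–10 metrics (self-generated speech, overall severity, repetition,
   naming).
2. **Univariate VLSM** — a general linear model at every voxel relating
   lesion status to the self-generated speech metric, with nuisance
   covariates, a lesioned-in-at-least-*k* inclusion rule, and max-statistic
   permutation correction.
3. **Multivariate SVR-LSM** — one epsilon-SVR over all included voxels
   jointly, nuisance covariates regressed out of the outcome, direct total
   lesion volume control (dTLVC) on the features, and permutation
   thresholding of the back-projected weight map.
4. **LSM-ROI and cohort statistics** — the intersection of the two
   significant clusters defines a region of interest; 1.5-SD rules classify
   subjects by ROI resection and by disproportionate deficit; a 2×2 table
   yields relative risk (RR) and odds ratio (OR) with confidence intervals,
   plus chi-square, rank-sum, and percent-damage comparisons.
5. **Synthetic cohorts** — because the clinical data underlying this kind of
   study are not public, a generator with planted ground truth provides the
   test bed.

## Harmonization model

Both batteries score 0–10 with 0 most impaired. The shared metrics are:

| metric | WAB source | QAB source |
|---|---|---|
| self-generated | Fluency rating (0–10, as-is) | mean of Reduced Length & Complexity, Reduced Speech Rate, Overall Communication Impairment (each 0–4) × 2.5 |
| overall | Aphasia Quotient / 10 | Overall score (as-is) |
| repetition | Repetition score | Repetition summary score |
| naming | Object Naming (pre-scaled 0–10) | Picture Naming (pre-scaled 0–10) |

The three QAB connected-speech ratings are averaged *before* rescaling;
this is algebraically identical to rescaling first but keeps thirds exact
until the final float. Picture Naming (not the Word Finding summary) is the
QAB naming source because it corresponds to a confrontation-naming task.
The raw maximum of WAB Object Naming differs across battery versions, so
this module takes a 0–10 pre-scaled input and documents that normalization
happens upstream. AOS is an input flag (clinically rated by consensus), not
something the package infers.

## Univariate model and permutation scheme

At voxel $v$ with lesion indicator $\ell_v$, the model is

$$y_i = \beta_0 + \beta_v \ell_{iv} + \mathbf{z}_i^\top\gamma + \varepsilon_i$$

with covariates $\mathbf{z}$ = overall severity, AOS, instrument,
days post-surgery, lesion volume. The stored statistic is the t value of
$\hat\beta_v$, computed by Frisch–Waugh residualization (identical to the
full per-voxel fit, but one shared projection makes thousands of voxels and
permutations cheap). Inclusion requires at least 5 lesioned subjects
(configurable) *and* at least 2 intact subjects — the second bound is ours:
the published rule states only the lesioned minimum, but the contrast is
inestimable without intact variance. Voxels whose lesion indicator is
collinear with the covariates are excluded and counted.

Correction permutes the outcome vector across subjects with lesions and
covariates fixed, refits, and records the extreme statistic (max of $-t$
for the default lower tail, $|t|$ two-sided) plus the largest
face-connected suprathreshold extent at a primary threshold. The primary
cluster-forming threshold is the parametric one-tailed t at p = 0.01 — an
implementation choice; the original VLSM tool's internals are unstated, so
both voxel-FWER and cluster-extent nulls are exposed and the voxel-FWER
rule (corrected p ≤ α, (B+1)-denominator convention) drives the
significant-cluster mask. When the requested permutation count covers all
n! orderings (n ≤ 8) the enumeration is exhaustive and p values are exact
proportions.

## Multivariate model

The SVR stage follows the SVR-LSM recipe: nuisance covariates are regressed
out of the outcome (not entered as features), each subject's binary lesion
row is divided by the square root of their total lesioned-voxel count
(dTLVC, giving unit-norm binary rows), and one epsilon-SVR is fit over all
included voxels. Weights are back-projected as $w_v = \sum_i \beta_i
x_{iv}$ — exactly the primal weights for the linear kernel. Defaults are
linear kernel, C = 1, epsilon = 0.1: the original toolbox's MATLAB defaults
are not stated in the text we work from, and a linear kernel makes the
back-projection exact and testable; rbf is available for fidelity to the
method family, in which case the map is a sensitivity map. Permutation
refits reuse identical hyperparameters and the (permutation-invariant)
kernel matrix; per-voxel p is the fraction of permuted $|w|$ at or above
the observed one, and the significant set is thresholded at α voxelwise
(cluster-level inference for the multivariate map is deliberately not
asserted, since the reference tool's convention is unstated).

No SVM library ships in the target environment, so the solver is a
LIBSVM-style SMO on the 2n-variable dual with a precomputed kernel,
implemented in C++. It was validated against scikit-learn's SVR during
development (max weight deviation ~7e-7 on a 30×50 problem) and is checked
in the test suite by strong duality (primal-dual gap < 1e-4 at tol 1e-8)
and tube KKT conditions — checks that do not share code with the solver.

## ROI construction and cohort statistics

The LSM-ROI is the voxelwise AND of the univariate and multivariate
significant-cluster masks. Classification rules recompute their thresholds
from the supplied cohort, never from constants: ROI resection means
per-subject Dice with the ROI ≥ mean + 1.5·SD; deficit means
(overall − self-generated) ≥ mean + 1.5·SD *and* no AOS. Sample SD
(n − 1) is used; the source text does not specify population vs sample SD.
The deficit threshold is computed over all subjects with the AOS exclusion
applied afterwards — the alternative (excluding AOS cases before computing
the threshold) is defensible but not what we read the rule to say.

RR uses the Katz log CI, OR the Woolf log CI, both with z = 1.96 — the
standard closed forms; the source does not name its method, and the match
of both intervals to the published values at two decimals supports the
choice. Chi-square is uncorrected Pearson (a published χ² of exactly 0.00
at equal proportions is consistent with no Yates correction); Yates is
available by flag. The rank-sum test reports the Mann–Whitney U of the
first sample with midranks; p is exact (Wilcoxon distribution) without ties
for small samples, else normal with tie correction.

## The synthetic world

`sim_config()` defaults state the cohort the pipeline expects, and they are
not tuned per test:

* grid 32×36×32 at 2 mm — desk-scale, same resolution as the target data;
* n = 60 subjects; lesions are axis-aligned ellipsoids with lognormal
  semi-axes (median 17 mm, sdlog 0.3), giving volumes averaging ~21 cm³
  with a long right tail, matching the clinical distribution
  (21.4 ± 18.6 cm³); centers sampled in the central 70% of the grid;
* a planted critical ellipsoid (5 cm³); the latent self-generated score is
  $10 - \beta_{\mathrm{eff}}\,c_i - \beta_{\mathrm{ov}}\,V_i/V_{\mathrm{ref}}$
  with coverage $c_i$ the lesioned fraction of the region,
  $\beta_{\mathrm{eff}} = 4$, $\beta_{\mathrm{ov}} = 2$,
  $V_{\mathrm{ref}} = 21.43$ cm³, Gaussian noise SD 1, clamped to [0,10].
  Overall severity carries the volume term only; repetition and naming
  track it with independent noise;
* an AOS region disjoint from the critical region (any overlap sets the
  flag), so the deficit rule's AOS exclusion is exercised independently;
  AOS has no additional score effect — nothing in the stated model requires
  one;
* instruments mixed 50/50 (the WAB/QAB split of the clinical database is
  not published), evaluations 1–5 days post-surgery, ages ~46 ± 16
  truncated to 18–87, etiologies in the clinical mix (~81% glioma);
  covariates are drawn independently — the joint distribution is not
  described anywhere, so no correlation is asserted.

Raw subscores are back-generated from the latent metrics so harmonization
recovers them exactly; the three QAB connected-speech ratings are set equal
(real raters disagree — instrument noise in
`generate_paired_assessments()` models between-instrument disagreement
instead).

What the generator does *not* emulate: vascular-territory or surgical
lesion geometry, registration/warping error, mask-smoothing artifacts,
recovery trajectories, or rater noise within a battery. A green
recovery test therefore establishes that the estimators recover a planted
signal under the stated noise model on this geometry — not that they would
localize the published region in real data.

## Numerical choices and degenerate inputs

* Ellipsoid rasterization is strict (`< 1`): a voxel center exactly on the
  surface is outside, so 2 mm radii at 2 mm spacing hit exactly one voxel.
* Excluded voxels carry NaN in written maps; the inclusion mask is written
  alongside. NIfTI I/O is a minimal NIfTI-1 implementation (no NIfTI
  package exists in the supported environment): sform affine, uint8 masks,
  float32 maps, gzip via connections; cross-checked against nibabel.
* Permutation p values use the (B+1) convention except under exhaustive
  enumeration, where the identity permutation is in the set and p is an
  exact proportion.
* Constant outcomes yield t = 0 (guarded against projection round-off) and
  a zero SVR map with a warning.
* Zero-SD classification inputs flag nobody, with a warning; zero cells in
  the 2×2 table error with a pointer to the 0.5 continuity-correction flag
  (the pipeline applies it automatically and records that it did).
* `dice()` of two empty masks is 0 with a warning.
* dTLVC in the full pipeline scales by each subject's *total* lesion size
  before subsetting to included voxels, so a subject whose whole small
  lesion falls below the inclusion threshold contributes an all-zero row
  rather than crashing the fit.

## Known limitations

The permutation scheme shuffles the raw outcome (the stated design), not
Freedman–Lane residuals; with strong covariate effects its FWER control is
approximate, though calibrated in our null simulations (empirical FWER
0.05–0.06 at α = 0.05). The rbf back-projection is a heuristic sensitivity
map, not a primal weight. Published full-cohort quantities (cluster volumes
and coordinates, Dice 0.52/0.86, within-subgroup statistics, battery
correlations r = 0.91–0.95) require the non-public patient data and are
validation context only — the package reproduces the machinery, and the
reconstructed contingency analysis, not those maps.
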