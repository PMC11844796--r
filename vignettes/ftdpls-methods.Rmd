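---
title: "Methods: brain-cognition PLS and subtype classification in FTD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-cognition PLS and subtype classification in FTD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftdpls)
```

## The problem

Frontotemporal dementia (FTD) presents as three core clinical variants —
behavioural variant FTD (bvFTD) and the semantic (svPPA) and non-fluent
(nfvPPA) variants of primary progressive aphasia — whose overlapping
symptoms make subtype diagnosis difficult. Structural MRI processed with
deformation-based morphometry (DBM) yields a per-subject vector of
regional volume-change values (here 102 atlas parcels: Jacobian
contraction reads as atrophy, expansion as ventricular/sulcal
enlargement). The package links this brain block to a battery of
cognitive and clinical scores through two-block partial least squares
(PLS), compares the resulting brain-cognition associations between
variants, classifies the variant from the latent scores with a bagged
discriminant ensemble, and quantifies longitudinal change of the latent
scores. Because the clinical data this design targets are access
restricted, a synthetic-cohort generator with planted ground truth stands
in for them; every stage is tested against that truth.

## The model

With `X` (n subjects x p_x cognition columns) and `Y` (n x p_y brain
columns) both column z-scored, the cross-block correlation matrix
`R = X'Y/(n-1)` is decomposed by SVD,

    R = U diag(d) V',

giving latent variables (LVs): paired salience vectors `u_k`, `v_k` and a
singular value `d_k`. The effect size of LV k is its covariance explained,
`d_k^2 / sum_j d_j^2`, computed over the full rank and unaffected by
truncation. Subject expression of a pattern is the projection score
`X u_k` (cognition side) and `Y v_k` (brain side); with the `(n-1)`
convention the sample covariance of the paired scores equals `d_k`
exactly, an identity the test suite checks at `1e-8`.

Conventions that pin down the numbers:

* **Standardization** always uses the unbiased SD (divisor `n-1`), so the
  correlation matrix, the singular values and the score covariance agree.
* **Permutation test** (default 500): rows of the X block are permuted,
  `R` and its SVD recomputed, and each rank-k singular value is compared
  rank-to-rank against the observed one. P-values use the add-one rule
  `(1 + #exceedances)/(n_perm + 1)` — finitely many permutations cannot
  certify `p = 0`. Comparing covariance-explained fractions instead is
  available via `statistic = "covexp"`. Rank-wise nulls are conservative
  for the leading LV and can flag late-rank LVs whose observed `d_k`
  exceeds the uniformly deflated permuted spectrum; the number of retained
  LVs is the count of `p < 0.05`, unadjusted.
* **Bootstrap ratios** (default 500): subjects are resampled with
  replacement jointly across blocks, each resample re-z-scored and
  re-decomposed, each LV sign-aligned to the original by the dot product
  of the concatenated `[u; v]`. `BSR = original weight / bootstrap SE`;
  a variable contributes reliably when `|BSR| >= 1.959964` (the 95% CI
  criterion). No Procrustes rotation is applied across resamples — sign
  alignment only — so BSRs near degenerate (tied) singular values are
  conservative; ties in `d` are broken by input column order at `1e-12`.
* **w-scores** (sensitivity branch): for each variable an OLS fit on
  controls with intercept + age + sex + education predicts the healthy
  expectation; the patient w-score is the residual divided by the control
  residual standard error (divisor `n - p - 1`). Sex is encoded 0/1
  (F/M). The pipeline defaults to z-scoring raw values and treats
  w-scoring as a sensitivity analysis, since the two orderings are not
  distinguishable from the published description.

## Group contrasts

Per retained LV, the OLS model
`cognition_score ~ brain_score * variant` is fit with dummy coding and
all three pairwise intercept and slope contrasts are extracted by
reference-level rotation; estimates are invariant to the chosen reference
(checked to `1e-8`). The FDR family is the six contrasts (3 pairs x
{intercept, slope}) within one LV, adjusted by Benjamini-Hochberg via
`stats::p.adjust`; the family definition is a design choice — published
tables report per-LV blocks without stating the family. Tests are
two-sided.

## Subtype classifier

The classifier is a bagging ensemble of `B = 100` pooled-covariance
Gaussian linear discriminant learners (B is configurable; the common
bagging default is used because the reference protocol does not state a
count). Each learner trains on a with-replacement resample of the
training fold; draws missing a class are redrawn. When a pooled
covariance is numerically singular (small folds), a ridge
`1e-6 * trace(S)/p` is added and escalated tenfold until the Cholesky
succeeds. Prediction is by majority vote; ties break by the highest mean
class posterior across learners, then lexicographic class order — a
deterministic rule chosen because the reference implementation's
tie-breaking is unspecified.

Evaluation uses stratified 10-fold cross-validation repeated over
randomized splits (stratification is a design choice forced by a
30-subject minority class). Accuracy is pooled over folds within a
repeat; reported SDs are over repeats. Per-class metrics are one-vs-rest:
sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, balanced accuracy
their mean — an identity the acceptance suite also verifies against
externally published benchmark tables.

Two leakage regimes are exposed. The default replicates the reference
protocol: the PLS is fit once on all baseline patients (labels never
enter the PLS or the standardization) and only the classifier is
cross-validated. Because even unsupervised full-sample PLS lets test
subjects influence the saliences, `cv_repeated_nested()` refits the
z-scoring and the SVD inside every training fold and projects held-out
subjects onto frozen saliences.

Feature sets mirror the reference design: `maximal` (both blocks' LV
scores + age/sex/education), `brain_only`, `cognition_only`, and a
`minimal` model whose PLS is refit on a short battery (CDR sum of
boxes/language/behaviour + Boston Naming Test) against the full brain
block. Validation protocols include severity-filtered subsamples
(threshold rule, e.g. CDR sum of boxes < 1.5), age matching by greedy
nearest-age selection without replacement within a 5-year caliper
(smallest group as reference; infeasible matching errors out with
diagnostics), and longitudinal hold-out: follow-up rows, standardized
with baseline statistics, are predicted only by ensembles whose training
folds exclude that subject's baseline row. The subject-level exclusion is
asserted at run time and surfaced in the report's audit field.

## Longitudinal change

The yearly rate of change of a score is
`(followup - baseline)/interval_years`, computed per subject, LV and
block from a subject-keyed join (mis-paired inputs raise an error rather
than silently misalign). Within-cohort change uses two-sided paired
t-tests; because the published analysis reports the LV x block family
without a stated correction, raw and BH-adjusted p-values are both
emitted. Between-variant rate contrasts use pairwise two-sample
t-statistics with Tukey-Kramer familywise adjustment through the
studentized-range distribution (pooled within-group variance across all
three groups, df = N - g), which accommodates the unbalanced group
sizes; Welch t-statistics are available by flag, while the Tukey p-values
keep the classical pooled variance. If both visits carry identical
scores the paired test returns `t = 0, p = 1`; a non-zero constant shift
has zero difference variance and is flagged as degenerate instead of
fabricating a p-value.

## The synthetic cohort generator

`sim_config()` defaults describe the study conditions: 70/36/30 patients
(bvFTD/svPPA/nfvPPA) and 50 controls; 12 cognition columns named after a
standard FTD battery (CDR subscales, MMSE, BNT, PPVT, CVLT, digit span,
fluency — names carry no semantics) and 102 brain columns; four planted
LVs with within-group latent correlations (0.7, 0.55, 0.4, 0.3);
demographics matched to the published cohort (group-specific age, sex
proportion, education truncated at >= 8 years); small linear
age/sex/education effects added to every raw variable; follow-up
intervals drawn from N(1.03, 0.44^2) years truncated positive, with
group-specific yearly drift of the latent scores (svPPA fastest on LV-1,
matching the published longitudinal contrast).

Mechanism: per LV, the two blocks' latent scores are bivariate normal
with correlation `rho_k`; group shifts move both blocks' latent means, so
`rho` is the *within-group* correlation (shifts add shared between-group
variance on top). Observed blocks are
`latent %*% t(salience) + demographics + iid Gaussian noise`.

Design choices worth restating:

* **Salience construction.** Each planted salience has a `sparsity`
  fraction of exactly-zero loadings at random positions; the non-zero
  loadings share one magnitude with random signs, and support-preserving
  alternating projections enforce exact within-block orthogonality before
  renormalization. Equal magnitudes are the standard identifiable
  construction under column standardization: z-scoring rescales every
  column by its own SD, so unequal loading magnitudes would be flattened
  toward a sign pattern and the planted vector would not be the
  population singular vector of the correlation matrix.
* **Residual SD** defaults to 0.3. This was calibrated once against the
  joint set of published signatures — four LVs detectable by permutation
  at the published sample size, saliences recoverable from ~150 patients,
  a leading covariance-explained share in the 40-55% range, and
  three-class accuracy in the 80s — because the covariance-explained
  profile alone is scale-free and does not pin the noise level.
* **Null cohorts** require `n_latent = 0`; the blocks are then
  independent given zero demographic effects, which is how the
  permutation-calibration experiments configure them.
* **Gaussian residuals are an assumption**: the marginal distribution of
  regional DBM values is not published. Site effects are available as
  additive offsets but default off, and no site harmonization is
  modelled.

What passing tests on this generator do *not* show about real data:
regional DBM values are simulated directly (no images, registrations or
Jacobians), residuals are homoscedastic and uncorrelated within block
(real atrophy is spatially correlated), cognitive scores are continuous
Gaussians (real scales are bounded and discrete), and missingness beyond
education is not modelled. Classifier accuracies on synthetic cohorts
therefore validate the protocol, not the clinical effect size.

## Problem sizes used by the shipped experiments

The analysis scripts and the acceptance computation run at the study's
scale (136 patients, 12 x 102 blocks, 500 permutations and bootstraps,
32 follow-ups) with 10-fold CV over 20-25 repeats of 100-learner
ensembles; Monte-Carlo calibrations use 50-200 replicate cohorts with
200 permutations each. These sizes were chosen so every experiment
re-runs from scratch in minutes on a single core while keeping
Monte-Carlo error well inside the asserted margins.

## Known limitations

* Rank-wise permutation nulls can admit more "significant" late-rank LVs
  than planted, since permutation deflates the whole spectrum; the
  covexp-based statistic is offered as an alternative.
* Sign alignment without Procrustes rotation makes bootstrap SEs
  conservative near degenerate spectra.
* Salience recovery at n = 150 with 102 regions is limited by sampling
  noise of the cross-block correlation matrix: occasional rotation
  between LVs with adjacent singular values is expected, so recovery is
  assessed by its typical (median) value over replicate cohorts.
* The interaction regressions are plain OLS: no robust or mixed-effects
  variants, and only the two-visit difference design is supported
  longitudinally.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
manifest <- run_pipeline(cfg, out_dir = "ftdpls-run",
                         n_perm = 500, n_boot = 500,
                         k = 10, n_repeats = 20, B = 100)
```

The numbered scripts under `analysis/` run the same stages piecewise
(simulate, preprocess, PLS, contrasts, classify, longitudinal), each
reading only the serialized artifacts of the previous stage, printing
what it found, and writing its tables under `results/analysis/`.
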