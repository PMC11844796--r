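# ftdpls

Brain–cognition partial least squares and subtype classification for
frontotemporal dementia (FTD) cohorts.

## What this is for

FTD presents as three clinical variants — behavioural variant FTD
(bvFTD), semantic variant PPA (svPPA) and non-fluent variant PPA
(nfvPPA) — whose overlapping symptoms complicate subtype diagnosis.
Given a cohort table with regional atrophy values (deformation-based
morphometry over a 102-parcel atlas) and a cognitive test battery, this
package provides, for researchers in neuroimaging and biostatistics:

* **Behavioural two-block PLS**: with z-scored blocks `X` (cognition) and
  `Y` (brain), the cross-block correlation matrix `R = X'Y/(n−1)` is
  decomposed as `R = U Δ V'`. Each latent variable (LV) pairs a cognitive
  salience `u_k` with an atrophy salience `v_k`; its effect size is the
  covariance explained, `d_k² / Σ d_j²`. Inference: permutation tests on
  the singular values (rank-to-rank, add-one p-values) and bootstrap
  ratios (weight / bootstrap SE, thresholded at the 95% CI criterion).
  Subject expression of a pattern is the projection score `X u_k` /
  `Y v_k`; `cov(Xu_k, Yv_k) = d_k` exactly.
* **w-scores**: covariate-adjusted z-scores relative to a control-group
  regression on age, sex and education.
* **Variant contrasts**: per LV, `cognition score ~ brain score × variant`
  with all pairwise intercept/slope contrasts and per-LV BH-FDR.
* **Subtype classifier**: a bagging ensemble of pooled-covariance Gaussian
  linear discriminant learners with majority vote, evaluated by stratified
  10-fold CV over repeated randomized splits, with per-class
  sensitivity/specificity/balanced accuracy, severity- and age-matched
  validation subsamples, a leakage-free nested-PLS mode, and longitudinal
  hold-out with subject-level exclusion.
* **Longitudinal rates**: yearly change of LV scores,
  `(follow-up − baseline)/interval`, with paired change tests and
  Tukey–Kramer-corrected between-variant contrasts.
* **A synthetic cohort generator** with planted saliences, latent
  correlations, group shifts, demographic confounds and follow-up drift,
  so the full pipeline is testable without restricted clinical data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort at the published scale (70/36/30 patients + 50 controls, 12
cognition × 102 brain columns, 32 one-year follow-ups):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_pls.R
Rscript analysis/04_contrasts.R
Rscript analysis/05_classify.R
Rscript analysis/06_longitudinal.R
```

Stage 3 prints, for the seed shipped in the scripts:

```
5 LV(s) significant at permuted p < 0.05; top-4 explain 96.5% of cross-block covariance.
LV-1 strongest cognition contributors (by |BSR|):
            variable salience   bsr significant
 digit_span_backward   -0.456 -9.97        TRUE
  digit_span_forward    0.498  7.81        TRUE
    fluency_semantic    0.343  5.56        TRUE
        cdr_language    0.412  4.75        TRUE
         cvlt_memory   -0.254 -4.29        TRUE
LV-1 brain regions passing the 95% BSR criterion: 57 of 102
```

The four planted LVs are recovered (plus one late-rank LV admitted by the
rank-wise permutation null — see the methods vignette), LV-1 explains
57.5% of the cross-block covariance at permuted p = 0.002, and 57 of the
102 regions contribute reliably to its atrophy pattern. Stage 5 then
reports three-class accuracy (mean ± SD over 20 repeated 10-fold CVs,
100-learner ensembles):

```
maximal          82.0% (SD 1.4)   brain only   79.6% (SD 1.4)
cognition only   83.4% (SD 1.1)   minimal      80.3% (SD 1.0)
severity-matched 83.0%            age-matched  75.1%
```

and stage 6 validates the classifier on follow-up visits that were
standardized with baseline statistics and predicted only by models that
never saw the subject's baseline row (73.4%, audit passed). Tables land
under `results/analysis/`; `run_pipeline()` performs the same sequence as
one call and writes a manifest with seeds and artifact checksums.

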