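---
title: "Methods: molecular-enriched connectivity, normative deviations, and transdiagnostic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular-enriched connectivity, normative deviations, and transdiagnostic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(molnorm)
```

This vignette documents the models implemented in `molnorm`, the
assumptions behind them, the parameters a user may want to change, the
synthetic-data generator that stands in for clinical data, and the
numerical and design decisions taken where the methodology leaves room.

## 1. Receptor-enriched connectivity estimation

The estimator is a two-step multiple regression ("dual regression" against
molecular templates). Let `Y` be the in-mask voxel × time BOLD matrix and
`M` the voxel × K matrix of molecular density templates.

**Template conditioning.** Each template is min–max rescaled to `[0, 1]`
within the mask (`rescale_templates()`). Rescaling is affine per map, so it
changes neither pairwise template correlations nor the subspace spanned
with an intercept; it only standardises the scale of the stage-1
coefficients. A constant map cannot be rescaled and raises an error.
Collinearity of the template design is screened with variance inflation
factors (`compute_vif()`), `VIF_k = 1/(1 − R²_k)`; values ≥ 5 warn but do
not stop the analysis, and perfect collinearity is reported as `Inf`.

**Stage 1** (`stage1_spatial_regression()`): for each timepoint the in-mask
volume is demeaned across voxels and regressed on the K rescaled maps plus
an intercept. The demeaning plus intercept removes the global signal level
of each volume (including any site-constant offset), so the system time
series capture fluctuations *within* the molecular distribution, not global
intensity. A rank-deficient template design is a hard error naming the
offending systems.

**Stage 2** (`stage2_temporal_regression()`): each system time series is
z-scored (unit-variance regressors make betas comparable across systems and
give the scale covariance property: scaling the BOLD by c scales both the
stage-1 series and the stage-2 betas by c), and every in-mask voxel's time
series is regressed on the K normalised series plus an intercept. Positive
betas mean coupling to the system's dominant fluctuation, negative betas
anti-correlation.

**Parcellation** (`parcellate()`): voxel betas are averaged within the
integer-labelled ROIs of an atlas on the identical grid. An ROI with no
in-mask voxels yields `NA` with a warning — never a silent drop — so the
subject × ROI × system array keeps a stable shape. No confound regressors,
smoothing or resampling are applied anywhere: preprocessing is declared
upstream, and grid mismatches (shape or affine beyond 1e-4) are hard
errors.

Both stages are exact least squares via QR; the test suite checks them
against an explicit pseudo-inverse oracle to 1e-8 on random instances.

## 2. Hierarchical Bayesian normative model

For each (ROI, system) cell, healthy training values follow

    y_i = b0 + b_age * age_i + b_sex * sex_i + u_site(i) + eps_i
    u_s   ~ N(0, tau^2)
    eps_i ~ N(0, sigma_s(i)^2)

Age is in years (uniform 18–88 in the default synthetic cohort), sex is
coded 0/1, and the site offsets and site-specific noise variances are tied
across sites through shared priors. Noise is homoskedastic in the
covariates within a site — only site-linked variance is modelled.

**Split.** `stratified_split()` holds out `ceiling(test_fraction * N)`
healthy subjects (default `test_fraction = 0.30`), allocated across sites
by largest remainder with both partitions forced nonempty at every site;
membership within site is randomised by the seed. This rounding rule is
what makes a 496 + 111 cohort split into 150 + 33 held-out subjects.

**Inference engines.** Both engines fit the identical model and share one
output contract (posterior means and covariances of the fixed effects,
shrunken site offsets with uncertainties, site noise variances):

* `mode = "eb"` (default): an empirical-Bayes/EM iteration — weighted least
  squares for the fixed effects, conjugate shrinkage `u_s =
  m_s · tau²/(tau² + sigma_s²/n_s)` of the site residual means, EM updates
  for `tau²`, and site noise variances partially pooled towards their
  common mean (pseudo-observation weight 4). Deterministic, convergent in
  a few dozen iterations, and fast enough to fit thousands of cells; the
  cross-term between fixed-effect and site-offset uncertainty is neglected
  (it is carried exactly in the Gibbs mode).
* `mode = "gibbs"`: a fully conjugate Gibbs sampler. Priors are weakly
  informative and scale-adaptive: `beta_j ~ N(0, (10 sd(y)/sd(x_j))²)`,
  `tau² ~ IG(2, 0.5 var(y))`, `sigma_s² ~ IG(2, b)` with a shared
  `b ~ Gamma(2, 2/var(y))` hyperprior tying the site noises. Conjugate
  Inverse-Gamma/Gamma forms were chosen over half-Normal scale priors so
  every conditional is exact; at these weakly-informative settings the
  posterior is insensitive to the choice. The fixed effects and site
  offsets are drawn as one joint Gaussian block — sampling them separately
  mixes poorly because the intercept and the offsets trade off along a
  ridge. Two chains of 1000 warmup + 1000 draws by default; a cell is
  flagged non-converged when its largest split-R̂ exceeds 1.05 (a Gibbs
  sampler has no divergence diagnostic, so convergence is R̂-based), and
  non-converged cells are excluded downstream exactly like cells with
  non-positive explained variance.

With a single site the offset is unidentifiable next to the intercept; the
declared fallback drops the random effect (`u = 0`) and fits the fixed
effects with a single noise variance.

**Evaluation, retention, scoring.** `explained_variance()` computes
`EV = 1 − SSE/SST` on the held-out healthy subjects from posterior-mean
predictions, with SST about the held-out mean; zero held-out variance flags
the cell `NA`. `retain_rois()` keeps, per system, the ROIs with strictly
positive EV *and* a converged fit; the retention mask is computed from
healthy data only and applied identically to every diagnostic group.
`deviation_scores()` returns `z = (y − ŷ)/σ_pred` with `σ_pred` the full
posterior-predictive sd (fixed-effect uncertainty + site-offset uncertainty
+ site noise) — "prediction uncertainty" is read as full predictive
uncertainty rather than noise sd alone; at training sizes of a few hundred
the two differ by only a few percent, and the full form is what makes
held-out healthy z-scores pool to approximately unit variance. Observed
above prediction gives positive z. Scoring a subject from a site unseen in
training is an error, never an extrapolation. Patients are scored with the
same trained models as the held-out controls. `summary_deviation()` is the
arithmetic mean of z over retained ROIs, per subject and system.

## 3. Symptom reduction

`normalize_symptoms()` z-scores each measure across all patients pooled
transdiagnostically using the population (1/n) standard deviation — the
convention of the standard scaler used in the Python ecosystem this
analysis family comes from. `pca_reduce()` eigendecomposes the Pearson
correlation matrix (equivalent to covariance PCA of the z-scored data; the
eigenvalues of a p-measure table then sum to p), orders components by
eigenvalue, applies no rotation, and retains components with eigenvalue
strictly greater than 1. Component signs are arbitrary in the algebra; they
are fixed deterministically by making the largest-magnitude loading of each
component positive, so repeated runs are bit-identical. Scores are the
standardised data projected on the loadings, using the same pooled-patient
standardisation (healthy controls have no symptom data in the emulated
design, so standardisation is patients-only).

## 4. Similarity and group-level inference

`subject_similarity_matrix()` correlates subjects' feature vectors (all
symptom measures, or one system's deviation z over that system's retained
ROIs — unretained ROIs carry no valid z). Pearson correlation is the
default, matching the "correlation coefficient" convention of this
analysis family; Spearman is exposed as an option. The diagonal is excluded
from every summary, and a subject never enters their own within-group mean.

`friedman_conover()` compares the k related similarity conditions per
subject (within-group, between-group-1, between-group-2). The Friedman
chi-square uses within-subject average ranks in the tie-corrected
Conover–Iman form `n(k−1)(B−C)/(A−C)` (`A` = sum of squared ranks, `B` =
mean squared rank sums, `C` its null expectation), which reduces exactly to
the classical statistic without ties. Post-hoc Conover t statistics are
rank-sum differences over `sqrt(2n(A−B)/((n−1)(k−1)))` — `A − B` is the
within-subject error sum of squares of the ranks — on `(n−1)(k−1)` degrees
of freedom, Bonferroni-corrected over the pairs. Below n = 5 the asymptotic
chi-square null is unreliable, so an exact permutation p for the Friedman
statistic is substituted (full enumeration of within-row rank permutations
when feasible, Monte Carlo otherwise).

`ks_within_group()` compares within-group similarity distributions by
two-sample Kolmogorov–Smirnov test (exact p for small samples via
`stats::ks.test`), Bonferroni-corrected over the full systems × clinical
groups family — 18 for six systems and three clinical groups.
`transdiagnostic_similarity()` averages each patient over all other
patients pooled across diagnoses, and `correlate_transdiag()` correlates it
with the mean-deviation summary and the retained symptom components,
Bonferroni-corrected over systems × targets — 30 for six systems and
(1 summary + 4 components).

**Permutation inference.** `roi_group_anova()` computes a one-way F per
retained (ROI, system) cell and compares it to free permutations of the
group labels — a single-factor design with no repeated measures or family
structure is freely exchangeable under the null. P-values use the
add-one smoothing convention `p = (1 + #(F* ≥ F))/(1 + n_perm)`, so they
are valid at any `n_perm` and never zero. The default `n_perm = 2000`
is configurable, and the seed is mandatory, making all statistics
bit-reproducible. Benjamini–Hochberg FDR is applied across retained ROIs
within each system (and within each system × component family for the
deviation–symptom regression), matching per-network reporting; pairwise
two-sided pooled-variance t contrasts are reported for ROIs passing the
FDR threshold. `deviation_symptom_regression()` uses the Pearson
correlation/t of patient deviations on component scores — for a single
regressor the correlation and the GLM t are monotonically related, and the
t form is reported — with the permutation null obtained by shuffling
component scores across patients. The same ANOVA code path accepts raw
molecular-enriched FC values in place of deviations, which is the
conventional-analysis comparison mode.

`summary_anova()` is a parametric one-way ANOVA with Tukey HSD on the
per-subject summary deviations, and `logistic_auc()` screens a summary
metric with an unregularised single-predictor logistic regression,
reporting the rank (Mann–Whitney) AUC of the fitted probabilities — the
model's coefficient sign sets the direction, so protective effects still
report discrimination above 0.5, and the AUC is invariant to monotone
predictor rescaling. Perfect separation yields AUC 1.0 with the
coefficient flagged non-converged.

## 5. The synthetic-data generator

The generator emulates a two-site design: a larger healthy-ageing cohort
("bank") pooled with a clinical cohort ("clinic") that contributes healthy
controls and three patient groups. A single master seed spawns independent
substreams per component (templates, atlas, cohort, per-subject noise,
symptoms), so outputs are bit-reproducible and componentwise independent.

Two generative levels share one ground truth:

* **Voxel level** (`make_templates()`, `make_bold()`): templates are
  smoothed Gaussian random fields on a spherical mask, orthonormalised and
  mixed with a shared component so every pair attains exactly the target
  correlation (default 0.3, "moderate" overlap), then shifted nonnegative.
  BOLD is the generative inverse of the dual regression: AR(1) latent
  system time courses (lag-1 correlation 0.4, a mild haemodynamic-like
  autocorrelation) scaled by a per-subject network amplitude, mixed
  through the template maps, plus a site offset and white Gaussian noise
  with sd set by `snr` (default 5). Age, sex and site act on the network
  *amplitude*: every system carries a genuine ageing effect of random sign
  (magnitude 0.15–0.35 per age-sd — ageing as the dominant predictable
  source of network-strength variation) with smaller sex and site effects,
  so parcellated FC inherits covariate structure through the estimator
  itself and the explained-variance screen has realistic spatial
  heterogeneity: well-predicted systems retain most ROIs, poorly predicted
  systems retain few.
* **ROI level** (`make_roi_values()`): values drawn directly from the
  normative linear model (per-cell intercept, age slope ~ N(0, 0.02) FC
  units/year, sex offset ~ N(0, 0.3), per-site offsets ~ N(0, 0.5), site
  noise sd uniform 0.8–1.25). This level is used for normative-calibration
  and inference simulations at hundreds of subjects, where voxelwise
  generation would be wasteful.

`inject_deviations()` plants patient effects *after* generation: each
clinical group's affected cells (default 10 ROIs in one system per group,
groups cycling over systems) are shifted by `deviation_effect` (default
−1, i.e. FC below the normative range) in units of the healthy residual sd
at that cell, times a subject-level multiplier uniform on 0.6–1.4. The
multiplier gives within-group severity variation, which is also what
couples symptoms to deviations: `make_symptoms()` builds 28 measures from
4 latent factors (block loadings 0.6–0.9, small cross-loadings, measure
noise sd 0.5 — chosen so the eigenvalue-one criterion cleanly retains the
planted factors), with factor 2 correlated 0.6 with the patient's planted
deviation magnitude. The effect sizes of real group differences are not
known in FC units, so `deviation_effect` is a free parameter of the
simulation, not a calibrated quantity.

What the generator does **not** emulate: motion, drift, physiological
noise, spatial autocorrelation of the noise, non-Gaussian FC
distributions, diagnosis-specific symptom profiles beyond the severity
coupling, and site differences in acquisition length. Passing tests
therefore demonstrate correctness of the estimators and calibration of the
inference under the stated model, not robustness to real-data artefacts.

## 6. Numerical choices and degenerate inputs

* Seeds: a small deterministic hash maps (master seed, purpose) to 32-bit
  substream seeds; all permutation and sampler functions take explicit
  seeds.
* EB iteration: convergence at relative parameter change 1e-10, cap 200
  iterations; noise variances floored at 1e-10 · var(y) so noiseless cells
  remain finite.
* Ties in ranks use midranks throughout; the Conover se of 0 (all
  conditions identical) yields t = 0 rather than 0/0.
* Empty retained sets degrade gracefully: summary deviations become NA
  with a warning, similarity and mapping stages skip or return empty
  tables, and the pipeline completes.
* TSV output writes 9 significant digits with literal `NA` sentinels;
  round trips agree to ~1e-9 relative. Volumes round-trip bit-exactly as
  NIfTI-1 float64.
* Atlas labels are 1-based and must be contiguous; `relabel_atlas()`
  normalises arbitrary positive labels and records the mapping.

## 7. Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to make the statistical checks sharp while staying
lightweight: REACT validation on 10–12-voxel-per-axis grids with 60–120
timepoints; normative calibration on two-site cohorts of 200 per site
(pooled held-out z over ~1900 cell-scores); permutation validity on
200–500 null replicates of 4 × 10 subjects with 199 permutations; power on
4 groups of ~40 with 30 ROIs and 499 permutations; PCA retention on 120
patients × 28 measures. The end-to-end pipeline demo (70 healthy + 45
patients, 20 ROIs, 3 systems) completes in a few seconds in EB mode.

## 8. Interface notes and limitations

The R functions are the primary interface; a thin command-line dispatcher
(`inst/scripts/molnorm.R`) wraps the two end-to-end entry points
(`simulate`, `run-all`) for shell use, and `run_pipeline()` writes every
intermediate artefact plus a JSON manifest so a run directory is
self-describing and exactly reproducible from its config and seed.

Known limitations: no warped or non-Gaussian likelihoods and no
Gaussian-process normative variants; no transfer of normative models to
unseen sites; no voxelwise group inference, TFCE or cluster-extent
correction; no exchangeability blocks for family or repeated-measures
structure; similarity matrices are summarised, not clustered; and the EB
mode's predictive variance omits the fixed-effect × site-offset cross-term
(use the Gibbs mode where that matters).
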