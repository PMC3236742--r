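---
title: "Decoding depression scores from personalized task fMRI with principal component regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding depression scores from personalized task fMRI with principal component regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrfmri)
```

## The problem

Depression severity is usually assessed with self-report instruments such
as the Beck Depression Inventory II (BDI-II, an integer score on 0–63) and
clinical interviews. `pcrfmri` implements a decoding pipeline that instead
*predicts* a subject's BDI-II — and, secondarily, their Adult Attachment
Interview (AAI) coherence-of-mind score on 1–9 — from fMRI activity
recorded while the subject views photographs of their own mother (M), a
female friend (F), and female strangers (S). The working hypothesis is that
activity evoked by attachment figures carries a signal that is
approximately **linear** in depression severity, so a deliberately simple
linear decoder is preferred over flexible classifiers: it is interpretable
(the fitted model is a 3×2 matrix over two spatial activity patterns) and
it is honest about what is being tested — if the linear relationship is
absent, the decoder fails.

## The pipeline

### First-level model

Each run is modelled with the standard event-related GLM. Per condition
$c \in \{M, F, S\}$ the regressor is the event indicator convolved with the
canonical double-gamma haemodynamic response function

$$h(t) \propto g(t;\,6, 1) - \tfrac{1}{6}\, g(t;\,16, 1),$$

where $g(\cdot;\,a, b)$ is the gamma density with shape $a$ and scale $b$:
response peak near 5 s, undershoot near 15 s, 32 s support, peak-normalized
to 1 (`canonical_hrf()`). These are the conventional canonical parameters;
all are arguments, so other choices remain available. Confound regressors
(motion parameters, white-matter mean signal) are accepted as a precomputed
matrix and passed through unchanged — the package neither estimates motion
nor centers confound columns, and documents that any centering is the
caller's responsibility.

Volumes may be spatially smoothed (`gaussian_smooth()`) with a separable
Gaussian kernel of given FWHM (9 mm by default in `subject_contrasts()`),
$\sigma_\text{vox} = \text{FWHM}/(2\sqrt{2\ln 2})/\text{voxel size}$,
reflect boundaries, truncation at $4\sigma$. Smoothing is applied to the
time series before fitting.

Fitting is voxelwise ordinary least squares (`fit_glm()`). No prewhitening
or AR modelling is performed: the synthetic noise model is white by
construction, and this is a documented limitation for real data, whose
temporal autocorrelation would make the per-run contrast variances
optimistic. Contrast effect and variance maps for M–F, M–S and F–S follow
the usual formulas $c^\top\hat\beta$ and
$\hat\sigma^2 c^\top (X^\top X)^{-1} c$, and runs are combined by
inverse-variance fixed-effects averaging (`fixed_effects_combine()`); a
voxel with a zero run variance (possible on noiseless synthetic data) falls
back to the unweighted mean with a warning rather than propagating an
infinite weight.

### ROI selection

Across the sample subjects of a fold, each voxel's contrast value is
regressed on `[intercept, BDI-II, AAI]` — one joint model, both
psychometric covariates together (`group_zmaps()`). Each regressor's $t$
statistic (dof $= n - 3$) is converted to a Z score by matching cumulative
probabilities, $Z = \Phi^{-1}(F_t(t))$, computed on the log scale so the
extreme tails relevant at the cutoff remain accurate. The ROI is the union
over all six (contrast, regressor) maps of voxels with $|Z|$ strictly
greater than 4.265, the three-decimal cutoff whose upper-tail normal
probability sits just below $10^{-5}$ (`select_roi()`).

Three design choices here were genuinely open:

* **Group model.** A desk-scale OLS group model replaces a mixed-effects
  analysis: per-subject variance maps are not used at the group level.
  This keeps the package self-contained and exactly reproducible; it is
  the main deviation from what a full neuroimaging suite would do.
* **Sidedness.** Selection is two-sided by default (`two_sided = TRUE`):
  negative associations are just as informative for a regression decoder
  as positive ones. The one-sided rule is available since the pairing of a
  Z cutoff with a one-tailed $P$ is also a defensible reading.
* **Empty unions.** On weak-signal data a fold's union can be empty. The
  selector then takes the `fallback_k = 50` voxels of largest max-|Z|
  (with a warning), mirroring the nominal ROI size, so leave-one-out folds
  always remain runnable. The fallback never engages on the default
  synthetic conditions.

No cluster-extent filtering is applied: the selection rule is voxelwise,
and contiguity of the resulting ROI is an empirical outcome, not a
constraint.

The feature matrix (`assemble_features()`) concatenates, per subject, the
masked voxel values of the three contrast maps in fixed block order (M–F,
M–S, F–S; voxels sorted by linear index within a block) — with a 50-voxel
ROI, 150 features. A pure re-indexing, no arithmetic. Whether the decoder
should consume contrast *effect* values or per-subject standardized values
is ambiguous; the package uses effect values and exposes
`source = "z"` (effect / per-voxel SD) as an alternative.

### The PCR decoder

Two principal components are extracted from the sample subjects' feature
matrix (`extract_pcs()`): the top right singular vectors of the
column-mean-centered sample matrix. Conventions that the data do not fix
are pinned down deterministically:

* **Centering.** PCA is computed on sample-mean-centered features, and the
  stored sample mean — never the held-out subject's own data — is used
  when projecting a test subject. This prevents test-subject leakage.
* **Sign.** Each component's largest-magnitude loading is made positive,
  so repeated runs are bit-identical.
* **Rank.** A centered $n \times p$ sample supports at most
  $\min(n-1, p)$ components; requesting more is an error. Numerically
  degenerate data within that bound still yield a valid orthonormal basis
  whose trailing components simply explain ~0 variance — so rank-1 data
  report explained fractions $(1, 0)$ rather than erroring.
* **k = 2.** The component count is configurable but defaults to two, the
  dimension at which this decoder is intended to operate.

Each subject's weights row is obtained by OLS of their sample-mean-centered
feature vector on `[PC1, PC2, 1]`, after which the fitted intercept is
discarded and replaced by the constant 1 (`subject_weights()`), giving the
weights-matrix layout $(w_1, w_2, 1)$. Regressing the *raw* vector instead
would shift every subject's $(w_1, w_2)$ by one common constant — the mean
vector's own loadings — which the model map's intercept row absorbs
exactly, so predictions are identical under either convention; the
centered convention is used because it makes the weights interpretable as
deviation-from-sample loadings (the vector `mean + 2·PC1` has weights
exactly $(2, 0, 1)$).

Stacking the sample rows gives $W$ ($n \times 3$) and the measured scores
give $Y$ ($n \times 2$, BDI-II and AAI columns). The model map is the
Moore–Penrose solution

$$\text{ModelMap} = W^{+} Y,$$

computed by SVD with singular values below
$\max(\dim) \cdot \varepsilon \cdot d_{\max}$ treated as zero
(`fit_model_map()`, `pinv()`) — the minimum-Frobenius-norm least-squares
solution, so rank-deficient folds degrade gracefully rather than
exploding. A held-out subject's prediction is the linear map
$[w_1, w_2, 1] \cdot \text{ModelMap}$, never clipped to the instrument
ranges: categorical calls are made on the raw predictions, *depressed* iff
predicted BDI-II $> 13.5$ and *insecure* iff predicted AAI $< 4$, both
strict. The 13.5 cut is the established clinical BDI-II threshold of 14
shifted half a point to bisect continuous predictions; 4 is the
conventional boundary below which AAI coherence indicates insecure
attachment.

### Leave-one-out orchestration

`run_loo()` holds out each subject in turn and recomputes **everything** —
group Z maps, ROI, PC basis, model map — from the remaining $n-1$ subjects
only. Fold-wise ROI recomputation is the only reading consistent with a
valid cross-validation; a single pre-computed ROI would leak every
subject's scores into every fold. The package still emits the full-cohort
ROI (`cohort_roi()`) for inspection and reporting, clearly separated from
the fold masks that generate predictions. The central correctness property
— that perturbing a held-out subject's psychometric scores changes nothing
in their fold — is asserted bit-exactly in the test suite.

Degenerate folds (non-finite predictions, constant regressors) abort the
run with the held-out subject named, rather than being dropped silently.

`evaluate_loo()` reports sensitivity, specificity and agreement in percent
together with their raw fractions (so a printed 92.9% is never ambiguous
about being 13/14), Pearson correlations between predicted and measured
scores, and the AAI classification agreement accompanied by an exact
binomial test against chance. The binomial test is an interpretive choice:
LOO folds share training data, so the independence assumption is
approximate, and the p-value should be read as a calibration aid, not a
formal test.

## The synthetic cohort

No scan data ship with the package; `simulate_cohort()` generates cohorts
with the statistical structure the decoder assumes:

* 14 control + 14 depressed subjects; control BDI-II uniform on the
  integers 0–12, depressed on 11–54 (the observed cohort ranges); AAI on
  [1, 9] with a configurable negative correlation to BDI-II
  (`aai_bdi_weight`, default 0.5, giving $r \approx -0.5$).
* Four 12.6-minute runs at TR = 2 s (378 frames), 2×2×3 mm voxels, with
  21 events per condition per run placed at distinct TR-grid frames in
  randomized order (exactly balanced, never overlapping, one-TR duration).
* A single contiguous cluster of ~50 voxels grown from a random interior
  voxel; condition amplitudes linear in the subject's scores. The
  defaults — Mother amplitude $1 + 0.05\,\text{BDI} - 0.02\,\text{AAI}$,
  Friend $1 + 0.01\,\text{BDI}$, Stranger $1$, noise SD 0.5 — are this
  package's calibration, chosen once to represent a clearly detectable
  effect (group-level |Z| well above the 4.265 cutoff at $n = 27$, voxel
  SNR well below 1 for any single feature); no physical-unit effect sizes
  exist to copy. Depressed subjects therefore show the higher
  Mother-involving contrast activity.
* Noise is i.i.d. Gaussian, white in space and time — the simplest model
  satisfying the GLM's assumptions. The generator plants no drift,
  autocorrelation, motion, or anatomy.

The fast path (`render_contrast_maps()`) emits contrast maps directly;
`render_bold_run()` renders full 4-D time series whose first-level analysis
recovers the planted amplitudes to numerical precision at zero noise,
tying the two routes together. All outputs are pure functions of
`(seed, subject_id, operation)` via per-stream derived seeds, so cohorts
are reproducible element-wise, not just run-wise.

What passing tests on this cohort **do** show: the pipeline's selection,
projection and regression stages are correct, leak-free and deterministic,
and the decoder recovers a planted linear signal (LOO $r \ge 0.9$,
agreement $\ge 90\%$ under the default conditions) while staying at chance
when no signal exists. What they **cannot** show: performance on real
scans, where autocorrelated noise, inter-subject anatomical variability,
motion artifacts, and non-linearities all reduce accuracy. The simulator
validates the machinery, not the clinical claim.

## Worked example

```{r example}
spec <- cohort_spec(seed = 7)
sim <- simulate_cohort(spec)
folds <- run_loo(sim$contrast_sets, sim$records)
report <- evaluate_loo(folds, sim$records)
report

# fold-wise ROI sizes and the full-cohort ROI
range(vapply(folds, `[[`, integer(1), "roi_size"))
roi <- cohort_roi(sim$contrast_sets, sim$records)
length(intersect(roi$indices, sim$truth$cluster_indices))
```

## Numerical and scale choices

Problem sizes were chosen so the whole battery runs comfortably on a
laptop: unit tests use 8×8×6 to 12×12×8 grids; the parameter-recovery and
acceptance runs use the default 20×20×12 grid (4 800 voxels — a
desk-scale stand-in for a whole brain) with the full 28-subject LOO
completing in under a second; the null-calibration check uses 200
pure-noise replicate grids of 1 000 voxels. Tolerances follow the quantity:
algebraic identities at 1e-8 to 1e-12, Monte-Carlo comparisons at 5–15%.

Known limitations, beyond those noted above: NIfTI-1 only (sform preferred
over qform when both are present); OLS group statistics rather than mixed
effects; no slice-timing, registration, or multiple-comparison correction
(the Z threshold is per-voxel by design); predictions are unbounded and
only thresholded, never calibrated as probabilities.
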