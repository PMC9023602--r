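---
title: "Constrained PCA of event-related task fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained PCA of event-related task fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskCPCA)
```

## The analysis in one paragraph

Given parcellated BOLD time series from a fast event-related task, the package
(1) regresses every region's series on a finite impulse response (FIR) basis —
one indicator per acquisition in the 0–18 s window after each of six task
events (threat / non-threat stimuli crossed with correct / incorrect /
non-response) — keeping the predicted, task-related part of the signal;
(2) stacks the predicted matrices over subjects and takes one singular value
decomposition, which yields group-level spatial loadings with subject-level
temporal scores (constrained PCA); (3) back-regresses each subject's component
scores on the same FIR basis to estimate event-locked response curves at the
six post-event acquisitions; (4) compares curve shape between groups with
multilevel growth models selected by a forward likelihood-ratio ladder;
(5) relates each subject's peak component scores to rank-transformed task
accuracy with covariate adjustment and Benjamini–Hochberg FDR over the
20-cell family; and (6) tests whether regional structural difference maps
(cortical thickness, cortical surface area) concentrate inside each
component's suprathreshold regions, using the mean absolute value (MAV)
statistic against spatial-autocorrelation-preserving surrogate maps.

The package ships a synthetic-data generator with complete ground truth, so
every stage can be validated by parameter recovery and null calibration
without access to restricted clinical data.

## The CPCA model

For subject $i$, let $Z_i$ be the volumes × regions matrix after per-region
standardization and $G_i$ the FIR design. Task-related variance is the
least-squares projection $\hat Z_i = G_i G_i^{+} Z_i$ (pseudoinverse
throughout, so designs missing an event type never fail; the deficiency is
recorded). The group decomposition stacks the $\hat Z_i$ over subjects and
factorizes $[\hat Z_1; \dots; \hat Z_n] = U D V^\top$: the columns of $V$ are
common spatial maps, the rows of $UD$ belonging to subject $i$ are that
subject's temporal scores, and $d_k^2 / \sum_j d_j^2$ is the fraction of
task-related variance per component. Each loading column is sign-fixed so its
largest-magnitude entry is positive, making output deterministic across
platforms.

**Lag convention.** Acquisition $k$ (interval $[k\,\mathrm{TR},(k+1)\mathrm{TR})$)
belongs to lag bin $j$ of a trial at $t_0$ iff $k\,\mathrm{TR}-t_0 \in
[j\,\mathrm{TR},(j+1)\mathrm{TR})$; reported lag times are bin midpoints
(1.5, 4.5, …, 16.5 s at TR 3 s), which is why peaks land at half-TR offsets
such as 7.5 or 10.5 s. Trials not aligned to volume boundaries are assigned
by the same interval rule without interpolation.

**Component count.** The retained count is the elbow of the *cumulative*
variance curve by the maximum-distance-to-chord rule (both axes normalized).
On the raw scree curve the same rule collapses to the first large gap, which
is not what "elbow" means for these spectra; on the cumulative curve it
reproduces the intended reading (six components for a sequence like
.37, .08, .07, .05, .04, .03, .005, …). An explicit `n_components` always
overrides the rule.

**Global component.** Among retained components, the one whose loadings have
the highest same-sign fraction is flagged as a global signal fluctuation when
that fraction exceeds 0.90; it is labelled PC0 and the remaining components
are re-indexed PC1…PC(K−1) in variance order, mirroring how such components
are set aside in practice.

**Standardization.** Per-region z-scoring is the default (regions on a common
scale before the group SVD); `"center"` and `"none"` are available. Noiseless
recovery experiments must use `"none"`: for rank-one planted data the region
means are generally not in the design's column space, so centering alone
provably distorts an otherwise exact reconstruction. With realistic noise the
choice is immaterial to calibration and recovery.

## Inference on the maps

Bootstrap significance resamples subjects with replacement, refits the group
decomposition, aligns replicate components to the reference by greedy
maximal-|correlation| matching with sign flips (ties broken by component
order), and forms $z = \text{loading}/\widehat{SE}_{boot}$ with two-sided
normal p-values. The analytic z-ratio is used because a fixed threshold of
$p<10^{-4}$ is unreachable by empirical percentiles at feasible replicate
counts. Calibration was checked on planted-null regions (empirical
false-positive rate at $\alpha=.05$ within [0.03, 0.07]).

The stimulus-independence null multiplies the positive-frequency Fourier
coefficients of every region by random unit phases *shared across regions*:
each region's power spectrum (hence mean and autocovariance) and all lag-0
cross-covariances are preserved exactly while event-locking is destroyed.
Shared phases matter — independent phases would also destroy the spatial
covariance that the null is supposed to keep.

## Growth models

Response-curve estimates for the four response events enter a linear
mixed-effects model per component: post-event time in seconds, centered at
the window midpoint (9 s), raw polynomials up to degree five so coefficients
read as Time^k effects; mandatory covariates age, sex, total brain volume,
mean framewise displacement, handedness and group; a subject random
intercept, with a random time slope tested and kept unless singular
(singular fits are refit without the slope, in fixed order). Estimation uses
lme4; it reaches the zero-variance boundary exactly, which makes the pooled
OLS limit testable to 1e-6 and singular random effects detectable rather
than merely ill-conditioned. Wald t statistics use containment
(within/between subject) degrees of freedom: at the study scale
(116 subjects × 4 events × 6 lags = 2784 rows) within-subject terms carry
~2200 df and between-subject terms ~96, matching the df conventions usual
for this design. Continuous nuisance covariates are z-scored before fitting;
factor covariates constant in a given sample are dropped with a message.

Selection is forward stepwise over a hierarchy-respecting ladder — time
polynomials in increasing degree, then stimulus/response terms and their
time interactions, then group interactions — admitting a term when the ML
likelihood-ratio test improves fit at `alpha_select` (default 0.05); the full
trace (term, LRT, p, decision) is returned and written by the pipeline. The
final model is refit by REML. Under a cubic + group × time² generating model
the ladder recovers exactly that structure in ≥ 80% of replicates at the
generator's noise level, and admits extra terms at about the nominal rate
under pure noise (both are exercised in the test suite).

## Brain–behaviour and structural alignment

Peak scores default to the signed value at the |.|-maximizing lag (earliest
lag on ties; a signed-maximum convention is available). Accuracy is
rank-transformed (average ranks) and z-scored, peaks are z-scored, and each
(component, event type) cell gets its own OLS fit with the mandatory
covariates; the coefficient on the peak is the standardized β. FDR is
Benjamini–Hochberg over exactly the 20 case-group cells; control-group and
group-interaction models are reported separately without joint correction.

MAV is the mean |structural difference| over a component's suprathreshold
cortical regions. Its null distribution comes from variogram-matched
permutation surrogates: values are permuted across regions, smoothed with an
exponential kernel over inter-centroid distances whose bandwidth is chosen to
match the observed short-range variogram, then rank-remapped onto the
original value multiset — so each surrogate is a reassignment of the observed
values with approximately the observed spatial autocorrelation. A
rotation-based engine would need surface geometry; the variogram engine only
needs centroids, which is the package's input contract. The permutation
p-value uses the +1 correction, so p is never zero; BH-FDR runs over the full
component × metric family (6 × 2 = 12 cells by default, including PC0).

## The synthetic-data generator

The generator emulates the emotion-identification task geometry: 60 trials of
5.5 s, ISI jittered in 0.5–18.5 s and affinely rescaled so the run fills
10.5 min exactly (the jitter distribution is not specified by the task
description; uniform-then-rescale is the simplest scheme consistent with the
bounds and total duration), TR 3 s, 214 regions (200 cortical + 14
subcortical), 58 cases and 58 controls. Response classes are sampled per
trial from each subject's accuracy (errors split 2:1 between incorrect and
non-response, the ratio seen in the study population), so all six event
types occur.

Signals are built from planted orthonormal spatial maps times event-locked
curves placed at trial onsets by exactly the FIR bin rule, plus AR(1)
regional noise (φ = 0.3) — so a noiseless run is perfectly deconvolvable by
construction, which anchors the exactness tests. Key design points:

* **Identifiability.** Principal components are orthogonal by construction,
  so planted truth is recoverable only if the planted temporal profiles are
  (near-)orthogonal too. The default curves start from qualitative shapes —
  an early 7.5 s component, a delayed 10.5 s error-sensitive component, a
  valence component with opposite correct/incorrect responses, an early
  salience-like component, a biphasic component — and are then
  orthogonalized across components in the metric of the expected *centered*
  design Gram matrix (estimated over schedules and both accuracy regimes),
  with a 1.4× amplitude ladder so the planted variance order is strict.
* **Global component.** The planted global is a slow shared AR(0.95)
  fluctuation on a near-uniform positive map, not an evoked response; the FIR
  projection captures part of it, reproducing a large same-sign component
  (~35–40% of task-related variance at the default signal scale) that the
  global-component detector flags as PC0.
* **Signal scale.** `signal_scale = 8` puts the task-related variance
  fraction near 0.2 at study scale ("moderate SNR"); it is one knob — the
  drift amplitude tracks it.
* **Group effects.** Case-group curves are modified multiplicatively (the
  error-sensitive component attenuated ×0.7; the biphasic component's late
  lags removed), emulating reduced error-related activation and a lost late
  peak.
* **Behaviour coupling.** Accuracy = group base rate + coupling ×
  cohort-standardized realized peak amplitudes + noise, clipped to [0.02,
  0.995]. Standardizing the peaks makes the coupling independent of the
  planted signal scale; with raw peaks, accuracy would saturate the clip and
  incorrect trials would all but vanish. Because one subject amplitude
  multiplies all of a component's event types, coupling planted on
  incorrect-trial peaks induces genuine association for the same component's
  correct trials as well — recovery tests therefore assert detection in the
  planted cells and calibration under the full null, not per-cell
  specificity.
* **Structural maps.** Cortical-only maps on synthetic sphere centroids:
  exponential-kernel smooth noise, plus (for the surface-area analogue) an
  effect proportional to a chosen component's |loadings|.

What the generator does **not** emulate: hemodynamic nonlinearity and
saturation, voxel-level spatial structure within parcels, scanner drift and
motion artefacts, non-Gaussian noise, and spatially structured loading maps
(planted maps are dense Gaussian vectors). Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to every property of real BOLD data.

## Numerical choices and problem sizes

Pseudoinverses use an SVD with tolerance `max(dim) * eps * d_max`. Bootstrap
replicates that fail to factorize are dropped (error if >10% fail). Permutation
p-values are +1-corrected. Ties in peak extraction break to the earliest lag;
ties in component matching break by component order. Seeds: every stochastic
function takes `rng_seed` and restores the caller's RNG state; the pipeline
derives per-stage seeds deterministically from one master seed (all derived
seeds stay below 2^31).

The validation experiments run at these sizes: exactness checks at 6–10
subjects (noiseless); study-scale recovery at 116 subjects × 214 regions ×
210 volumes; bootstrap calibration over 3 cohorts × 200 replicates
(240 null regions); selection consistency over 25 replicates of 40 subjects;
FDR null calibration over 200 replicate families; MAV type-I over 200 null
maps × 200 surrogates. These sizes give stable Monte-Carlo estimates for the
stated tolerance bands while keeping the full suite in the minutes range.

## Known limitations

* The FIR bins are locked to stimulus onset; response-time locking is not
  implemented (onset locking is the common convention when the alternative is
  unstated).
* Bootstrap inference uses the normal z-ratio approximation; percentile
  intervals are not implemented.
* The variogram surrogate engine approximates, not reproduces, a
  rotation-based null; for parcellations with strongly anisotropic geometry
  the match is only as good as the isotropic exponential kernel allows.
* The exhaustive component-matching used in recovery checks prunes to the
  best 9 candidate columns before enumerating permutations; with more
  components a Hungarian solver would be preferable.
* No varimax or oblique rotation of the solution, and no non-negative
  factorization; the decomposition is reported as the SVD gives it.
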