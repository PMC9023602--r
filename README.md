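# taskCPCA

Constrained principal component analysis (CPCA) of event-related task fMRI,
for researchers who study evoked spatiotemporal brain activity in clinical
case–control cohorts. The package implements the full analysis chain around
the CPCA estimator — finite impulse response (FIR) deconvolution, group
decomposition, event-locked response curves, multilevel growth models,
brain–behaviour association, and alignment of activation maps with regional
structural difference maps — together with a synthetic-data generator that
emulates a fast event-related emotion-identification task with known ground
truth, so every stage is testable by parameter recovery and null calibration.

## The model

For subject $i$ with standardized parcellated BOLD matrix $Z_i$
(volumes × regions) and FIR design $G_i$ (one indicator column per event type
× post-event acquisition bin, six bins spanning 0–18 s at TR 3 s for each of
six task events), the task-related signal is the projection

$$\hat Z_i = G_i G_i^{+} Z_i .$$

One SVD of the row-concatenated $[\hat Z_1;\dots;\hat Z_n] = U D V^\top$
gives group spatial loadings $V$ with subject-level temporal scores (the rows
of $UD$); component $k$ accounts for $d_k^2/\sum_j d_j^2$ of the task-related
variance. A near-uniform-sign component is flagged as the global signal
component (PC0) and the rest are re-indexed PC1…PC5. Back-regression of each
subject's scores on the same FIR basis yields response curves — the mean
component score at each of the six acquisitions after each event type — which
feed linear mixed-effects growth models (polynomials of post-event time,
stimulus/response terms, group interactions; subject random intercepts and
optional time slopes) selected by a forward likelihood-ratio ladder. Peak
scores per (component, event type) predict rank-transformed task accuracy in
covariate-adjusted regressions with Benjamini–Hochberg FDR over the 20-cell
family, and the mean absolute value (MAV) of structural change inside each
component's suprathreshold cortical regions is tested against
variogram-matched surrogate maps that preserve spatial autocorrelation.

## Worked example

```r
library(taskCPCA)

model  <- default_planted_model(rng_seed = 1)        # 5 components + global
cohort <- generate_cohort(12, 12, model,
                          config = list(n_trials = 40, run_duration = 430),
                          rng_seed = 1)
fit <- cpca(cohort, n_components = 6)
summary(fit)
#> CPCA solution (24 subjects, 214 regions, standardization: zscore)
#>  component variance_explained cumulative
#>        PC0           0.382085     0.3821
#>        PC1           0.118669     0.5008
#>        PC2           0.045685     0.5464
#>        PC3           0.031916     0.5784
#>        PC4           0.024402     0.6028
#>        PC5           0.008414     0.6112
```

The six retained components explain 61% of the task-related variance and the
first is flagged as the global component (PC0): its loadings share one sign,
the signature of a global fluctuation rather than an evoked response. Curve
estimation and growth-model selection for the error-sensitive component PC2
(whose case-group response is attenuated in the generator):

```r
curves <- response_curves(fit)
dat    <- growth_data(curves, cohort$covariates, "PC2")
sel    <- select_growth_model(dat)
sel
#> growth-model selection (alpha = 0.05): 15 term(s) selected
#>    time, time2, time3, time4, time5, correct, time:correct, ...,
#>    time:group_case, time2:group_case, time3:group_case, time5:group_case
#> random structure: intercept
sel$fit$coefficients[c(7, 9, 20), c("term", "estimate", "p")]
#>               term   estimate        p
#> 7       group_case -0.8690460 9.95e-04
#> 9            time2 -0.1925000 9.71e-75
#> 20 group_case:time2  0.0150310 5.65e-10
```

The selected model carries significant group × time interactions — the
planted case-group attenuation of this component's response curve, read back
from the fitted trajectories. Downstream, `extract_peak_scores()` +
`rank_accuracy_regression()` return the 20-cell standardized-β table with
q-values, and `mav_permutation_test()` the component × metric alignment
family. `run_pipeline(config)` chains all stages, writes TSV/JSON artifacts
and a provenance manifest, and offers robustness re-runs (high-accuracy
subset; phase-randomized surrogates).

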