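# microstatr

EEG microstate analysis in R: from multichannel resting-state recordings to
microstate classes, their temporal dynamics, condition contrasts and trait
correlations — with a synthetic-cohort generator carrying known ground truth
so that every stage of the pipeline can be validated by parameter recovery.

The package is aimed at electrophysiologists studying how brief, quasi-stable
scalp potential topographies ("microstates", classes A–D in the canonical
resting-state taxonomy) reorganize across experimental conditions — e.g. rest
following emotionally negative versus neutral stimulation — and how their
dynamics relate to stable traits such as neuroticism.

## The model

At each time point *t* the scalp field strength is summarized by the global
field power, the population standard deviation across the *C* electrodes:

    GFP(t) = sqrt( (1/C) * sum_c ( v_c(t) - mean_c v(t) )^2 )

Topographies at local GFP maxima (maximal signal-to-noise) are clustered by a
**polarity-invariant modified k-means**: map *x_t* is assigned to the template
*a_k* maximizing the absolute spatial correlation |corr(x_t, a_k)|, and each
template is updated as the dominant eigenvector of the outer-product sum of
its assigned maps — the polarity-invariant centroid (plain averaging would
cancel, since microstate topographies alternate sign with the oscillatory
carrier). Iteration is coordinate ascent on the global explained variance

    GEV = sum_t ( GFP_t * corr(x_t, a_{L_t}) )^2 / sum_t GFP_t^2 ,

and the number of classes is chosen by a predictive cross-validation
criterion, `CV(k) = sigma2_hat * ((C-1)/(C-1-k))^2`, with the GEV curve
reported and a user override available.

Clustering is two-level (per subject-and-condition, then across the pooled
subject templates), conditions are paired by optimal |spatial correlation|
assignment (Hungarian algorithm) and gated by a topographic permutation test
(TANOVA). The continuous data are then backfit sample-by-sample with a
winner-takes-all rule, giving per class the **mean duration** (ms, from
uncensored runs) and **time coverage** (fraction of labeled time). Statistics
follow the standard repertoire: two-way repeated-measures ANOVA
(class x condition), paired t contrasts with Bonferroni control and Cohen's
d, and Pearson trait correlations with Benjamini–Hochberg FDR control.

## Worked example

Simulate a 12-subject cohort (two conditions, known effects: class C coverage
down and class D coverage up after "fear", trait slopes on both) and run the
full pipeline:

```r
library(microstatr)
mont   <- make_montage(32)
gt     <- ground_truth(mont, k = 4, seed = 1)
spec   <- cohort_spec(n_subjects = 12, n_epochs_per_condition = 2,
                      epoch_s = 20, seed = 2)
cohort <- simulate_cohort(spec, gt)
res    <- run_pipeline(cohort, pipeline_config(band = NULL, n_restarts = 20,
                                               n_perm = 499, seed = 3))
res
#> <ms_pipeline> K = 4 classes, 12 subjects
#>   group GEV: neutral 0.999, fear 0.999
#>   TANOVA p per class: 0.184, 0.425, 0.818, 0.593
#>   interaction p (coverage): 0.000273

subset(res$contrasts, parameter == "time_coverage")
#>  class     parameter      t df        p      d significant threshold
#>      1 time_coverage -2.623 11 0.023694 -0.652       FALSE   0.00625
#>      2 time_coverage -0.476 11 0.643247 -0.217       FALSE   0.00625
#>      3 time_coverage  5.729 11 0.000132  0.959        TRUE   0.00625
#>      4 time_coverage -1.726 11 0.112307 -0.313       FALSE   0.00625
```

Reading the output: the TANOVA gate finds no topographic difference between
the paired classes across conditions (all p > 0.18), as it should — the same
four maps generate both conditions. The class x condition interaction on time
coverage is significant (p = 2.7e-4), and the per-class contrasts
(`neutral - fear`) localize it: the class paired with generative class C
(here class 3, t(11) = 5.73) loses coverage after fear, the strongest
single effect at this cohort size. The recovered group templates match the
generative ones almost perfectly:

```r
pr <- pair_conditions(res$group_fits$neutral, gt$templates)
abs(pr$corr_matrix[cbind(1:4, pr$pairing)])
#> 0.9996 0.9995 0.9997 0.9996
```

The central estimator is also available directly as a classed fit with the
usual methods (`print`, `summary`, `coef`, `predict` = backfitting, `plot`,
`residuals`, `simulate`):

```r
fit <- microstates(cohort$recordings[[1]], k = 4, seed = 4)
seg <- predict(fit, cohort$recordings[[2]])
temporal_params(seg)
```

## Package layout

- `R/synthetic.R`, `R/montage.R`, `R/templates.R` — ground-truth cohort
  generator (semi-Markov state sequences, oscillatory rendering, condition
  and trait effects)
- `R/recording.R`, `R/filters.R` — containers, referencing, GFP, peaks,
  zero-phase Kaiser band-pass / notch / decimation
- `R/microstates.R`, `R/kselect.R` — the modified k-means fit, GEV,
  cluster-count selection, two-level clustering, condition pairing
- `R/backfit.R` — winner-takes-all labeling, temporal parameters, split-half
  reliability
- `R/stats.R` — TANOVA, repeated-measures ANOVA, paired contrasts,
  trait correlations, instrument scoring
- `R/io.R`, `R/pipeline.R` — text cohort format, minimal EDF, the pipeline
  driver with provenance stamping
- `vignettes/microstate-analysis.Rmd` — the methods vignette (model,
  assumptions, design choices, limitations)
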