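# cuejudge

Cognitive modelling of human **multiple-cue judgment** — estimating a
continuous criterion (here, the toxicity of a fictitious bug) from five
binary cues — together with the second-level statistics used to relate
judgment strategies to brain activity.

Two models of the judgment process are pitted against each other per
participant:

- the **cue-abstraction model (CAM)**, a rule-based linear-additive model

  $$\hat c_{CAM} = k + \sum_{i=1}^{5} \omega_i C_i,$$

  with intercept $k$ and cue weights $\omega_i$ as free parameters,
  estimated by analytic least squares;

- the **exemplar-based model (EBM)**, a similarity-based model that
  averages the criteria $c_n$ of stored exemplars, weighted by the
  original context-model similarity

  $$\hat c_{EBM} = \frac{\sum_n S_n c_n}{\sum_n S_n}, \qquad
  S_n = \prod_{i=1}^{5} d_i, \quad
  d_i = \begin{cases} 1 & \text{cue } i \text{ matches} \\
  s_i & \text{cue } i \text{ mismatches,} \end{cases}$$

  with mismatch parameters $s_i \in [0,1]$ estimated by Nelder–Mead
  simplex on a logistic reparameterization.

Model comparison uses leave-one-out cross-validated (or projective)
**RMSD** between predictions and judgments; the smaller RMSD labels the
participant rule- or similarity-based. Around this core the package
provides:

- the additive and multiplicative task environments
  ($c = 15 + 5C_1 + 4C_2 + 3C_3 + 2C_4 + C_5$ and
  $c = 2 + 3e^{(5C_1+4C_2+3C_3+2C_4+C_5)/6}$), item-set generation under
  the study's structural constraints, and item-table I/O;
- synthetic judgment agents and four-condition cohorts (instructed /
  spontaneous × rule / similarity), including the feedback-training
  stopping rule (< 2 RMSE on a block, at most 40 blocks = 640 trials);
- second-level statistics: Pearson correlations of ROI activity with
  model fit (Bonferroni-controlled), the Meng–Rosenthal–Rubin
  dependent-correlation z-test, Fisher's independent-correlation z,
  max-p conjunction analysis with Benjamini–Hochberg FDR, voxelwise
  t / correlation maps, 5-mm-sphere ROI averaging, and the 2×2 mixed
  model-by-condition ANOVA;
- `run_study()`, a seeded end-to-end pipeline, plus a command-line
  dispatcher at `inst/cli/cuejudge.R`.

## Worked example

Simulate a small cohort, fit both models to one instructed-similarity
participant's fMRI-phase judgments with leave-one-out cross-validation,
and classify the strategy:

```r
library(cuejudge)

env <- task_environment("additive")
criterion(rep(1, 5), env)
#> [1] 30

co <- simulate_cohort(cohort_config(n = c(6, 6, 6, 6), seed = 2))
d <- co$data[co$data$participant == "P007" & co$data$phase == "fmri", ]
pool <- exemplar_pool(design_items(co$designs$additive, "memorized"))

fit_e <- fit_judgment(d, model = "ebm", pool = pool, regime = "loocv", seed = 1)
fit_c <- fit_judgment(d, model = "cam", regime = "loocv")
fit_e
#> exemplar-based model fit (leave-one-out CV)
#>   n = 24 observations, RMSD = 2.6441
#>   parameters: s1 = 0.204, s2 = 2.85e-05, s3 = 2.69e-05, s4 = 2.93e-05, s5 = 2.04e-08

classify_strategy(fit_c, fit_e)
#> Strategy: similarity  (RMSD CAM 5.651 vs EBM 2.644, margin 3.006)
```

The held-out RMSD of 2.64 criterion units for the EBM against 5.65 for
the CAM labels this (exemplar-generated) agent similarity-based, as it
should. The full pipeline chains cohort simulation, fitting,
classification, the mixed ANOVA, ROI correlation analyses and a
conjunction analysis:

```r
cfg <- study_config(cohort = cohort_config(n = c(6, 6, 6, 6), seed = 2),
                    fit_regime = "loocv", seed = 99)
run_study(cfg)
#> Synthetic multiple-cue judgment study report
#>   seed 99; 24 participants
#>   strategy classification accuracy: 83.3%
#>   model-by-condition interaction (overall): Mixed ANOVA interaction: F(1, 22) = 30.433, MSE = 1.443, p = 1.523e-05
#>   ROI correlations with model fit:
#>  model           r  n         p threshold significant
#>    ebm -0.34293103 24 0.1008987     0.025       FALSE
#>    cam  0.02302673 24 0.9149483     0.025       FALSE
#>   dependent-correlation z = -1.11, p = 0.2685 (not significant)
#>   conjunction: 53/4096 voxels significant, 83% of the planted region recovered
```

At n = 24 the ROI correlation (population target −0.4 with EBM fit) is
visible but not yet significant at the Bonferroni threshold of 0.025; at
the study-scale cohort of 74 participants it is detected in the large
majority of seeds. Every number in the report is recomputable from the
persisted tables (`study_config(..., output_dir = )`).

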