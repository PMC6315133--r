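---
title: "Models and methods behind cuejudge"
author: "cuejudge maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cuejudge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuejudge)
```

# The task and the two models

In a multiple-cue judgment task a person estimates a continuous
criterion — here the "toxicity" of a bug, on a 0–30 integer response
scale — from five binary cues $C_1,\dots,C_5 \in \{-1,+1\}$. The
environment fixes how cues map to the criterion. In the *additive*
environment

$$c = 15 + 5C_1 + 4C_2 + 3C_3 + 2C_4 + 1C_5,$$

so the criterion spans exactly 0 (all cues low) to 30 (all cues high)
and each cue contributes independently. In the *multiplicative*
environment

$$c = 2 + 3\,e^{(5C_1 + 4C_2 + 3C_3 + 2C_4 + 1C_5)/6},$$

a strictly increasing transform of the same weighted cue sum, so the two
environments rank all 32 profiles identically while the multiplicative
one defeats linear cue abstraction. Additive structure is known to
promote rule-based strategies; multiplicative structure promotes
similarity-based ones.

Two process models formalize the strategies. The **cue-abstraction
model** (CAM) is linear-additive with free intercept $k$ and weights
$\omega_i$ (criterion units):

$$\hat c_{CAM} = k + \sum_{i=1}^5 \omega_i C_i.$$

The **exemplar-based model** (EBM) assumes the judgment is a
similarity-weighted average over stored exemplars $(x_n, c_n)$:

$$\hat c_{EBM} = \frac{\sum_n S_n c_n}{\sum_n S_n},$$

with the original context-model similarity $S_n = \prod_i d_i$, where
$d_i = 1$ on matching cue dimensions and $d_i = s_i \in [0,1]$ on
mismatching ones. Small $s_i$ means strong discounting of mismatching
exemplars (high attention to dimension $i$); $s = (1,\dots,1)$ collapses
to the unweighted pool mean. The EBM prediction is always a convex
combination of the stored criteria, so it cannot extrapolate beyond the
training range — which is exactly what makes extreme test items
diagnostic between the models. Model predictions are *not* clipped to
the response scale: clipping and rounding are properties of the response
process, not of the models, and fits are made to raw model outputs.

The key structural diagnostic is the test phase: new items never seen in
learning, including the two extreme profiles whose criteria lie outside
the training range. CAM extrapolates linearly; EBM is bounded by its
pool. Item sets are generated algorithmically under the study's
constraints (`generate_design()`): the published item tables exist only
as images in the source article, so exact profiles cannot be transcribed
reliably; instead the design preserves the logic — 16 training items, 6
new screening items, the 2 extremes (a 24-item screening test set), 8
new fMRI items disjoint from everything encountered in learning, and 6
memorized items drawn from the training slots. `read_items()` accepts
user-supplied tables so a transcribed published set can be plugged in.
The fMRI item set is additionally resampled until its cue design matrix,
and every leave-one-out subset of it, has full column rank; without this
the cross-validated linear fits would be ill-posed for some folds.

# Estimation and model comparison

CAM estimation is analytic least squares via the QR decomposition; a
Nelder–Mead pathway (`fit_cam(method = "simplex")`) is retained for
audits since both target the same quadratic loss. Rank-deficient cue
matrices raise an error naming the collinear dimensions rather than
silently dropping them.

EBM estimation minimizes the summed squared deviation over
$s \in [0,1]^5$. The bounds are reconciled with an *unconstrained*
simplex search through the logistic reparameterization
$s_i = \mathrm{logit}^{-1}(\eta_i)$. Because the loss surface can be
multimodal, the optimizer restarts from seeded Latin-hypercube points
(default 10 restarts, convergence tolerance `reltol = 1e-8`, at most
1000 iterations — the source procedure does not state its optimizer
settings, so these are package defaults chosen to make restart-to-restart
agreement comfortably tighter than any scientific tolerance used in the
tests). The boundary candidate $s = (1,\dots,1)$ is always evaluated, so
the returned loss never exceeds the pool-mean baseline. If no restart
converges the result is flagged, not silently returned.
`ebm_grid_search()` provides an independent derivative-free cross-check:
a full factorial pass at step 0.2 followed by an exhaustive 0.05-step
pass over the surrounding box (an exhaustive global 0.05 grid would be
$21^5 \approx 4.1$M evaluations; the two-stage scheme reaches 0.05
resolution at the optimum at about 1/50 of that cost).

Model fit is compared by RMSD between predictions and judgments under
three regimes in `fit_judgment()`: in-sample (`plain`), leave-one-out
cross-validation (`loocv`; the default folds iterate over unique test
*items*, so all repeated presentations of the held-out item are
predicted out of sample — an `event` option holds out single
presentations instead), and `projective` (parameters frozen from the
last three training blocks, scored on the test phase). Classification
takes the smaller RMSD, with a tie tolerance of $10^{-6}$ RMSD units
(the source specifies no tie rule; exact ties essentially never occur
with continuous responses).

# What the synthetic cohort emulates

Synthetic agents replace the human cohort. A rule agent responds from
the CAM with the environment's true parameters; an exemplar agent from
the EBM with mismatch parameters $s = (0.2,\dots,0.2)$ over its
condition's pool (memorized items when instructed, training items when
spontaneous). Responses are the model prediction plus additive Gaussian
noise (default SD 2 criterion units — the scale of the learning
criterion, RMSE < 2 — so simulated training phases terminate in a
realistic handful of blocks rather than degenerately at block 1 or
never), clipped to the 0–30 scale and rounded to whole numbers as on the
fMRI response scale. The four default group sizes (19, 19, 16, 20) give
the study's total of 74 participants. Screening responses use the 0–30
criterion scale; the real screening phase typed 0–100 (%) responses, but
the mapping between those scales is unstated in the source, so no
rescaling is invented.

The generator deliberately does *not* emulate: learning dynamics (agents
are stationary; the training stopping rule operates on a fixed-noise
agent), sequential effects, heteroscedastic or non-Gaussian response
noise, individual parameter variability within condition, BOLD time
series or any scanner physics. Passing recovery tests therefore show
that the estimation machinery is correct and that the design separates
the models under the stated conditions — not that real participants obey
either model.

ROI activity is generated by the standard latent-correlation
construction: standardized covariates (the per-subject model fits) enter
a linear combination solving the target population correlations exactly,
plus independent Gaussian noise. Targets are enforced in population, not
per sample; the default pipeline targets (−0.4 with EBM fit, 0 with CAM
fit) mirror a region whose activity tracks similarity-based processing
only. Voxelwise fixtures are white Gaussian noise plus a boxcar effect —
no spatial autocorrelation or smoothing, so FDR behavior is evaluated
under independence, the setting in which Benjamini–Hochberg is exact.

# Second-level statistics

Group maps use pooled-variance two-sample t, one-sample t (feeding the
conjunction), and per-voxel Pearson correlations with a subject
covariate. Zero-variance voxels are flagged and assigned p = 1 rather
than p = 0, and are excluded from no FDR family silently. Conjunction
testing takes the voxelwise *maximum* of the constituent uncorrected
p-volumes — a valid test of the conjunction null (that at least one
effect is absent) — followed by Benjamini–Hochberg FDR over all finite
in-mask voxels at q = 0.05. The max-p statistic is conservative under
the complete null, so the realized false discovery rate sits below q;
the calibration tests assert that bound rather than two-sided equality,
which the statistic cannot attain by construction.

Comparing the two model-fit correlations at one ROI is a *dependent*
correlation problem (both share the ROI variable); the package uses the
Meng–Rosenthal–Rubin z,

$$z = (z_{jk} - z_{jh})\sqrt{\frac{n-3}{2(1 - r_{kh})h}},$$

with $z_{\cdot}$ the Fisher transforms, $\bar r^2$ the mean squared
correlation, $f = \min\{(1-r_{kh})/(2(1-\bar r^2)), 1\}$ and
$h = (1 - f\bar r^2)/(1-\bar r^2)$. The inter-fit correlation $r_{kh}$
is an explicit argument (the source never prints it); the pipeline uses
the observed correlation between the two RMSD vectors. Both one- and
two-tailed p-values are reported, labeled — the source's reported
z = −2.4 with p = 0.008 is consistent with one-tailed reporting, so the
convention is left to the caller, defaulting to two-tailed. At n = 74
the test's simulated type-I error is approximately 0.048 at a nominal
0.05: slightly conservative, as expected of an asymptotic z at finite n.
Independent-group correlation comparisons use Fisher's z. The
model-recovery ANOVA is the 2×2 mixed design actually used (two-level
within factor model, between factor condition); for this design the
interaction F provably equals the squared two-sample t on within-subject
difference scores, an identity the tests exercise on every input, and
degenerate zero-variance strata are mapped to F = 0 (no signal) or
F = ∞, p = 0 (noiseless interaction) instead of 0/0.

Sphere ROI averaging uses center-to-center Euclidean distance with
inclusive boundary on the voxel lattice (origin + index × voxel size, 5
mm default radius). Bonferroni control divides α by the number of
hypotheses per family — two per cluster (one per model), matching the
source's thresholds (e.g. 0.05/8 = 0.00625, displayed as 0.006).

# Reproducibility and problem sizes

Every generative function is a pure function of (arguments, seed); a
single pipeline seed is fanned out into per-stage substreams so stages
are independently reproducible, and `run_study()` twice with one seed is
byte-identical. The test suite exercises the study-scale quantities at
sizes chosen to keep the whole suite in a few minutes while leaving
Monte-Carlo margins wide: 20 cohorts of 74 agents for model recovery
(plain fits; cross-validated and plain fits agree on the direction of
the model × condition interaction, and the LOOCV implementation is
verified against an explicit fold loop separately), 100 seeds for CAM
noise-level recovery, $10^5$ trivariate-normal nulls for the z-test
calibration, $10^4$ null grids of $20^3$ voxels for the conjunction FDR
bound, and 200 ROI draws at n = 74 for the similarity-specific
association.

# Known limitations

- Exact published item sets are not reproduced (source tables are
  images); the algorithmic designs preserve counts and disjointness
  constraints only.
- The generalized context model (graded similarity kernels, response
  scaling) is out of scope; only the original binary-cue context model
  is implemented.
- No information-criterion or Bayesian model comparison; the comparison
  is RMSD-based as in the modelled study.
- The voxelwise machinery performs no cluster-extent or random-field
  inference and no first-level GLM; volumes enter as subject-level
  contrast grids.
- Real-data headline values (published correlations, F statistics, RMSE
  tables) depend on unreleased human data and are not reproduction
  targets; the package reproduces the study's *machinery* and its
  structural predictions.
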