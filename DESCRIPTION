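Package: cuejudge
Title: Cue-Abstraction and Exemplar Models for Multiple-Cue Judgment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cognitive modelling of human multiple-cue judgment: the linear
    cue-abstraction model and the exemplar-based model with the original
    context-model similarity rule, fitted per participant by analytic least
    squares and Nelder-Mead simplex with leave-one-out cross-validated or
    projective RMSD model comparison and strategy classification. Includes
    generators for the judgment task environments (additive and
    multiplicative cue-criterion functions), synthetic judgment agents and
    cohorts with the training stopping rule, synthetic region-of-interest
    activity and voxelwise statistic volumes, and the second-level
    statistics used in model-based neuroimaging: Pearson correlations with
    Bonferroni control, dependent- and independent-correlation z-tests,
    max-p conjunction testing with Benjamini-Hochberg FDR, voxelwise
    two-sample t and correlation maps, sphere ROI averaging, and the 2x2
    mixed ANOVA on model fits.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
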