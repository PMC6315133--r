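#' Fit both judgment models to every participant of a cohort
#'
#' Runs the CAM and the EBM on one phase of each participant's data
#' (fMRI test phase by default), using the exemplar pool appropriate to
#' the participant's condition (memorized items for instructed
#' conditions, training items for spontaneous ones), and classifies the
#' strategy from the paired RMSDs.
#'
#' @param cohort A \code{\link{simulate_cohort}} result, or any cohort
#'   data frame plus \code{designs} in the same layout.
#' @param phase Phase to fit (default "fmri").
#' @param regime Fitting regime passed to \code{\link{fit_judgment}}.
#' @param restarts,seed EBM optimizer settings.
#' @param tie_tol Tie tolerance for \code{\link{classify_strategy}}.
#' @return A data frame with one row per participant: condition, true
#'   strategy, RMSD of each model, classification label and margin.
#' @export
fit_cohort <- function(cohort, phase = "fmri",
                       regime = c("loocv", "plain", "projective"),
                       restarts = 10, seed = 1, tie_tol = 1e-6) {
  stopifnot(inherits(cohort, "judgment_cohort"))
  regime <- match.arg(regime)
  if (regime == "projective") {
    stopf("use projective_fit() directly for the projective regime")
  }
  data <- cohort$data[cohort$data$phase == phase, , drop = FALSE]
  if (nrow(data) == 0L) stopf("no records in phase '%s'", phase)
  ids <- unique(data$participant)
  seeds <- substream_seeds(seed, length(ids))
  pools <- list(
    instructed_rule = exemplar_pool(
      design_items(cohort$designs$additive, "memorized")),
    instructed_similarity = exemplar_pool(
      design_items(cohort$designs$additive, "memorized")),
    spontaneous_rule = exemplar_pool(
      design_items(cohort$designs$additive, "training")),
    spontaneous_similarity = exemplar_pool(
      design_items(cohort$designs$multiplicative, "training"))
  )
  res <- lapply(seq_along(ids), function(i) {
    d <- data[data$participant == ids[i], , drop = FALSE]
    cond <- d$condition[1]
    fc <- fit_judgment(d, model = "cam", regime = regime)
    fe <- fit_judgment(d, model = "ebm", pool = pools[[cond]],
                       regime = regime, restarts = restarts,
                       seed = seeds[i])
    lab <- classify_strategy(fc, fe, tie_tol = tie_tol)
    data.frame(participant = ids[i], condition = cond,
               strategy_true = d$strategy_true[1],
               rmsd_cam = fc$rmsd, rmsd_ebm = fe$rmsd,
               label = lab$label, margin = lab$margin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' ROI-by-model-fit correlation analysis
#'
#' The second-level correlation table of the study: Pearson correlations
#' between per-subject ROI contrast values and the per-subject fit (RMSD)
#' of each model, tested against the Bonferroni-corrected threshold for
#' the two hypotheses per ROI, plus the dependent-correlation z-test for
#' whether the two model correlations differ (using the observed
#' inter-fit correlation as the shared term).
#'
#' @param roi Per-subject ROI contrast values.
#' @param rmsd_ebm,rmsd_cam Per-subject model fits.
#' @param alpha Family-wise level before Bonferroni division (default
#'   0.05).
#' @param z_alpha Level for the dependent-correlation z-test (default
#'   0.05).
#' @param tails Tail convention for the z-test (default "two").
#' @return A list with \code{table} (data frame: model, r, n, p,
#'   threshold, significant), \code{comparison} (a
#'   \code{\link{meng_dependent_z}} result with a \code{significant}
#'   element) and \code{r_fits} (the inter-fit correlation).
#' @export
roi_model_correlations <- function(roi, rmsd_ebm, rmsd_cam, alpha = 0.05,
                                   z_alpha = 0.05,
                                   tails = c("two", "one")) {
  tails <- match.arg(tails)
  ce <- pearson_correlation(roi, rmsd_ebm)
  cc <- pearson_correlation(roi, rmsd_cam)
  thr <- bonferroni_threshold(alpha, 2)
  tab <- data.frame(model = c("ebm", "cam"),
                    r = c(ce$r, cc$r), n = c(ce$n, cc$n),
                    p = c(ce$p, cc$p), threshold = thr,
                    significant = c(ce$p, cc$p) <= thr,
                    stringsAsFactors = FALSE)
  r_fits <- stats::cor(rmsd_ebm, rmsd_cam)
  cmp <- meng_dependent_z(ce$r, cc$r, r_fits, n = length(roi), tails = tails)
  cmp$significant <- cmp$p <= z_alpha
  list(table = tab, comparison = cmp, r_fits = r_fits)
}

#' Study configuration
#'
#' Bundles every tunable of the end-to-end synthetic study: the cohort,
#' the fitting regime, the second-level statistics settings, and the
#' geometry of the synthetic volumes used for the conjunction stage. The
#' single \code{seed} is fanned out into independent per-stage
#' substreams.
#'
#' @param cohort A \code{\link{cohort_config}}.
#' @param fit_regime "loocv" (default) or "plain".
#' @param restarts EBM optimizer restarts.
#' @param alpha Correlation-analysis level (Bonferroni-divided per ROI).
#' @param q FDR level for the conjunction analysis.
#' @param sphere_radius ROI sphere radius in mm (default 5).
#' @param tails Tail convention for the z-tests.
#' @param roi_target_r Population correlations of the synthetic ROI
#'   activity with (EBM RMSD, CAM RMSD); the defaults mirror a region
#'   whose activity tracks similarity-based fit only.
#' @param volume_dim,volume_effect,volume_n Grid, voxelwise effect size
#'   (Cohen's d) and subjects per group of the synthetic conjunction
#'   volumes.
#' @param seed Mandatory integer seed.
#' @param output_dir Optional directory for persisted stage artifacts.
#' @return An object of class \code{"study_config"}.
#' @export
study_config <- function(cohort = cohort_config(), fit_regime = "loocv",
                         restarts = 10, alpha = 0.05, q = 0.05,
                         sphere_radius = 5, tails = "two",
                         roi_target_r = c(ebm = -0.4, cam = 0),
                         volume_dim = c(16, 16, 16), volume_effect = 1.5,
                         volume_n = 16, seed, output_dir = NULL) {
  if (missing(seed)) stopf("a seed is required")
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(cohort = cohort, fit_regime = fit_regime,
                 restarts = restarts, alpha = alpha, q = q,
                 sphere_radius = sphere_radius, tails = tails,
                 roi_target_r = roi_target_r, volume_dim = volume_dim,
                 volume_effect = volume_effect, volume_n = volume_n,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "study_config")
}

#' Run the end-to-end synthetic study
#'
#' Executes the full pipeline deterministically for the configured seed:
#' simulate the cohort, fit and cross-validate both models per
#' participant, classify strategies, run the mixed model-by-condition
#' ANOVAs, generate ROI activity with the configured population
#' correlation to model fit and run the correlation and
#' dependent-correlation analyses, and run a planted-effect conjunction
#' analysis on synthetic group volumes. When \code{output_dir} is set,
#' intermediate tables are persisted as delimited text and the report as
#' JSON.
#'
#' @param config A \code{\link{study_config}}.
#' @return An object of class \code{"study_report"}.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  seeds <- substream_seeds(config$seed, 5L)

  cohort_cfg <- config$cohort
  cohort_cfg$seed <- seeds[1]
  cohort <- simulate_cohort(cohort_cfg)

  fits <- fit_cohort(cohort, regime = config$fit_regime,
                     restarts = config$restarts, seed = seeds[2])
  accuracy <- mean((fits$strategy_true == "rule" & fits$label == "rule") |
                     (fits$strategy_true == "exemplar" &
                        fits$label == "similarity"))

  cond_type <- ifelse(grepl("rule$", fits$condition), "rule", "similarity")
  mode <- ifelse(grepl("^instructed", fits$condition), "instructed",
                 "spontaneous")
  anova <- list(
    overall = mixed_anova_interaction(fits[, c("rmsd_cam", "rmsd_ebm")],
                                      cond_type),
    instructed = mixed_anova_interaction(
      fits[mode == "instructed", c("rmsd_cam", "rmsd_ebm")],
      cond_type[mode == "instructed"]),
    spontaneous = mixed_anova_interaction(
      fits[mode == "spontaneous", c("rmsd_cam", "rmsd_ebm")],
      cond_type[mode == "spontaneous"])
  )

  roi_values <- simulate_roi_activity(
    cbind(fits$rmsd_ebm, fits$rmsd_cam),
    target_r = unname(config$roi_target_r), seed = seeds[3])
  roi <- roi_model_correlations(roi_values, fits$rmsd_ebm, fits$rmsd_cam,
                                alpha = config$alpha, tails = config$tails)

  dimv <- config$volume_dim
  box <- lapply(dimv, function(d) {
    c0 <- max(1L, floor(d / 2) - 1L)
    c0:min(d, c0 + 3L)
  })
  groups <- simulate_stat_volumes(dimv, active = box,
                                  effect = config$volume_effect,
                                  n_subjects = config$volume_n,
                                  groups = 2, seed = seeds[4])
  pvols <- lapply(groups, function(g) voxelwise_one_sample_t(g)$p)
  conj <- conjunction_fdr(pvols, q = config$q)
  active <- attr(groups, "active")
  peak <- which(conj$p_volume$data == min(conj$p_volume$data),
                arr.ind = TRUE)[1, ]
  peak_mm <- conj$p_volume$origin +
    (peak - 1) * conj$p_volume$voxel_size
  group_mean <- stat_volume(
    array(colMeans(volumes_to_matrix(c(groups[[1]], groups[[2]]))), dimv),
    conj$p_volume$voxel_size, conj$p_volume$origin)
  sphere <- sphere_average(group_mean, peak_mm,
                           radius_mm = config$sphere_radius)
  conjunction <- list(
    n_significant = sum(conj$significant),
    n_voxels = conj$n_voxels,
    threshold = conj$threshold,
    active_recovered = if (any(active)) {
      sum(conj$significant & active) / sum(active)
    } else NA_real_,
    false_positive_voxels = sum(conj$significant & !active),
    peak_mm = unname(peak_mm),
    peak_sphere_mean = as.numeric(sphere),
    peak_sphere_voxels = attr(sphere, "n_voxels")
  )

  report <- structure(
    list(config = config, seed = config$seed,
         n_participants = length(cohort$agents),
         fits = fits, classification_accuracy = accuracy,
         anova = anova, roi_values = roi_values, roi = roi,
         conjunction = conjunction,
         provenance = list(
           package = "cuejudge",
           version = as.character(utils::packageVersion("cuejudge")),
           seed = config$seed,
           stage_seeds = seeds)),
    class = "study_report")

  if (!is.null(config$output_dir)) {
    write_study_report(report, cohort, config$output_dir)
  }
  report
}

write_study_report <- function(report, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_data(cohort$data, file.path(dir, "cohort.csv"))
  utils::write.table(report$fits, file.path(dir, "fits.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(participant = report$fits$participant, roi = report$roi_values),
    file.path(dir, "roi.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  json <- list(
    seed = report$seed,
    n_participants = report$n_participants,
    classification_accuracy = report$classification_accuracy,
    anova = lapply(report$anova, function(a) {
      list(F = a$F, df = a$df, MSE = a$MSE, p = a$p)
    }),
    roi_table = report$roi$table,
    roi_comparison = report$roi$comparison[c("r_jk", "r_jh", "r_kh", "n",
                                             "z", "p", "significant")],
    conjunction = report$conjunction,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic multiple-cue judgment study report\n")
  cat(sprintf("  seed %d; %d participants\n", x$seed, x$n_participants))
  cat(sprintf("  strategy classification accuracy: %.1f%%\n",
              100 * x$classification_accuracy))
  cat("  model-by-condition interaction (overall): ")
  print(x$anova$overall)
  cat("  ROI correlations with model fit:\n")
  print(x$roi$table, row.names = FALSE)
  cat(sprintf("  dependent-correlation z = %.2f, p = %.4g (%s)\n",
              x$roi$comparison$z, x$roi$comparison$p,
              if (x$roi$comparison$significant) "significant"
              else "not significant"))
  cat(sprintf("  conjunction: %d/%d voxels significant, %.0f%% of the %s\n",
              x$conjunction$n_significant, x$conjunction$n_voxels,
              100 * x$conjunction$active_recovered,
              "planted region recovered"))
  invisible(x)
}
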