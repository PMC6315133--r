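#' Synthetic judgment agent
#'
#' A stationary synthetic stand-in for a participant: a rule agent
#' responds from the cue-abstraction model, an exemplar agent from the
#' exemplar-based model over its pool. Responses are the model prediction
#' plus additive homoscedastic Gaussian noise, clipped to the response
#' scale and then (optionally) rounded to whole numbers, mirroring an
#' integer response scale.
#'
#' @param strategy "rule" or "exemplar".
#' @param params \code{\link{cam_params}} (rule) or \code{\link{ebm_params}}
#'   (exemplar).
#' @param pool \code{\link{exemplar_pool}}; required for exemplar agents.
#' @param noise_sd Response noise standard deviation (criterion units).
#' @param response_rounding Round responses to integers after clipping?
#' @param response_scale Closed response interval, default \code{c(0, 30)}.
#' @return An object of class \code{"agent_spec"}.
#' @export
agent_spec <- function(strategy = c("rule", "exemplar"), params, pool = NULL,
                       noise_sd = 2, response_rounding = TRUE,
                       response_scale = c(0, 30)) {
  strategy <- match.arg(strategy)
  if (strategy == "rule" && !inherits(params, "cam_params")) {
    stopf("rule agents take cam_params")
  }
  if (strategy == "exemplar") {
    if (!inherits(params, "ebm_params")) stopf("exemplar agents take ebm_params")
    if (!inherits(pool, "exemplar_pool") || pool$n < 1L) {
      stopf("exemplar agents need a nonempty exemplar pool")
    }
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(strategy = strategy, params = params, pool = pool,
                 noise_sd = noise_sd, response_rounding = response_rounding,
                 response_scale = response_scale),
            class = "agent_spec")
}

agent_predict <- function(agent, items) {
  if (agent$strategy == "rule") cam_predict(agent$params, items)
  else ebm_predict(agent$params, agent$pool, items)
}

#' Simulate judgment responses from an agent
#'
#' Response = model prediction + Gaussian(0, noise_sd), clipped to the
#' response scale and then rounded to whole numbers when the agent's
#' \code{response_rounding} is set. Pure function of (agent, items, seed).
#'
#' @param agent An \code{\link{agent_spec}}.
#' @param items Items data frame (or cue profile matrix).
#' @param seed Integer seed.
#' @return Numeric response vector, one per item row.
#' @export
simulate_judgments <- function(agent, items, seed) {
  stopifnot(inherits(agent, "agent_spec"))
  pred <- agent_predict(agent, items)
  resp <- with_seed(seed, pred + stats::rnorm(length(pred), 0, agent$noise_sd))
  resp <- pmin(pmax(resp, agent$response_scale[1]), agent$response_scale[2])
  if (agent$response_rounding) resp <- round(resp)
  resp
}

#' Simulate a training phase with the learning stopping rule
#'
#' The agent judges the training items block by block with outcome
#' feedback (the agent itself is stationary; feedback only drives the
#' stopping rule): training stops at the first block whose RMSE between
#' judgments and criteria falls below \code{rmse_criterion}, or after
#' \code{max_blocks} blocks. With 16-item blocks and the default cap of
#' 40 blocks, a never-learning agent accumulates 640 trials.
#'
#' @param agent An \code{\link{agent_spec}}.
#' @param training_items Items data frame with a \code{criterion} column.
#' @param rmse_criterion Stopping threshold on block RMSE (default 2).
#' @param max_blocks Block cap (default 40).
#' @param seed Integer seed.
#' @return A list with \code{blocks} (data frame: block, item_id, c1..c5,
#'   criterion, response), \code{block_rmse}, \code{terminated_at_block},
#'   \code{met_criterion} and \code{total_trials}.
#' @export
simulate_training_phase <- function(agent, training_items, rmse_criterion = 2,
                                    max_blocks = 40, seed) {
  if (nrow(training_items) == 0L) stopf("training items must be nonempty")
  block_seeds <- substream_seeds(seed, max_blocks)
  out <- vector("list", max_blocks)
  block_rmse <- numeric(0)
  for (b in seq_len(max_blocks)) {
    resp <- simulate_judgments(agent, training_items, block_seeds[b])
    out[[b]] <- cbind(block = b, training_items, response = resp)
    block_rmse[b] <- rmsd(resp, training_items$criterion)
    if (block_rmse[b] < rmse_criterion) break
  }
  blocks <- do.call(rbind, out[seq_len(b)])
  rownames(blocks) <- NULL
  list(blocks = blocks, block_rmse = block_rmse, terminated_at_block = b,
       met_criterion = block_rmse[b] < rmse_criterion,
       total_trials = b * nrow(training_items))
}

cohort_conditions <- c("instructed_rule", "instructed_similarity",
                       "spontaneous_rule", "spontaneous_similarity")

#' Cohort configuration
#'
#' Describes the four-condition, between-subjects study the synthetic
#' cohort emulates: rule-based and similarity-based processing, each
#' either instructed (additive environment; instructed agents skip the
#' training simulation) or spontaneously induced (rule via the additive
#' environment, similarity via the multiplicative environment, both with
#' a feedback training phase under the stopping rule). The default group
#' sizes (19, 19, 16, 20) give the study's total of 74 participants.
#'
#' @param n Named or positional integer vector of group sizes for
#'   instructed_rule, instructed_similarity, spontaneous_rule,
#'   spontaneous_similarity.
#' @param noise_sd Agent response noise SD (criterion units, default 2).
#' @param ebm_s True mismatch parameters of exemplar agents
#'   (default 0.2 on every dimension).
#' @param response_rounding Integer rounding of responses (default TRUE).
#' @param n_fmri_new Number of new fMRI-phase items (default 8).
#' @param fmri_reps Presentations of each fMRI item (default 3).
#' @param screening_reps Presentations of each screening item (default 2).
#' @param seed Integer seed.
#' @return An object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n = c(instructed_rule = 19, instructed_similarity = 19,
                                spontaneous_rule = 16, spontaneous_similarity = 20),
                          noise_sd = 2, ebm_s = rep(0.2, 5),
                          response_rounding = TRUE, n_fmri_new = 8,
                          fmri_reps = 3, screening_reps = 2, seed = 1) {
  if (length(n) != 4L || any(n < 1) || any(n != round(n))) {
    stopf("n must give >= 1 participants for each of the 4 conditions")
  }
  n <- stats::setNames(as.integer(n), cohort_conditions)
  structure(list(n = n, noise_sd = noise_sd, ebm_s = ebm_s,
                 response_rounding = response_rounding,
                 n_fmri_new = n_fmri_new, fmri_reps = fmri_reps,
                 screening_reps = screening_reps, seed = seed),
            class = "cohort_config")
}

#' Simulate a judgment cohort
#'
#' Generates per-participant judgment datasets for the four conditions.
#' The additive and multiplicative environments share one item allocation
#' (same profiles per role; criteria recomputed per environment), so the
#' training range is structurally matched across environments. Rule agents
#' respond from the environment's true linear parameters; exemplar agents
#' respond from the exemplar-based model with mismatch parameters
#' \code{ebm_s} over their condition's pool (the memorized items for
#' instructed conditions, the training items for spontaneous ones).
#' Instructed agents perform only the fMRI test phase; spontaneous agents
#' run training (with the stopping rule), the screening test phase
#' (training + screening-new + extreme items, i.e. 24 distinct exemplars)
#' and the fMRI test phase. The ground-truth agent registry is retained
#' for recovery testing.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return An object of class \code{"judgment_cohort"}: a list with
#'   \code{data} (long data frame: participant, condition, strategy_true,
#'   phase, block, item_id, role, c1..c5, criterion, response),
#'   \code{agents} (per-participant truth), \code{designs} (additive and
#'   multiplicative study designs), \code{training} (per-participant
#'   training summaries) and the echoed \code{config}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- substream_seeds(config$seed, 2L + sum(config$n))
  env_add <- task_environment("additive")
  env_mult <- task_environment("multiplicative")
  design_add <- generate_design(env_add, n_fmri_new = config$n_fmri_new,
                                seed = seeds[1])
  design_mult <- generate_design(env_mult, n_fmri_new = config$n_fmri_new,
                                 seed = seeds[1])
  designs <- list(additive = design_add, multiplicative = design_mult)

  agent_for <- function(condition, design) {
    env <- design$environment
    if (condition %in% c("instructed_rule", "spontaneous_rule")) {
      agent_spec("rule", cam_params(env$intercept, env$weights),
                 noise_sd = config$noise_sd,
                 response_rounding = config$response_rounding,
                 response_scale = env$response_scale)
    } else {
      pool_role <- if (condition == "instructed_similarity") "memorized"
      else "training"
      pool <- exemplar_pool(design_items(design, pool_role))
      agent_spec("exemplar", ebm_params(config$ebm_s), pool = pool,
                 noise_sd = config$noise_sd,
                 response_rounding = config$response_rounding,
                 response_scale = env$response_scale)
    }
  }

  rows <- list()
  agents <- list()
  training <- list()
  pid <- 0L
  for (condition in cohort_conditions) {
    design <- if (condition == "spontaneous_similarity") design_mult
    else design_add
    strategy <- if (grepl("rule$", condition)) "rule" else "exemplar"
    agent <- agent_for(condition, design)
    for (k in seq_len(config$n[[condition]])) {
      pid <- pid + 1L
      id <- sprintf("P%03d", pid)
      agents[[id]] <- list(condition = condition, strategy = strategy,
                           params = agent$params, noise_sd = agent$noise_sd)
      pseeds <- substream_seeds(seeds[2L + pid], 3L)
      recs <- list()
      if (grepl("^spontaneous", condition)) {
        tr_items <- design_items(design, "training")
        tr <- simulate_training_phase(agent, tr_items, seed = pseeds[1])
        training[[id]] <- tr[c("block_rmse", "terminated_at_block",
                               "met_criterion", "total_trials")]
        recs$training <- cbind(phase = "training",
                               tr$blocks[, c("block", "item_id", "role",
                                             paste0("c", 1:5), "criterion",
                                             "response")])
        sc_items <- design_items(design, c("training", "screening_new",
                                           "extreme"))
        sc <- sc_items[rep(seq_len(nrow(sc_items)), config$screening_reps), ]
        recs$screening <- cbind(phase = "screening", block = 1L,
                                sc[, c("item_id", "role", paste0("c", 1:5),
                                       "criterion")],
                                response = simulate_judgments(agent, sc,
                                                              pseeds[2]))
      }
      fm_items <- design_items(design, "fmri_new")
      fm <- fm_items[rep(seq_len(nrow(fm_items)), config$fmri_reps), ]
      recs$fmri <- cbind(phase = "fmri", block = 1L,
                         fm[, c("item_id", "role", paste0("c", 1:5),
                                "criterion")],
                         response = simulate_judgments(agent, fm, pseeds[3]))
      block <- do.call(rbind, recs)
      rows[[id]] <- cbind(participant = id, condition = condition,
                          strategy_true = strategy, block)
    }
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  structure(list(data = data, agents = agents, designs = designs,
                 training = training, config = config),
            class = "judgment_cohort")
}

#' @export
print.judgment_cohort <- function(x, ...) {
  cat(sprintf("Synthetic judgment cohort: %d participants, %d records\n",
              length(x$agents), nrow(x$data)))
  print(x$config$n)
  invisible(x)
}

#' Read and write cohort judgment datasets
#'
#' The long tabular format of a cohort: participant, condition,
#' strategy_true, phase, block, item_id, role, c1..c5, criterion,
#' response.
#'
#' @param data Cohort data frame (e.g. \code{cohort$data}).
#' @param path File path (".tsv" for tab-separated, otherwise CSV).
#' @return \code{read_cohort_data} returns the data frame.
#' @export
write_cohort_data <- function(data, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(data, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_data
#' @export
read_cohort_data <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("participant", "phase", paste0("c", 1:5), "response")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("cohort table lacks columns: %s",
                          paste(miss, collapse = ", "))
  d
}

#' Simulate ROI activity with a controlled correlation to model fit
#'
#' Draws per-subject region-of-interest contrast values whose population
#' correlation with one or more covariates (typically per-subject model
#' fits) is fixed by construction: the standardized covariates enter a
#' latent linear combination solving the target correlations exactly in
#' population, plus independent Gaussian noise. The sample correlation
#' converges to the target as n grows; with a single covariate and
#' \code{|target_r| = 1} the noise term vanishes and the sample
#' correlation is exactly the target.
#'
#' @param fit_values Numeric vector, or an n x k matrix of covariates.
#' @param target_r Target population correlation(s), one per covariate,
#'   each in [-1, 1].
#' @param seed Integer seed.
#' @return Numeric vector of n synthetic ROI contrast values (unit
#'   population variance).
#' @export
simulate_roi_activity <- function(fit_values, target_r, seed) {
  X <- as.matrix(fit_values)
  n <- nrow(X)
  k <- ncol(X)
  if (n < 3L) stopf("at least 3 subjects are required")
  if (length(target_r) != k || any(abs(target_r) > 1)) {
    stopf("target_r needs one value in [-1, 1] per covariate")
  }
  if (any(apply(X, 2, stats::sd) == 0)) stopf("constant fit values")
  Z <- scale(X)
  R <- stats::cor(X)
  a <- solve(R, target_r)
  v <- drop(t(a) %*% R %*% a)
  if (v > 1 + 1e-10) {
    stopf("target correlations are jointly infeasible given the %s",
          "covariate intercorrelations")
  }
  noise_sd <- sqrt(max(1 - v, 0))
  with_seed(seed, drop(Z %*% a) + stats::rnorm(n, 0, noise_sd))
}

#' Simulate subject-level statistic volumes
#'
#' A fixture generator for the voxelwise machinery: per-subject contrast
#' volumes equal to white Gaussian baseline noise plus a constant effect
#' inside an active region. With \code{effect = 0} the group-level
#' p-values are uniform (null calibration); a common active region across
#' groups gives a planted conjunction effect.
#'
#' @param dim Grid dimensions, e.g. \code{c(20, 20, 20)}.
#' @param active Active-region specification: \code{NULL} (none), a
#'   logical array of dimension \code{dim}, or a list of three index
#'   ranges, e.g. \code{list(x = 5:8, y = 5:8, z = 5:8)}.
#' @param effect Effect size added inside the active region, in units of
#'   \code{noise_sd} (so it equals Cohen's d at the voxel level).
#' @param n_subjects Subjects per group.
#' @param groups Number of groups (default 2).
#' @param noise_sd Baseline noise SD (default 1).
#' @param voxel_size,origin Geometry passed to \code{\link{stat_volume}}.
#' @param seed Integer seed.
#' @return A list with one element per group, each a list of
#'   \code{n_subjects} \code{\link{stat_volume}} objects, with the active
#'   mask attached as attribute \code{"active"}.
#' @export
simulate_stat_volumes <- function(dim, active = NULL, effect = 0,
                                  n_subjects = 20, groups = 2, noise_sd = 1,
                                  voxel_size = 2, origin = c(0, 0, 0), seed) {
  if (length(dim) != 3L || any(dim < 1)) stopf("dim must be 3 positive sizes")
  mask <- array(FALSE, dim)
  if (is.list(active)) {
    if (any(vapply(active, max, 0) > dim) || any(vapply(active, min, 1) < 1)) {
      stopf("active region extends outside the grid")
    }
    mask[active[[1]], active[[2]], active[[3]]] <- TRUE
  } else if (!is.null(active)) {
    if (!identical(base::dim(active), as.integer(dim))) {
      stopf("active mask dimensions do not match the grid")
    }
    mask <- active
  }
  signal <- array(0, dim)
  signal[mask] <- effect * noise_sd
  gseeds <- substream_seeds(seed, groups)
  out <- lapply(seq_len(groups), function(g) {
    with_seed(gseeds[g], lapply(seq_len(n_subjects), function(s) {
      stat_volume(signal + array(stats::rnorm(prod(dim), 0, noise_sd), dim),
                  voxel_size = voxel_size, origin = origin)
    }))
  })
  attr(out, "active") <- mask
  out
}
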