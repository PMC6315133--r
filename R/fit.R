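#' Root mean squared deviation
#'
#' Goodness-of-fit criterion used throughout: the root of the mean squared
#' deviation between model predictions and observed judgments.
#'
#' @param predictions,observations Equal-length nonempty numeric vectors.
#' @return A nonnegative number.
#' @export
rmsd <- function(predictions, observations) {
  if (length(predictions) == 0L || length(predictions) != length(observations)) {
    stopf("predictions and observations must be nonempty and equal length")
  }
  sqrt(mean((predictions - observations)^2))
}

#' Judgment performance (RMSE against the true criterion)
#'
#' Performance, as opposed to model fit: the root mean squared error
#' between responses and the environment's true criterion values.
#'
#' @param data A judgment data frame with \code{response} and
#'   \code{criterion} columns (no baseline items).
#' @return A nonnegative number.
#' @export
rmse_vs_criterion <- function(data) {
  if ("role" %in% names(data) && any(data$role == "baseline")) {
    stopf("baseline items carry no criterion; drop them first")
  }
  if (!all(c("response", "criterion") %in% names(data))) {
    stopf("data must have 'response' and 'criterion' columns")
  }
  if (any(!is.finite(data$criterion))) stopf("every record needs a criterion")
  rmsd(data$response, data$criterion)
}

#' Fit the cue-abstraction model
#'
#' Least-squares estimation of the CAM intercept and cue weights. The
#' default is the analytic (QR) solution of the linear least-squares
#' problem; \code{method = "simplex"} minimizes the identical loss with
#' Nelder-Mead instead, kept for fidelity audits (both target the same
#' optimum).
#'
#' @param data Judgment data frame with columns \code{c1..c5} and
#'   \code{response}; at least 6 distinct cue profiles and a full-rank cue
#'   design matrix are required.
#' @param method "analytic" (default) or "simplex".
#' @return A \code{\link{cam_params}} object.
#' @export
fit_cam <- function(data, method = c("analytic", "simplex")) {
  method <- match.arg(method)
  p <- as_profile_matrix(data)
  y <- data$response
  if (is.null(y) || any(!is.finite(y))) stopf("finite responses required")
  if (length(unique(profile_key(p))) < 6L) {
    stopf("at least 6 distinct cue profiles are required to fit CAM")
  }
  X <- cbind(`(Intercept)` = 1, p)
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    dropped <- colnames(X)[dec$pivot[(dec$rank + 1L):ncol(X)]]
    stopf("cue design matrix is rank deficient; collinear dimension(s): %s",
          paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(dec, y)
  if (method == "simplex") {
    sse <- function(b) sum((y - X %*% b)^2)
    opt <- stats::optim(rep(0, 6L), sse, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    beta <- opt$par
  }
  cam_params(beta[1], beta[2:6])
}

# Precomputed EBM loss closure: sum of squared deviations between
# similarity-weighted predictions and responses, as a function of s.
ebm_loss_fun <- function(data, pool) {
  p <- as_profile_matrix(data)
  y <- data$response
  mism <- lapply(1:5, function(i) {
    outer(p[, i], pool$profiles[, i], "!=") * 1
  })
  cn <- pool$criteria
  function(s) {
    S <- s[1]^mism[[1]] * s[2]^mism[[2]] * s[3]^mism[[3]] *
      s[4]^mism[[4]] * s[5]^mism[[5]]
    den <- rowSums(S)
    if (any(den == 0)) return(Inf)
    sum(((S %*% cn) / den - y)^2)
  }
}

#' Fit the exemplar-based model
#'
#' Estimates the five context-model mismatch parameters \eqn{s_i \in
#' [0,1]} by minimizing the summed squared deviation between EBM
#' predictions and responses. The bounded parameters are optimized with
#' the Nelder-Mead simplex on an unconstrained logistic reparameterization
#' (\eqn{s_i = \mathrm{logit}^{-1}(\eta_i)}), restarted from seeded
#' Latin-hypercube starting points; the boundary candidate
#' \eqn{s = (1,\dots,1)} (the unweighted pool mean) is always evaluated as
#' well, so the returned loss never exceeds that baseline.
#'
#' @param data Judgment data frame with \code{c1..c5} and \code{response};
#'   at least 6 observations.
#' @param pool An \code{\link{exemplar_pool}}.
#' @param restarts Number of Latin-hypercube restarts (default 10).
#' @param seed Seed for the restart design.
#' @param maxit,reltol Nelder-Mead control parameters.
#' @return An \code{\link{ebm_params}} object with attributes
#'   \code{"loss"} (achieved summed squared deviation) and
#'   \code{"converged"} (FALSE when no restart converged, with a warning).
#' @export
fit_ebm <- function(data, pool, restarts = 10, seed = 1,
                    maxit = 1000, reltol = 1e-8) {
  stopifnot(inherits(pool, "exemplar_pool"))
  if (is.null(data$response) || nrow(data) < 6L) {
    stopf("at least 6 observations are required to fit EBM")
  }
  loss <- ebm_loss_fun(data, pool)
  starts <- with_seed(seed, lhs::randomLHS(max(1L, restarts), 5))
  starts <- pmin(pmax(starts, 0.02), 0.98)
  best <- NULL
  converged <- FALSE
  for (r in seq_len(nrow(starts))) {
    opt <- stats::optim(stats::qlogis(starts[r, ]),
                        function(eta) loss(stats::plogis(eta)),
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    if (opt$convergence == 0) converged <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  s_hat <- stats::plogis(best$par)
  val <- best$value
  ones <- rep(1, 5)
  if (loss(ones) <= val) {
    s_hat <- ones
    val <- loss(ones)
  }
  if (!converged) {
    warning("EBM simplex failed to converge in every restart; ",
            "returning the best point found", call. = FALSE)
  }
  structure(ebm_params(s_hat), loss = val, converged = converged)
}

#' Grid-search oracle for the exemplar-based model
#'
#' An independent, derivative-free estimate of the EBM parameters by
#' exhaustive factorial grid search, used as a cross-check on the simplex
#' fits: a full coarse pass over [0,1]^5 at \code{coarse_step}, followed
#' by an exhaustive fine pass at \code{step} resolution over the
#' \code{coarse_step}-wide box around the coarse optimum.
#'
#' @inheritParams fit_ebm
#' @param step Fine grid resolution (default 0.05).
#' @param coarse_step Coarse global resolution (default 0.2).
#' @return A list with elements \code{s} (best grid point) and
#'   \code{loss}.
#' @export
ebm_grid_search <- function(data, pool, step = 0.05, coarse_step = 0.2) {
  stopifnot(inherits(pool, "exemplar_pool"))
  p <- as_profile_matrix(data)
  y <- data$response
  n_obs <- nrow(p)
  N <- pool$n
  # rows ordered pool-within-observation
  M <- sapply(1:5, function(i) {
    as.vector(t(outer(p[, i], pool$profiles[, i], "!=") * 1))
  })
  obs_index <- rep(seq_len(n_obs), each = N)
  cn_rep <- rep(pool$criteria, times = n_obs)
  eval_grid <- function(G, chunk = 20000L) {
    K <- nrow(G)
    losses <- numeric(K)
    for (lo in seq(1L, K, by = chunk)) {
      hi <- min(lo + chunk - 1L, K)
      E <- exp(M %*% t(log(pmax(G[lo:hi, , drop = FALSE], 1e-300))))
      den <- rowsum(E, obs_index)
      num <- rowsum(E * cn_rep, obs_index)
      pred <- num / den
      sq <- (pred - y)^2
      sq[den == 0] <- Inf
      losses[lo:hi] <- colSums(sq)
    }
    losses
  }
  search <- function(lower, upper, by) {
    axes <- lapply(1:5, function(i) seq(lower[i], upper[i], by = by))
    G <- as.matrix(expand.grid(axes))
    losses <- eval_grid(G)
    i <- which.min(losses)
    list(s = unname(G[i, ]), loss = losses[i])
  }
  coarse <- search(rep(0, 5), rep(1, 5), coarse_step)
  fine <- search(pmax(coarse$s - coarse_step, 0),
                 pmin(coarse$s + coarse_step, 1), step)
  if (fine$loss <= coarse$loss) fine else coarse
}

params_vector <- function(params) {
  if (inherits(params, "cam_params")) {
    stats::setNames(c(params$k, params$w), c("k", paste0("w", 1:5)))
  } else {
    stats::setNames(params$s, paste0("s", 1:5))
  }
}

predict_params <- function(params, pool, profiles) {
  if (inherits(params, "cam_params")) {
    cam_predict(params, profiles)
  } else {
    ebm_predict(params, pool, profiles)
  }
}

#' Fit a judgment model to individual judgment data
#'
#' The central fitting interface: estimates either the cue-abstraction
#' model (\code{model = "cam"}, analytic least squares) or the
#' exemplar-based model (\code{model = "ebm"}, bounded simplex; see
#' \code{\link{fit_ebm}}) on one participant's judgment data, under one of
#' three fitting regimes:
#' \describe{
#'   \item{\code{"plain"}}{fit and score on the same observations
#'     (in-sample RMSD).}
#'   \item{\code{"loocv"}}{leave-one-out cross-validation: parameters are
#'     re-estimated with each test item held out in turn and the RMSD is
#'     computed over held-out predictions only. By default folds iterate
#'     over unique cue profiles (every presentation of the held-out item
#'     is predicted out of sample); \code{folds = "event"} holds out
#'     single presentations instead.}
#'   \item{\code{"projective"}}{parameters are estimated on the final
#'     three training blocks of \code{data} and frozen; RMSD is computed
#'     on \code{test_data}.}
#' }
#'
#' @param data Judgment data frame with columns \code{c1..c5} and
#'   \code{response} (plus \code{block} for the projective regime).
#' @param model "cam" or "ebm".
#' @param pool An \code{\link{exemplar_pool}}; required for the EBM.
#' @param regime Fitting regime, see Details.
#' @param test_data Test-phase data frame (projective regime only).
#' @param folds "item" (default) or "event" LOOCV folds.
#' @param n_training_blocks Number of final training blocks the projective
#'   regime estimates on (default 3).
#' @param restarts,seed,maxit,reltol Passed to \code{\link{fit_ebm}}.
#' @param cam_method Passed to \code{\link{fit_cam}}.
#' @return An object of class \code{"judgment_fit"} with components
#'   \code{model}, \code{regime}, \code{params} (full-data or
#'   frozen-parameter estimate), \code{fold_params} (per-fold list, LOOCV
#'   only), \code{predictions}, \code{observations}, \code{rmsd} and
#'   \code{converged}. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{fitted}, \code{residuals}, \code{simulate},
#'   \code{plot}.
#' @examples
#' env <- task_environment("additive")
#' items <- data.frame(cue_profiles())
#' items$criterion <- criterion(items, env)
#' items$response <- cam_predict(cam_params(15, 5:1), items)
#' fit <- fit_judgment(items, model = "cam")
#' coef(fit)
#' @export
fit_judgment <- function(data, model = c("cam", "ebm"), pool = NULL,
                         regime = c("plain", "loocv", "projective"),
                         test_data = NULL, folds = c("item", "event"),
                         n_training_blocks = 3, restarts = 10, seed = 1,
                         maxit = 1000, reltol = 1e-8,
                         cam_method = c("analytic", "simplex")) {
  model <- match.arg(model)
  regime <- match.arg(regime)
  folds <- match.arg(folds)
  cam_method <- match.arg(cam_method)
  if (model == "ebm" && is.null(pool)) stopf("the EBM requires a pool")
  cl <- match.call()

  fit_one <- function(d, s) {
    if (model == "cam") fit_cam(d, method = cam_method)
    else fit_ebm(d, pool, restarts = restarts, seed = s,
                 maxit = maxit, reltol = reltol)
  }

  converged_all <- TRUE
  note_conv <- function(params) {
    cv <- attr(params, "converged")
    if (!is.null(cv) && !cv) converged_all <<- FALSE
    params
  }

  if (regime == "plain") {
    params <- note_conv(fit_one(data, seed))
    preds <- predict_params(params, pool, data)
    scored <- data
    fold_params <- NULL
  } else if (regime == "loocv") {
    if (nrow(data) < 7L) {
      stopf("leave-one-out cross-validation needs at least 7 observations")
    }
    fold_id <- if (folds == "item") {
      match(profile_key(data), unique(profile_key(data)))
    } else {
      seq_len(nrow(data))
    }
    fold_seeds <- substream_seeds(seed, max(fold_id))
    preds <- numeric(nrow(data))
    fold_params <- vector("list", max(fold_id))
    for (f in seq_len(max(fold_id))) {
      held <- fold_id == f
      pf <- note_conv(fit_one(data[!held, , drop = FALSE], fold_seeds[f]))
      fold_params[[f]] <- pf
      preds[held] <- predict_params(pf, pool, data[held, , drop = FALSE])
    }
    params <- note_conv(fit_one(data, seed))
    scored <- data
  } else {
    if (is.null(test_data)) stopf("projective fitting requires test_data")
    if (is.null(data$block)) stopf("projective fitting requires a block column")
    blocks <- sort(unique(data$block))
    if (length(blocks) < n_training_blocks) {
      stopf("projective fitting needs at least %d training blocks, got %d",
            n_training_blocks, length(blocks))
    }
    last <- utils::tail(blocks, n_training_blocks)
    params <- note_conv(fit_one(data[data$block %in% last, , drop = FALSE],
                                seed))
    preds <- predict_params(params, pool, test_data)
    scored <- test_data
    fold_params <- NULL
  }

  obs <- scored$response
  if (is.null(obs)) stopf("scored data must have a response column")
  structure(
    list(model = model, regime = regime, params = params,
         fold_params = fold_params, predictions = preds,
         observations = obs, data = scored, pool = pool,
         rmsd = rmsd(preds, obs), n = length(obs),
         converged = converged_all, call = cl),
    class = "judgment_fit"
  )
}

#' Leave-one-out cross-validated model fit
#'
#' Convenience wrapper around \code{\link{fit_judgment}} with
#' \code{regime = "loocv"}.
#'
#' @inheritParams fit_judgment
#' @param ... Further arguments to \code{\link{fit_judgment}}.
#' @return A \code{"judgment_fit"} object.
#' @export
loocv_rmsd <- function(data, model = c("cam", "ebm"), pool = NULL, ...) {
  fit_judgment(data, model = model, pool = pool, regime = "loocv", ...)
}

#' Projective model fit
#'
#' Parameters estimated on the final training blocks and used, frozen, to
#' predict test-phase judgments: a wrapper around
#' \code{\link{fit_judgment}} with \code{regime = "projective"}.
#'
#' @inheritParams fit_judgment
#' @param training Training-phase data frame (with a \code{block} column).
#' @param test Test-phase data frame.
#' @param ... Further arguments to \code{\link{fit_judgment}}.
#' @return A \code{"judgment_fit"} object.
#' @export
projective_fit <- function(training, test, model = c("cam", "ebm"),
                           pool = NULL, ...) {
  fit_judgment(training, model = model, pool = pool, regime = "projective",
               test_data = test, ...)
}

#' Classify judgment strategy from paired model fits
#'
#' Labels a participant (or synthetic agent) as rule-based or
#' similarity-based according to which model attains the smaller RMSD on
#' the same observations, with an explicit tie tolerance.
#'
#' @param fit_cam,fit_ebm \code{"judgment_fit"} objects for the CAM and
#'   EBM fitted to identical observations.
#' @param tie_tol Absolute RMSD difference below which the outcome is a
#'   tie (default 1e-6).
#' @return An object of class \code{"strategy_label"}: the label
#'   ("rule", "similarity" or "tie"), both RMSDs and the margin
#'   \code{rmsd_cam - rmsd_ebm}.
#' @export
classify_strategy <- function(fit_cam, fit_ebm, tie_tol = 1e-6) {
  stopifnot(inherits(fit_cam, "judgment_fit"), inherits(fit_ebm, "judgment_fit"))
  if (fit_cam$model != "cam" || fit_ebm$model != "ebm") {
    stopf("fit_cam must be a CAM fit and fit_ebm an EBM fit")
  }
  if (length(fit_cam$observations) != length(fit_ebm$observations) ||
      any(fit_cam$observations != fit_ebm$observations)) {
    stopf("the two fits must score identical observations")
  }
  margin <- fit_cam$rmsd - fit_ebm$rmsd
  label <- if (abs(margin) <= tie_tol) "tie"
  else if (margin < 0) "rule" else "similarity"
  structure(list(label = label, rmsd_cam = fit_cam$rmsd,
                 rmsd_ebm = fit_ebm$rmsd, margin = margin,
                 tie_tol = tie_tol),
            class = "strategy_label")
}

#' @export
print.strategy_label <- function(x, ...) {
  cat(sprintf("Strategy: %s  (RMSD CAM %.4g vs EBM %.4g, margin %.4g)\n",
              x$label, x$rmsd_cam, x$rmsd_ebm, x$margin))
  invisible(x)
}

#' @export
print.judgment_fit <- function(x, ...) {
  lab <- c(cam = "cue-abstraction model", ebm = "exemplar-based model")[x$model]
  reg <- c(plain = "in-sample", loocv = "leave-one-out CV",
           projective = "projective")[x$regime]
  cat(sprintf("%s fit (%s)\n", lab, reg))
  cat(sprintf("  n = %d observations, RMSD = %.4f\n", x$n, x$rmsd))
  cat("  parameters:",
      paste(sprintf("%s = %.3g", names(params_vector(x$params)),
                    params_vector(x$params)), collapse = ", "), "\n")
  if (!x$converged) cat("  warning: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.judgment_fit <- function(object, ...) {
  res <- stats::residuals(object)
  structure(list(fit = object,
                 coef = coef(object),
                 residual_summary = summary(res),
                 fold_coef = if (!is.null(object$fold_params)) {
                   t(vapply(object$fold_params, params_vector,
                            params_vector(object$params)))
                 }),
            class = "summary.judgment_fit")
}

#' @export
print.summary.judgment_fit <- function(x, ...) {
  print(x$fit)
  cat("\nResiduals (observed - predicted):\n")
  print(x$residual_summary)
  if (!is.null(x$fold_coef)) {
    cat("\nPer-fold parameter estimates:\n")
    print(round(x$fold_coef, 4))
  }
  invisible(x)
}

#' @export
coef.judgment_fit <- function(object, by_fold = FALSE, ...) {
  if (by_fold) {
    if (is.null(object$fold_params)) {
      stopf("per-fold coefficients exist only for LOOCV fits")
    }
    return(t(vapply(object$fold_params, params_vector,
                    params_vector(object$params))))
  }
  params_vector(object$params)
}

#' @export
predict.judgment_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions)
  predict_params(object$params, object$pool, newdata)
}

#' @export
fitted.judgment_fit <- function(object, ...) object$predictions

#' @export
residuals.judgment_fit <- function(object, ...) {
  object$observations - object$predictions
}

#' @export
simulate.judgment_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sigma <- object$rmsd
  draw <- function() object$predictions + stats::rnorm(object$n, 0, sigma)
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  matrix(sims, nrow = object$n, ncol = nsim,
         dimnames = list(NULL, paste0("sim_", seq_len(nsim))))
}

#' @export
plot.judgment_fit <- function(x, ...) {
  plot(x$predictions, x$observations,
       xlab = "Model prediction", ylab = "Observed judgment",
       main = sprintf("%s fit (%s), RMSD = %.2f",
                      toupper(x$model), x$regime, x$rmsd), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
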