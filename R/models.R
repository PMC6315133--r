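#' Cue-abstraction model parameters
#'
#' The cue-abstraction model (CAM) describes a judgment as a linear
#' additive function of the cues,
#' \deqn{\hat c_{CAM} = k + \sum_{i=1}^{5} \omega_i C_i,}
#' with the intercept \eqn{k} and the five cue weights \eqn{\omega_i} free
#' parameters (criterion units).
#'
#' @param k Intercept.
#' @param w Five finite cue weights.
#' @return An object of class \code{"cam_params"}.
#' @export
cam_params <- function(k, w) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k)) {
    stopf("k must be a single finite number")
  }
  if (length(w) != 5L || !all(is.finite(w))) {
    stopf("w must be 5 finite cue weights")
  }
  structure(list(k = as.numeric(k), w = as.numeric(w)), class = "cam_params")
}

#' Exemplar-based model parameters
#'
#' The exemplar-based model (EBM) predicts a judgment as the
#' similarity-weighted average of stored exemplars' criteria,
#' \deqn{\hat c_{EBM} = \frac{\sum_n S_n c_n}{\sum_n S_n},}
#' with probe-exemplar similarity given by the original context model:
#' \eqn{S_n = \prod_i d_i}, where \eqn{d_i = 1} when probe and exemplar
#' coincide on cue dimension \eqn{i} and \eqn{d_i = s_i} when they
#' deviate. The five mismatch parameters \eqn{s_i} lie in the closed
#' interval [0, 1]; small \eqn{s_i} means strong discounting of exemplars
#' that mismatch on dimension \eqn{i}.
#'
#' @param s Five numbers in [0, 1].
#' @return An object of class \code{"ebm_params"}.
#' @export
ebm_params <- function(s) {
  if (length(s) != 5L || !all(is.finite(s)) || any(s < 0) || any(s > 1)) {
    stopf("s must be 5 numbers in [0, 1]")
  }
  structure(list(s = as.numeric(s)), class = "ebm_params")
}

#' Exemplar pool
#'
#' The set of stored (cue profile, criterion) pairs the exemplar-based
#' model averages over.
#'
#' @param profiles An n x 5 cue matrix, or an items data frame with
#'   columns \code{c1..c5} (and \code{criterion}, used when
#'   \code{criteria} is missing).
#' @param criteria Criterion value of each exemplar.
#' @return An object of class \code{"exemplar_pool"}.
#' @export
exemplar_pool <- function(profiles, criteria = NULL) {
  if (is.null(criteria) && is.data.frame(profiles) &&
      "criterion" %in% names(profiles)) {
    criteria <- profiles$criterion
  }
  p <- as_profile_matrix(profiles)
  if (is.null(criteria) || length(criteria) != nrow(p) ||
      !all(is.finite(criteria))) {
    stopf("need one finite criterion per exemplar")
  }
  if (nrow(p) < 1L) stopf("the exemplar pool must be nonempty")
  structure(list(profiles = p, criteria = as.numeric(criteria),
                 n = nrow(p)), class = "exemplar_pool")
}

#' @export
print.exemplar_pool <- function(x, ...) {
  cat(sprintf("Exemplar pool: %d exemplars, criteria in [%g, %g]\n",
              x$n, min(x$criteria), max(x$criteria)))
  invisible(x)
}

#' Cue-abstraction model prediction
#'
#' @param params A \code{\link{cam_params}} object.
#' @param profiles Cue profile(s): vector, matrix or items data frame.
#' @return Numeric vector of predicted criterion values.
#' @examples
#' cam_predict(cam_params(15, c(5, 4, 3, 2, 1)), rep(1, 5))  # 30
#' @export
cam_predict <- function(params, profiles) {
  stopifnot(inherits(params, "cam_params"))
  p <- as_profile_matrix(profiles)
  as.numeric(params$k + p %*% params$w)
}

#' Context-model similarity
#'
#' Similarity between a probe and an exemplar under the original context
#' model: the product over cue dimensions of 1 (match) or \eqn{s_i}
#' (mismatch). Symmetric in its two profile arguments and multiplicative
#' across dimensions.
#'
#' @param probe,exemplar Length-5 cue vectors.
#' @param params An \code{\link{ebm_params}} object.
#' @return A similarity in [0, 1].
#' @export
context_similarity <- function(probe, exemplar, params) {
  stopifnot(inherits(params, "ebm_params"))
  probe <- drop(as_profile_matrix(probe))
  exemplar <- drop(as_profile_matrix(exemplar))
  prod(ifelse(probe == exemplar, 1, params$s))
}

# Similarity matrix between probe profiles (rows) and pool exemplars
# (columns); the workhorse behind ebm_predict and the EBM loss.
similarity_matrix <- function(s, probes, pool_profiles) {
  S <- matrix(1, nrow(probes), nrow(pool_profiles))
  for (i in 1:5) {
    mism <- outer(probes[, i], pool_profiles[, i], "!=")
    S[mism] <- S[mism] * s[i]
  }
  S
}

#' Exemplar-based model prediction
#'
#' Similarity-weighted average of the pool criteria; always a convex
#' combination of the stored criteria, hence bounded by their range. A
#' probe with zero total similarity to the pool (possible when some
#' \eqn{s_i = 0}) has no defined prediction and raises an error rather
#' than silently returning 0/0.
#'
#' @param params An \code{\link{ebm_params}} object.
#' @param pool An \code{\link{exemplar_pool}}.
#' @param probes Cue profile(s) to predict.
#' @return Numeric vector of predicted criterion values.
#' @examples
#' pool <- exemplar_pool(rbind(rep(1, 5), rep(-1, 5)), c(30, 0))
#' ebm_predict(ebm_params(rep(0.5, 5)), pool, c(1, 1, 1, 1, -1))
#' @export
ebm_predict <- function(params, pool, probes) {
  stopifnot(inherits(params, "ebm_params"), inherits(pool, "exemplar_pool"))
  p <- as_profile_matrix(probes)
  S <- similarity_matrix(params$s, p, pool$profiles)
  den <- rowSums(S)
  if (any(den == 0)) {
    stopf("degenerate prediction: probe(s) %s have zero similarity to %s",
          paste(which(den == 0), collapse = ", "), "every pool exemplar")
  }
  as.numeric((S %*% pool$criteria) / den)
}

#' Read and write model parameters
#'
#' Parameter sets are serialized as JSON with explicit field names
#' (\code{k}, \code{w1..w5} for the cue-abstraction model; \code{s1..s5}
#' for the exemplar-based model).
#'
#' @param params A \code{\link{cam_params}} or \code{\link{ebm_params}}.
#' @param path File path.
#' @return \code{read_params} returns the reconstructed parameter object.
#' @export
write_params <- function(params, path) {
  x <- if (inherits(params, "cam_params")) {
    c(list(model = "cam", k = params$k),
      stats::setNames(as.list(params$w), paste0("w", 1:5)))
  } else if (inherits(params, "ebm_params")) {
    c(list(model = "ebm"),
      stats::setNames(as.list(params$s), paste0("s", 1:5)))
  } else {
    stopf("params must be cam_params or ebm_params")
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(as.character(x$model),
         cam = cam_params(x$k, unlist(x[paste0("w", 1:5)], use.names = FALSE)),
         ebm = ebm_params(unlist(x[paste0("s", 1:5)], use.names = FALSE)),
         stopf("unknown model kind in %s", path))
}

#' @export
print.cam_params <- function(x, ...) {
  cat("Cue-abstraction model parameters\n")
  cat(sprintf("  k = %.4g; w = (%s)\n", x$k,
              paste(signif(x$w, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.ebm_params <- function(x, ...) {
  cat("Exemplar-based model parameters\n")
  cat(sprintf("  s = (%s)\n", paste(signif(x$s, 4), collapse = ", ")))
  invisible(x)
}
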