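#' Statistic volume
#'
#' A 3-D grid of voxelwise statistics (t, r or p values) with isotropic
#' voxel size and an origin offset. Voxel indices are 0-based in mm space:
#' the center of voxel (i, j, k) (1-based array index) lies at
#' \code{origin + (index - 1) * voxel_size}.
#'
#' @param data A 3-D numeric array.
#' @param voxel_size Isotropic voxel edge in mm (default 2).
#' @param origin mm coordinate of the first voxel center.
#' @return An object of class \code{"stat_volume"}.
#' @export
stat_volume <- function(data, voxel_size = 2, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stopf("data must be a 3-D array")
  if (voxel_size <= 0) stopf("voxel_size must be positive")
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "stat_volume")
}

#' @export
print.stat_volume <- function(x, ...) {
  cat(sprintf("Statistic volume %s, %g mm voxels, values in [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = " x "), x$voxel_size,
              min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)))
  invisible(x)
}

same_grid <- function(volumes) {
  d <- dim(volumes[[1]]$data)
  all(vapply(volumes, function(v) {
    identical(dim(v$data), d) &&
      isTRUE(all.equal(v$voxel_size, volumes[[1]]$voxel_size)) &&
      isTRUE(all.equal(v$origin, volumes[[1]]$origin))
  }, logical(1)))
}

volumes_to_matrix <- function(volumes) {
  t(vapply(volumes, function(v) as.vector(v$data),
           numeric(length(volumes[[1]]$data))))
}

#' Read and write statistic volumes
#'
#' Volumes are exchanged as a flat text array (one value per line, full
#' precision) plus a small YAML header sidecar (\code{<path>.hdr.yml})
#' carrying grid dimensions, voxel size and origin.
#'
#' @param volume A \code{\link{stat_volume}}.
#' @param path Data file path.
#' @return \code{read_volume} returns the \code{stat_volume}.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "stat_volume"))
  writeLines(format(as.vector(volume$data), digits = 17, trim = TRUE), path)
  yaml::write_yaml(list(dim = dim(volume$data),
                        voxel_size = volume$voxel_size,
                        origin = volume$origin),
                   paste0(path, ".hdr.yml"))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  hdr <- yaml::read_yaml(paste0(path, ".hdr.yml"))
  vals <- as.numeric(readLines(path))
  stat_volume(array(vals, unlist(hdr$dim)),
              voxel_size = hdr$voxel_size, origin = unlist(hdr$origin))
}

#' Pearson correlation with p-value
#'
#' Standard product-moment correlation with a t-distributed p-value;
#' one-tailed p is half the two-tailed p in the direction of the observed
#' correlation.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @param tails "two" (default) or "one".
#' @return An object of class \code{"correlation_result"}: list with
#'   \code{r}, \code{n}, \code{p}, \code{tails}.
#' @export
pearson_correlation <- function(x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(x) != length(y) || length(x) < 3L) {
    stopf("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  p <- unname(ct$p.value)
  if (tails == "one") p <- p / 2
  structure(list(r = unname(ct$estimate), n = length(x), p = p,
                 tails = tails),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, n = %d, p = %.4g (%s-tailed)\n",
              x$r, x$n, x$p, x$tails))
  invisible(x)
}

check_cor_triple <- function(r_jk, r_jh, r_kh) {
  if (any(abs(c(r_jk, r_jh, r_kh)) > 1)) stopf("correlations must lie in [-1, 1]")
  R <- matrix(c(1, r_jk, r_jh, r_jk, 1, r_kh, r_jh, r_kh, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stopf("inconsistent correlation triple (matrix not positive semidefinite)")
  }
}

#' Asymptotic z-test for two dependent correlations
#'
#' Meng-Rosenthal-Rubin test for whether two correlations that share one
#' variable differ: the correlation of j with k versus the correlation of
#' j with h, given the correlation between k and h. The Fisher-z
#' difference is scaled by a factor involving \eqn{r_{kh}} and the mean
#' squared correlation:
#' \deqn{z = (z_{jk} - z_{jh}) \sqrt{\frac{n - 3}{2 (1 - r_{kh}) h}},}
#' with \eqn{\bar r^2 = (r_{jk}^2 + r_{jh}^2)/2},
#' \eqn{f = \min\{(1 - r_{kh}) / (2 (1 - \bar r^2)),\, 1\}} and
#' \eqn{h = (1 - f \bar r^2)/(1 - \bar r^2)}.
#'
#' @param r_jk,r_jh The two correlations sharing variable j.
#' @param r_kh Correlation between the two non-shared variables.
#' @param n Sample size (>= 4).
#' @param tails "two" (default) or "one".
#' @return An object of class \code{"correlation_comparison"}: list with
#'   \code{r_jk}, \code{r_jh}, \code{r_kh}, \code{n}, \code{z}, \code{p},
#'   \code{p_one}, \code{p_two}, \code{tails},
#'   \code{method = "dependent_meng"}.
#' @export
meng_dependent_z <- function(r_jk, r_jh, r_kh, n, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (n < 4) stopf("n must be at least 4")
  check_cor_triple(r_jk, r_jh, r_kh)
  rbar2 <- (r_jk^2 + r_jh^2) / 2
  f <- min((1 - r_kh) / (2 * (1 - rbar2)), 1)
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r_jk) - atanh(r_jh)) * sqrt((n - 3) / (2 * (1 - r_kh) * h))
  p_two <- 2 * stats::pnorm(-abs(z))
  p_one <- stats::pnorm(-abs(z))
  structure(list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n, z = z,
                 p = if (tails == "two") p_two else p_one,
                 p_one = p_one, p_two = p_two, tails = tails,
                 method = "dependent_meng"),
            class = "correlation_comparison")
}

#' Fisher z-test for two independent correlations
#'
#' Compares correlations from two independent groups:
#' \deqn{z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'   {\sqrt{1/(n_1 - 3) + 1/(n_2 - 3)}}.}
#'
#' @param r1,r2 Group correlations, each with |r| < 1.
#' @param n1,n2 Group sizes (>= 4).
#' @param tails "two" (default) or "one".
#' @return An object of class \code{"correlation_comparison"} with
#'   \code{method = "independent_fisher"}.
#' @export
fisher_independent_z <- function(r1, n1, r2, n2, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (abs(r1) >= 1 || abs(r2) >= 1) stopf("|r| must be < 1")
  if (n1 < 4 || n2 < 4) stopf("group sizes must be at least 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p_two <- 2 * stats::pnorm(-abs(z))
  p_one <- stats::pnorm(-abs(z))
  structure(list(r_jk = r1, r_jh = r2, r_kh = NA_real_, n = c(n1, n2),
                 z = z, p = if (tails == "two") p_two else p_one,
                 p_one = p_one, p_two = p_two, tails = tails,
                 method = "independent_fisher"),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  lab <- if (x$method == "dependent_meng") "dependent (Meng-Rosenthal-Rubin)"
  else "independent (Fisher)"
  cat(sprintf("Correlation comparison, %s\n", lab))
  cat(sprintf("  r = %.3f vs %.3f; z = %.3f, p = %.4g (%s-tailed)\n",
              x$r_jk, x$r_jh, x$z, x$p, x$tails))
  invisible(x)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up false discovery rate control at level q: rejects the
#' hypotheses whose BH-adjusted p-value is at most q.
#'
#' @param p Vector of p-values in [0, 1].
#' @param q FDR level in (0, 1).
#' @return A list with \code{reject} (logical mask), \code{critical_p}
#'   (largest rejected raw p, 0 if none), \code{q} and \code{m}.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0L) stopf("empty p-value vector")
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stopf("q must lie in (0, 1)")
  reject <- stats::p.adjust(p, method = "BH") <= q
  list(reject = reject,
       critical_p = if (any(reject)) max(p[reject]) else 0,
       q = q, m = length(p))
}

#' Voxelwise max-p conjunction
#'
#' Conjunction-null combination of several voxelwise p-volumes: the
#' voxelwise maximum of the input p-values, which is a valid p-value for
#' the null that at least one constituent effect is absent. Idempotent,
#' commutative and associative.
#'
#' @param p_volumes List of >= 2 \code{\link{stat_volume}} p-volumes on
#'   identical grids.
#' @return A \code{\link{stat_volume}} of voxelwise maxima.
#' @export
conjunction_max_p <- function(p_volumes) {
  if (length(p_volumes) < 2L) stopf("at least 2 p-volumes are required")
  if (!same_grid(p_volumes)) stopf("p-volumes are not on identical grids")
  out <- Reduce(pmax, lapply(p_volumes, function(v) v$data))
  stat_volume(out, p_volumes[[1]]$voxel_size, p_volumes[[1]]$origin)
}

#' FDR-thresholded conjunction analysis
#'
#' Applies Benjamini-Hochberg FDR at level q to the max-p conjunction
#' volume. The FDR family is all finite in-mask voxels; because the max-p
#' statistic is conservative under the conjunction null, the realized
#' false discovery rate is at most q.
#'
#' @inheritParams conjunction_max_p
#' @param q FDR level (default 0.05).
#' @param mask Optional logical array restricting the voxel family.
#' @return An object of class \code{"conjunction_result"}: list with the
#'   conjunction \code{p_volume}, the FDR \code{threshold} (critical p),
#'   the logical \code{significant} array, \code{q} and \code{n_voxels}.
#' @export
conjunction_fdr <- function(p_volumes, q = 0.05, mask = NULL) {
  conj <- conjunction_max_p(p_volumes)
  in_family <- is.finite(conj$data)
  if (!is.null(mask)) in_family <- in_family & mask
  fdr <- bh_fdr(conj$data[in_family], q)
  sig <- array(FALSE, dim(conj$data))
  sig[in_family] <- fdr$reject
  structure(list(p_volume = conj, threshold = fdr$critical_p,
                 significant = sig, q = q, n_voxels = sum(in_family)),
            class = "conjunction_result")
}

#' @export
print.conjunction_result <- function(x, ...) {
  cat(sprintf("Conjunction (max-p) with BH-FDR at q = %g\n", x$q))
  cat(sprintf("  %d of %d voxels significant (critical p = %.4g)\n",
              sum(x$significant), x$n_voxels, x$threshold))
  invisible(x)
}

finish_voxel_t <- function(tval, se_zero, df) {
  tval[se_zero] <- 0
  p <- 2 * stats::pt(-abs(tval), df)
  p[se_zero] <- 1
  if (any(se_zero)) {
    warning(sprintf("%d zero-variance voxel(s): p set to 1", sum(se_zero)),
            call. = FALSE)
  }
  list(t = tval, p = p, flagged = se_zero)
}

#' Voxelwise two-sample t-test
#'
#' Pooled-variance two-sample t and two-tailed p at every voxel.
#' Zero-variance voxels get t = 0 and p = 1 and are flagged with a
#' warning.
#'
#' @param volumes_a,volumes_b Lists of subject \code{\link{stat_volume}}s
#'   (>= 2 per group) on identical grids.
#' @return A list with \code{t} and \code{p} \code{stat_volume}s,
#'   \code{df}, and a logical \code{flagged} array of zero-variance
#'   voxels.
#' @export
voxelwise_two_sample_t <- function(volumes_a, volumes_b) {
  if (length(volumes_a) < 2L || length(volumes_b) < 2L) {
    stopf("at least 2 subjects per group are required")
  }
  if (!same_grid(c(volumes_a, volumes_b))) stopf("grid mismatch")
  A <- volumes_to_matrix(volumes_a)
  B <- volumes_to_matrix(volumes_b)
  n1 <- nrow(A); n2 <- nrow(B)
  df <- n1 + n2 - 2
  va <- apply(A, 2, stats::var)
  vb <- apply(B, 2, stats::var)
  sp2 <- ((n1 - 1) * va + (n2 - 1) * vb) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  res <- finish_voxel_t((colMeans(A) - colMeans(B)) / se, se == 0, df)
  g <- volumes_a[[1]]
  list(t = stat_volume(array(res$t, dim(g$data)), g$voxel_size, g$origin),
       p = stat_volume(array(res$p, dim(g$data)), g$voxel_size, g$origin),
       df = df, flagged = array(res$flagged, dim(g$data)))
}

#' Voxelwise one-sample t-test
#'
#' One-sample t and two-tailed p at every voxel for a set of subject
#' contrast volumes against a null mean; the group-level test feeding the
#' conjunction analyses.
#'
#' @param volumes List of subject \code{\link{stat_volume}}s (>= 2).
#' @param mu Null mean (default 0).
#' @return As \code{\link{voxelwise_two_sample_t}}.
#' @export
voxelwise_one_sample_t <- function(volumes, mu = 0) {
  if (length(volumes) < 2L) stopf("at least 2 subjects are required")
  if (!same_grid(volumes)) stopf("grid mismatch")
  X <- volumes_to_matrix(volumes)
  n <- nrow(X)
  se <- sqrt(apply(X, 2, stats::var) / n)
  res <- finish_voxel_t((colMeans(X) - mu) / se, se == 0, n - 1)
  g <- volumes[[1]]
  list(t = stat_volume(array(res$t, dim(g$data)), g$voxel_size, g$origin),
       p = stat_volume(array(res$p, dim(g$data)), g$voxel_size, g$origin),
       df = n - 1, flagged = array(res$flagged, dim(g$data)))
}

#' Voxelwise correlation with a subject covariate
#'
#' Pearson correlation between a per-subject covariate (e.g. model fit)
#' and every voxel's values across subjects, with two-tailed t-based
#' p-values; the whole-brain covariate analysis.
#'
#' @param volumes List of subject \code{\link{stat_volume}}s (>= 4).
#' @param covariate Numeric covariate, one value per subject;
#'   nonconstant.
#' @return A list with \code{r} and \code{p} \code{stat_volume}s, plus a
#'   logical \code{flagged} array of zero-variance voxels (r = NA,
#'   p = 1 there).
#' @export
voxelwise_correlation <- function(volumes, covariate) {
  if (length(volumes) < 4L) stopf("at least 4 subjects are required")
  if (length(covariate) != length(volumes)) {
    stopf("need one covariate value per subject")
  }
  if (stats::sd(covariate) == 0) stopf("constant covariate")
  if (!same_grid(volumes)) stopf("grid mismatch")
  X <- volumes_to_matrix(volumes)
  n <- nrow(X)
  sdx <- apply(X, 2, stats::sd)
  flagged <- sdx == 0
  r <- suppressWarnings(as.vector(stats::cor(covariate, X)))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), n - 2)
  p[abs(r) >= 1] <- 0
  r[flagged] <- NA_real_
  p[flagged] <- 1
  if (any(flagged)) {
    warning(sprintf("%d zero-variance voxel(s): r set to NA, p to 1",
                    sum(flagged)), call. = FALSE)
  }
  g <- volumes[[1]]
  list(r = stat_volume(array(r, dim(g$data)), g$voxel_size, g$origin),
       p = stat_volume(array(p, dim(g$data)), g$voxel_size, g$origin),
       flagged = array(flagged, dim(g$data)))
}

#' Spherical ROI average
#'
#' Mean of the voxel values whose center-to-center Euclidean distance
#' from \code{center_mm} is at most \code{radius_mm} (inclusive
#' boundary). Voxel centers lie at \code{origin + (index - 1) *
#' voxel_size}.
#'
#' @param volume A \code{\link{stat_volume}}.
#' @param center_mm Sphere center in mm (length 3), inside the grid.
#' @param radius_mm Sphere radius in mm (default 5).
#' @return The mean value, with the number of contributing voxels
#'   attached as attribute \code{"n_voxels"}.
#' @export
sphere_average <- function(volume, center_mm, radius_mm = 5) {
  stopifnot(inherits(volume, "stat_volume"))
  d <- dim(volume$data)
  lo <- volume$origin
  hi <- volume$origin + (d - 1) * volume$voxel_size
  if (any(center_mm < lo) || any(center_mm > hi)) {
    stopf("sphere center lies outside the grid")
  }
  ax <- lapply(1:3, function(i) {
    lo[i] + (seq_len(d[i]) - 1) * volume$voxel_size - center_mm[i]
  })
  dist2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  inside <- dist2 <= radius_mm^2 + 1e-9
  if (!any(inside)) stopf("no voxel center falls inside the sphere")
  structure(mean(volume$data[inside]), n_voxels = sum(inside))
}

#' Mixed 2 x 2 ANOVA interaction on model fits
#'
#' The repeated-measures ANOVA of the model-recovery analysis: model fit
#' (CAM vs EBM RMSD) as a two-level within-subjects factor and group
#' (rule- vs similarity-inducing condition) as the between-subjects
#' factor, reporting the model-by-group interaction from the
#' within-subjects error stratum. For the two-level within factor this F
#' equals the squared two-sample t on within-subject difference scores.
#'
#' @param values An n x 2 numeric matrix or data frame of within-subject
#'   fits (columns: the two models), no missing cells.
#' @param group Length-n group labels; >= 2 groups with >= 2 subjects
#'   each.
#' @return An object of class \code{"anova_result"}: list with \code{F},
#'   \code{df} (numerator, denominator), \code{MSE}, \code{p} and
#'   \code{effect = "interaction"}.
#' @export
mixed_anova_interaction <- function(values, group) {
  values <- as.matrix(values)
  if (ncol(values) != 2L) stopf("values must have exactly 2 within-levels")
  if (nrow(values) != length(group)) stopf("one group label per subject")
  if (any(!is.finite(values))) stopf("missing cells are not allowed")
  group <- factor(group)
  if (nlevels(group) < 2L || any(table(group) < 2L)) {
    stopf("at least 2 groups with at least 2 subjects each are required")
  }
  n <- nrow(values)
  long <- data.frame(
    subject = factor(rep(seq_len(n), 2L)),
    group = rep(group, 2L),
    model = factor(rep(c("m1", "m2"), each = n)),
    value = c(values[, 1], values[, 2])
  )
  fit <- stats::aov(value ~ group * model + Error(subject / model),
                    data = long)
  tab <- summary(fit)[["Error: subject:model"]][[1]]
  row <- grep("group:model", rownames(tab))
  err <- grep("Residuals", rownames(tab))
  Fval <- tab[row, "F value"]
  pval <- tab[row, "Pr(>F)"]
  # degenerate zero-variance strata: no interaction signal gives F = 0,
  # a noiseless interaction gives F = Inf, p = 0
  tol <- .Machine$double.eps * sum(long$value^2)
  if (tab[err, "Mean Sq"] <= tol) {
    if (tab[row, "Mean Sq"] <= tol) {
      Fval <- 0; pval <- 1
    } else {
      Fval <- Inf; pval <- 0
    }
  }
  structure(list(F = Fval,
                 df = c(tab[row, "Df"], tab[err, "Df"]),
                 MSE = tab[err, "Mean Sq"],
                 p = pval,
                 effect = "interaction"),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Mixed ANOVA %s: F(%d, %d) = %.3f, MSE = %.3f, p = %.4g\n",
              x$effect, x$df[1], x$df[2], x$F, x$MSE, x$p))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level.
#' @param m Number of tests in the family (>= 1).
#' @return \code{alpha / m}.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stopf("m must be at least 1")
  alpha / m
}
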