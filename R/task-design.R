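#' Judgment task environment
#'
#' Constructs the cue-criterion environment of the multiple-cue judgment
#' task: five binary cues (values -1 or +1) map to a continuous criterion
#' ("toxicity") either through a linear additive function,
#' \deqn{c = 15 + 5 C_1 + 4 C_2 + 3 C_3 + 2 C_4 + 1 C_5,}
#' or through a multiplicative (exponential) function of the same weighted
#' cue sum,
#' \deqn{c = 2 + 3 e^{(5 C_1 + 4 C_2 + 3 C_3 + 2 C_4 + 1 C_5)/6}.}
#' The additive criterion spans 0--30 for the default constants; the
#' multiplicative criterion is a strictly increasing transform of the same
#' weighted sum, so the two environments rank all cue profiles identically.
#'
#' @param kind "additive" or "multiplicative".
#' @param intercept Additive intercept (criterion units).
#' @param weights Five positive, strictly decreasing cue weights.
#' @param mult_offset,mult_scale,mult_divisor Constants of the
#'   multiplicative criterion function.
#' @param response_scale Closed integer response interval, default
#'   \code{c(0, 30)}.
#' @return An object of class \code{"judgment_env"}.
#' @examples
#' env <- task_environment("additive")
#' criterion(rep(1, 5), env)   # 30
#' criterion(rep(-1, 5), env)  # 0
#' @export
task_environment <- function(kind = c("additive", "multiplicative"),
                             intercept = 15, weights = c(5, 4, 3, 2, 1),
                             mult_offset = 2, mult_scale = 3,
                             mult_divisor = 6, response_scale = c(0, 30)) {
  kind <- match.arg(kind)
  if (length(weights) != 5L || !all(is.finite(weights))) {
    stopf("weights must be 5 finite numbers")
  }
  if (any(diff(weights) >= 0) || any(weights <= 0)) {
    stopf("weights must be strictly decreasing and positive")
  }
  if (length(response_scale) != 2L || response_scale[1] >= response_scale[2]) {
    stopf("response_scale must be an interval c(lower, upper), lower < upper")
  }
  structure(
    list(kind = kind, intercept = intercept, weights = weights,
         mult_offset = mult_offset, mult_scale = mult_scale,
         mult_divisor = mult_divisor, response_scale = response_scale),
    class = "judgment_env"
  )
}

#' @export
print.judgment_env <- function(x, ...) {
  cat("Judgment environment:", x$kind, "\n")
  if (x$kind == "additive") {
    cat(sprintf("  c = %g + sum(w_i * C_i), w = (%s)\n",
                x$intercept, paste(x$weights, collapse = ", ")))
  } else {
    cat(sprintf("  c = %g + %g * exp(sum(w_i * C_i) / %g), w = (%s)\n",
                x$mult_offset, x$mult_scale, x$mult_divisor,
                paste(x$weights, collapse = ", ")))
  }
  cat(sprintf("  response scale: [%g, %g]\n",
              x$response_scale[1], x$response_scale[2]))
  invisible(x)
}

#' Criterion functions
#'
#' \code{additive_criterion} and \code{multiplicative_criterion} evaluate
#' the two environment kinds on one or more cue profiles;
#' \code{criterion} dispatches on \code{env$kind}.
#'
#' @param profiles A length-5 cue vector, an n x 5 matrix of cue values
#'   (each -1 or +1), or an items data frame with columns \code{c1..c5}.
#' @param env A \code{\link{task_environment}}.
#' @return Numeric vector of criterion values (toxicity units).
#' @export
additive_criterion <- function(profiles, env = task_environment("additive")) {
  if (env$kind != "additive") stopf("environment kind is not 'additive'")
  p <- as_profile_matrix(profiles)
  as.numeric(env$intercept + p %*% env$weights)
}

#' @rdname additive_criterion
#' @export
multiplicative_criterion <- function(profiles,
                                     env = task_environment("multiplicative")) {
  if (env$kind != "multiplicative") {
    stopf("environment kind is not 'multiplicative'")
  }
  p <- as_profile_matrix(profiles)
  as.numeric(env$mult_offset +
               env$mult_scale * exp((p %*% env$weights) / env$mult_divisor))
}

#' @rdname additive_criterion
#' @export
criterion <- function(profiles, env) {
  switch(env$kind,
         additive = additive_criterion(profiles, env),
         multiplicative = multiplicative_criterion(profiles, env))
}

#' Enumerate all cue profiles
#'
#' All 2^5 = 32 distinct profiles of five binary cues, in a fixed
#' deterministic order (the last cue varies fastest).
#'
#' @return A 32 x 5 numeric matrix with columns \code{c1..c5}.
#' @export
cue_profiles <- function() {
  g <- expand.grid(c5 = c(-1, 1), c4 = c(-1, 1), c3 = c(-1, 1),
                   c2 = c(-1, 1), c1 = c(-1, 1))
  as_profile_matrix(as.matrix(g[, paste0("c", 1:5)]))
}

role_levels <- c("memorized", "training", "screening_new", "extreme",
                 "fmri_new", "baseline")

role_prefix <- c(memorized = "M", training = "T", screening_new = "S",
                 extreme = "E", fmri_new = "N", baseline = "B")

#' Generate a study item design
#'
#' Allocates the 32 cue profiles to the item roles of the judgment study:
#' the two extreme profiles (all-low and all-high, outside the training
#' range so that test judgments require extrapolation), a training set,
#' new screening-test items, new fMRI-test items never seen in learning,
#' and a memorized subset of the training items for the instructed
#' conditions. Baseline (visual detection) items carry no criterion.
#'
#' The allocation is random given \code{seed} under these constraints:
#' extremes are fixed to the all-(-1)/all-(+1) profiles; training,
#' screening-new and fMRI-new sets are mutually disjoint and exclude the
#' extremes; memorized items are a subset of the training profiles (so the
#' fMRI-new items are disjoint from everything encountered in learning);
#' and the fMRI-new set is resampled until its cue design matrix -- and
#' every leave-one-out subset of it -- has full column rank, so that
#' cross-validated linear fits on the fMRI phase are well posed.
#'
#' @param env A \code{\link{task_environment}}.
#' @param n_training,n_screening_new,n_fmri_new,n_memorized,n_baseline
#'   Item counts per role (extremes are always 2).
#' @param seed Integer seed; the design is a pure function of
#'   (arguments, seed).
#' @return An object of class \code{"study_design"}: a list with the
#'   environment, an \code{items} data frame (item_id, role, c1..c5,
#'   criterion) and the per-role \code{counts}.
#' @examples
#' d <- generate_design(task_environment("additive"), seed = 1)
#' table(d$items$role)
#' @export
generate_design <- function(env, n_training = 16, n_screening_new = 6,
                            n_fmri_new = 8, n_memorized = 6,
                            n_baseline = 8, seed) {
  if (missing(seed)) stopf("a seed is required")
  for (n in c(n_training, n_screening_new, n_fmri_new, n_memorized,
              n_baseline)) {
    if (!is_count(n)) stopf("item counts must be nonnegative integers")
  }
  if (n_training + n_screening_new + n_fmri_new > 30) {
    stopf("training + screening_new + fmri_new counts exceed the 30 %s",
          "non-extreme profiles")
  }
  if (n_memorized > n_training) {
    stopf("n_memorized cannot exceed n_training")
  }
  all32 <- cue_profiles()
  extreme_idx <- c(which(rowSums(all32) == -5), which(rowSums(all32) == 5))

  alloc <- with_seed(seed, {
    pool <- setdiff(seq_len(32), extreme_idx)
    for (try in 1:200) {
      ord <- sample(pool)
      tr <- ord[seq_len(n_training)]
      sc <- ord[n_training + seq_len(n_screening_new)]
      nw <- ord[n_training + n_screening_new + seq_len(n_fmri_new)]
      mem <- if (n_memorized > 0) sample(tr, n_memorized) else integer()
      if (fmri_set_ok(all32[nw, , drop = FALSE])) break
      if (try == 200) stopf("could not find a full-rank fMRI item set")
    }
    bl <- if (n_baseline > 0) sample(32, n_baseline, replace = TRUE) else integer()
    list(tr = tr, sc = sc, nw = nw, mem = mem, bl = bl)
  })

  mk <- function(idx, role) {
    if (length(idx) == 0) return(NULL)
    p <- all32[idx, , drop = FALSE]
    data.frame(
      item_id = sprintf("%s%02d", role_prefix[[role]], seq_along(idx)),
      role = role,
      p,
      criterion = if (role == "baseline") NA_real_ else criterion(p, env),
      stringsAsFactors = FALSE
    )
  }
  items <- rbind(mk(alloc$mem, "memorized"), mk(alloc$tr, "training"),
                 mk(alloc$sc, "screening_new"), mk(extreme_idx, "extreme"),
                 mk(alloc$nw, "fmri_new"), mk(alloc$bl, "baseline"))
  rownames(items) <- NULL
  counts <- table(factor(items$role, levels = role_levels))
  structure(list(environment = env, items = items,
                 counts = as.list(counts), seed = seed),
            class = "study_design")
}

# Full column rank of cbind(1, cues) for the fMRI-new set and for each of
# its leave-one-out subsets (needed by LOOCV linear fits).
fmri_set_ok <- function(p) {
  full <- function(m) qr(cbind(1, m))$rank == 6L
  if (nrow(p) < 7L) return(full(p))
  full(p) && all(vapply(seq_len(nrow(p)),
                        function(i) full(p[-i, , drop = FALSE]), logical(1)))
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design (", x$environment$kind, " environment)\n", sep = "")
  cnt <- x$counts
  for (r in names(cnt)) {
    if (cnt[[r]] > 0) cat(sprintf("  %-14s %d\n", r, cnt[[r]]))
  }
  invisible(x)
}

#' Extract items of given roles from a design
#'
#' @param design A \code{\link{generate_design}} result.
#' @param roles Character vector of roles to keep (default: all).
#' @return The items data frame restricted to those roles.
#' @export
design_items <- function(design, roles = NULL) {
  items <- design$items
  if (!is.null(roles)) {
    bad <- setdiff(roles, role_levels)
    if (length(bad)) stopf("unknown roles: %s", paste(bad, collapse = ", "))
    items <- items[items$role %in% roles, , drop = FALSE]
    rownames(items) <- NULL
  }
  items
}

#' Read and write item tables
#'
#' Items are exchanged as delimited tables with the header
#' \code{item_id, role, c1..c5, criterion}, so published item sets can be
#' plugged in for the algorithmically generated ones.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (".tsv" for tab, otherwise comma).
#' @param items An items data frame as in \code{\link{generate_design}}.
#' @return \code{read_items} returns the items data frame.
#' @export
read_items <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  items <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  need <- c("item_id", "role", paste0("c", 1:5), "criterion")
  miss <- setdiff(need, names(items))
  if (length(miss)) stopf("item table lacks columns: %s",
                          paste(miss, collapse = ", "))
  bad <- setdiff(unique(items$role), role_levels)
  if (length(bad)) stopf("unknown roles in item table: %s",
                         paste(bad, collapse = ", "))
  as_profile_matrix(items)  # validates cue values
  items[, need]
}

#' @rdname read_items
#' @export
write_items <- function(items, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(items, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
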