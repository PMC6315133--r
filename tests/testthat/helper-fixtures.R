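# Shared fixtures, all built in code.

env_add <- task_environment("additive")
env_mult <- task_environment("multiplicative")

# All 32 profiles with additive criteria, as an items-style data frame.
all_items <- function(env = env_add) {
  d <- data.frame(cue_profiles())
  d$criterion <- criterion(d, env)
  d
}

# Noiseless responses from a generating model on the full profile set.
cam_dataset <- function(k = 15, w = c(5, 4, 3, 2, 1)) {
  d <- all_items()
  d$response <- cam_predict(cam_params(k, w), d)
  d
}

ebm_dataset <- function(s = rep(0.2, 5), pool = full_pool()) {
  d <- all_items()
  d$response <- ebm_predict(ebm_params(s), pool, d)
  d
}

full_pool <- function(env = env_add) {
  exemplar_pool(cue_profiles(), criterion(cue_profiles(), env))
}

tiny_pool <- function() {
  exemplar_pool(rbind(rep(1, 5), rep(-1, 5)), c(30, 0))
}

# Profile subsets whose cue design matrix (and every leave-one-out
# subset of it) has full column rank.
rank_safe_rows <- list(`8` = c(1, 2, 4, 7, 11, 14, 23, 25),
                       `10` = c(1, 10, 14, 18, 19, 21, 22, 26, 27, 28))

# A small noisy per-participant dataset with repeated presentations.
noisy_dataset <- function(seed, n_items = 8, reps = 3, noise_sd = 2) {
  prof <- cue_profiles()[rank_safe_rows[[as.character(n_items)]], ,
                         drop = FALSE]
  d <- data.frame(prof[rep(seq_len(n_items), reps), , drop = FALSE])
  d$criterion <- criterion(d, env_add)
  agent <- agent_spec("rule", cam_params(15, c(5, 4, 3, 2, 1)),
                      noise_sd = noise_sd, response_rounding = FALSE)
  d$response <- simulate_judgments(agent, d, seed)
  d
}

# Independent brute-force step-up FDR: scan every candidate threshold.
brute_force_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) {
    if (p[ord[i]] <= i * q / m) k <- i
  }
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# Independent re-implementation of the dependent-correlation z statistic.
meng_z_oracle <- function(r_jk, r_jh, r_kh, n) {
  rb2 <- (r_jk^2 + r_jh^2) / 2
  f <- (1 - r_kh) / (2 * (1 - rb2))
  if (f > 1) f <- 1
  h <- (1 - f * rb2) / (1 - rb2)
  (0.5 * log((1 + r_jk) / (1 - r_jk)) -
      0.5 * log((1 + r_jh) / (1 - r_jh))) *
    sqrt((n - 3) / (2 * (1 - r_kh) * h))
}

# Column-wise sample correlations of y with each column of X.
cor_cols <- function(y, X) as.vector(stats::cor(y, X))
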