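test_that("pearson correlation matches the product-moment definition", {
  x <- c(1, 2, 3, 4)
  r <- pearson_correlation(x, 2 * x + 1)
  expect_equal(r$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  res <- pearson_correlation(x, c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$n, 4L)
  one <- pearson_correlation(x, c(1, 3, 2, 4), tails = "one")
  expect_equal(one$p, res$p / 2)
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), ">= 3")
})

test_that("dependent-correlation z matches an independent re-implementation", {
  expect_equal(meng_dependent_z(0.4, 0.4, 0.1, 50)$z, 0)
  expect_equal(meng_dependent_z(0.4, 0.4, 0.1, 50)$p_two, 1)
  a <- meng_dependent_z(0.5, 0.3, 0.2, 100)
  b <- meng_dependent_z(0.3, 0.5, 0.2, 100)
  expect_equal(a$z, -b$z)  # antisymmetry
  expect_equal(a$p_two, b$p_two)
  for (trip in list(c(0.5, 0.3, 0.2), c(-0.42, -0.12, 0.5),
                    c(0.7, 0.2, 0.4), c(0.1, -0.3, 0))) {
    expect_equal(meng_dependent_z(trip[1], trip[2], trip[3], 74)$z,
                 meng_z_oracle(trip[1], trip[2], trip[3], 74))
  }
  expect_error(meng_dependent_z(0.9, -0.9, 0.9, 50), "positive semidefinite")
  expect_error(meng_dependent_z(0.5, 0.3, 0.2, 3), "at least 4")
})

test_that("dependent-correlation test is calibrated under a trivariate null", {
  # equal population correlations with the shared variable: rejections at
  # alpha = 0.05 should occur at about the nominal rate
  n <- 74; reps <- 2000
  L <- chol(matrix(c(1, 0.3, 0.3, 0.3, 1, 0.2, 0.3, 0.2, 1), 3, 3))
  set.seed(1234)
  rej <- vapply(seq_len(reps), function(i) {
    X <- matrix(rnorm(3 * n), n, 3) %*% L
    r <- cor(X)
    meng_dependent_z(r[1, 2], r[1, 3], r[2, 3], n)$p_two <= 0.05
  }, logical(1))
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gt(mean(rej), ci[1] - 0.01)
  expect_lt(mean(rej), ci[2] + 0.01)
})

test_that("independent-correlation z follows the Fisher closed form", {
  expect_equal(fisher_independent_z(0.4, 30, 0.4, 50)$z, 0)
  a <- fisher_independent_z(0.5, 50, 0.2, 50)
  expect_equal(a$z, (atanh(0.5) - atanh(0.2)) / sqrt(2 / 47))
  expect_equal(a$z, 1.6801, tolerance = 1e-4)
  expect_equal(fisher_independent_z(0.2, 50, 0.5, 50)$z, -a$z)
  expect_error(fisher_independent_z(1, 30, 0.2, 30), "< 1")
})

test_that("BH step-up matches the brute-force scan on small families", {
  expect_equal(bh_fdr(rep(1, 6), 0.05)$reject, rep(FALSE, 6))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05), 0.05)$reject,
               rep(TRUE, 5))
  expect_true(bh_fdr(0.04, 0.05)$reject)
  expect_false(bh_fdr(0.06, 0.05)$reject)
  set.seed(55)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    expect_equal(bh_fdr(p, q)$reject, brute_force_bh(p, q))
  }
  expect_error(bh_fdr(numeric(0), 0.05), "empty")
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
})

test_that("max-p conjunction is an idempotent commutative elementwise max", {
  v1 <- stat_volume(array(c(0.01, 0.2), c(2, 1, 1)))
  v2 <- stat_volume(array(c(0.05, 0.1), c(2, 1, 1)))
  expect_equal(conjunction_max_p(list(v1, v2))$data,
               array(c(0.05, 0.2), c(2, 1, 1)))
  expect_equal(conjunction_max_p(list(v1, v1))$data, v1$data)
  expect_equal(conjunction_max_p(list(v1, v2)),
               conjunction_max_p(list(v2, v1)))
  set.seed(3)
  vols <- lapply(1:3, function(i) stat_volume(array(runif(24), c(2, 3, 4))))
  abc <- conjunction_max_p(vols)
  ab_c <- conjunction_max_p(list(conjunction_max_p(vols[1:2]), vols[[3]]))
  expect_equal(abc, ab_c)
  for (v in vols) expect_true(all(abc$data >= v$data))
  expect_error(conjunction_max_p(vols[1]), "at least 2")
  expect_error(conjunction_max_p(list(v1, stat_volume(array(0.5, c(1, 1, 1))))),
               "identical grids")
})

test_that("conjunction FDR rejects nothing when one test is never significant", {
  set.seed(8)
  v1 <- stat_volume(array(runif(64), c(4, 4, 4)))
  ones <- stat_volume(array(1, c(4, 4, 4)))
  res <- conjunction_fdr(list(v1, ones), q = 0.05)
  expect_equal(sum(res$significant), 0L)
  expect_s3_class(res$p_volume, "stat_volume")
})

test_that("conjunction FDR recovers a planted overlapping effect", {
  box <- list(x = 3:6, y = 3:6, z = 3:6)
  hits <- vapply(1:10, function(s) {
    g <- simulate_stat_volumes(c(10, 10, 10), active = box, effect = 1.5,
                               n_subjects = 20, groups = 2, seed = s)
    pvols <- lapply(g, function(grp) voxelwise_one_sample_t(grp)$p)
    res <- conjunction_fdr(pvols, q = 0.05)
    mean(res$significant[attr(g, "active")])
  }, numeric(1))
  expect_gte(mean(hits > 0.9), 0.9)
})

test_that("voxelwise two-sample t agrees with per-voxel textbook tests", {
  set.seed(10)
  ga <- lapply(1:6, function(i) stat_volume(array(rnorm(27), c(3, 3, 3))))
  gb <- lapply(1:7, function(i) stat_volume(array(rnorm(27, 0.5), c(3, 3, 3))))
  res <- voxelwise_two_sample_t(ga, gb)
  for (idx in list(c(1, 1, 1), c(2, 3, 1), c(3, 3, 3))) {
    a <- vapply(ga, function(v) v$data[idx[1], idx[2], idx[3]], numeric(1))
    b <- vapply(gb, function(v) v$data[idx[1], idx[2], idx[3]], numeric(1))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$t$data[idx[1], idx[2], idx[3]], unname(tt$statistic))
    expect_equal(res$p$data[idx[1], idx[2], idx[3]], tt$p.value)
  }
  expect_equal(res$df, 11)
  # zero-variance voxel flagged with p = 1
  za <- lapply(ga, function(v) { v$data[1, 1, 1] <- 5; v })
  zb <- lapply(gb, function(v) { v$data[1, 1, 1] <- 5; v })
  expect_warning(zres <- voxelwise_two_sample_t(za, zb), "zero-variance")
  expect_equal(zres$p$data[1, 1, 1], 1)
  expect_true(zres$flagged[1, 1, 1])
})

test_that("voxelwise correlation equals looping the scalar correlation", {
  set.seed(11)
  vols <- lapply(1:12, function(i) stat_volume(array(rnorm(8), c(2, 2, 2))))
  cov <- rnorm(12)
  res <- voxelwise_correlation(vols, cov)
  X <- t(vapply(vols, function(v) as.vector(v$data), numeric(8)))
  for (j in 1:8) {
    ref <- pearson_correlation(X[, j], cov)
    expect_equal(as.vector(res$r$data)[j], ref$r)
    expect_equal(as.vector(res$p$data)[j], ref$p)
  }
  # injecting the covariate into a voxel gives |r| = 1 there
  inj <- lapply(seq_along(vols), function(i) {
    v <- vols[[i]]; v$data[2, 2, 2] <- 3 * cov[i] - 1; v
  })
  expect_equal(abs(voxelwise_correlation(inj, cov)$r$data[2, 2, 2]), 1)
  expect_error(voxelwise_correlation(vols, rep(2, 12)), "constant")
  expect_error(voxelwise_correlation(vols[1:3], cov[1:3]), "at least 4")
})

test_that("sphere averaging uses inclusive center-to-center distances", {
  vol <- stat_volume(array(7.5, c(5, 5, 5)), voxel_size = 2)
  expect_equal(as.numeric(sphere_average(vol, c(4, 4, 4), 5)), 7.5)
  # radius below the voxel size, centered on a voxel: that voxel only
  v <- stat_volume(array(1:27, c(3, 3, 3)), voxel_size = 2)
  s1 <- sphere_average(v, c(2, 2, 2), 1.5)
  expect_equal(as.numeric(s1), v$data[2, 2, 2])
  expect_equal(attr(s1, "n_voxels"), 1L)
  # radius equal to the voxel size: the 7-voxel plus-shaped neighborhood
  s7 <- sphere_average(v, c(2, 2, 2), 2)
  expect_equal(attr(s7, "n_voxels"), 7L)
  idx <- rbind(c(2, 2, 2), c(1, 2, 2), c(3, 2, 2), c(2, 1, 2), c(2, 3, 2),
               c(2, 2, 1), c(2, 2, 3))
  expect_equal(as.numeric(s7), mean(v$data[idx]))
  expect_error(sphere_average(v, c(100, 0, 0), 5), "outside the grid")
  off <- stat_volume(array(1, c(3, 3, 3)), voxel_size = 2, origin = c(0, 0, 0))
  expect_error(sphere_average(off, c(1, 1, 1), 0.4), "no voxel center")
})

test_that("mixed ANOVA interaction equals the squared difference-score t", {
  set.seed(12)
  for (i in 1:5) {
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    v <- matrix(rnorm(2 * (n1 + n2)), ncol = 2)
    g <- rep(c("a", "b"), c(n1, n2))
    res <- mixed_anova_interaction(v, g)
    tt <- t.test((v[, 1] - v[, 2]) ~ g, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2)
    expect_equal(res$p, tt$p.value)
    expect_equal(res$df, c(1, n1 + n2 - 2))
  }
})

test_that("mixed ANOVA handles degenerate zero-variance designs", {
  v <- matrix(rep(c(3, 3), each = 8), ncol = 2)
  g <- rep(c("a", "b"), each = 4)
  res <- mixed_anova_interaction(v, g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  # noiseless interaction: difference scores shifted in one group only
  v2 <- cbind(rep(10, 8), rep(10, 8) - rep(c(0, 2), each = 4))
  res2 <- mixed_anova_interaction(v2, g)
  expect_equal(res2$p, 0)
  expect_error(mixed_anova_interaction(v[, 1, drop = FALSE], g), "2 within")
  expect_error(mixed_anova_interaction(v, rep("a", 8)), "2 groups")
})

test_that("Bonferroni thresholds divide alpha by the family size", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 2), 0.025)
  # four clusters x two models, displayed rounded as 0.006
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("statistic volumes round-trip through flat text plus sidecar", {
  set.seed(13)
  vol <- stat_volume(array(rnorm(24), c(2, 3, 4)), voxel_size = 3,
                     origin = c(-10, 0, 5))
  path <- withr::local_tempfile(fileext = ".txt")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$data, vol$data)
  expect_equal(back$voxel_size, vol$voxel_size)
  expect_equal(back$origin, vol$origin)
})
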