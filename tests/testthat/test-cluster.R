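test_that("cohens_d matches the pooled-SD formula and its edge cases", {
  # hand case: means 3 vs 2, both sample variances 4, pooled SD 2
  expect_identical(cohens_d(c(1, 3, 5), c(0, 2, 4)), 0.5)
  # group (1,3) vs rest (0,2): means 2 vs 1, pooled SD sqrt(2)
  expect_equal(cohens_d(c(1, 3), c(0, 2)), 1 / sqrt(2), tolerance = 1e-12)
  expect_identical(cohens_d(c(2, 2), c(2, 2)), 0)
  expect_identical(cohens_d(c(3, 3), c(1, 1)), Inf)
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("cohens_d is antisymmetric and scale invariant", {
  for (s in 1:25) {
    withr::with_seed(s, {
      a <- rnorm(sample(2:20, 1), mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
      b <- rnorm(sample(2:20, 1), mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
      c_pos <- runif(1, 0.1, 10)
    })
    expect_equal(cohens_d(a, b), -cohens_d(b, a), tolerance = 1e-12)
    expect_equal(cohens_d(c_pos * a, c_pos * b), cohens_d(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the cluster matrix has the documented widths and standardized columns", {
  gen <- generate_dataset(default_study_config(n_participants = 60), seed = 3)
  std <- standardize(gen$raw)
  blocks <- assemble_blocks(std)
  waves <- run_prediction_waves(blocks, std$health_index,
                                fast_net(seed = 2, max_epochs = 150))
  X0 <- build_cluster_matrix(blocks, waves$saturated,
                             cluster_config(feature_mode = "predictors_only"))
  expect_equal(ncol(X0), 145)
  X1 <- build_cluster_matrix(blocks, waves$saturated)
  expect_equal(ncol(X1), 146)
  expect_lt(max(abs(colMeans(X1))), 1e-9)
  expect_lt(max(abs(apply(X1, 2, sd) - 1)), 1e-9)
  XH <- build_cluster_matrix(blocks, waves$saturated,
                             cluster_config(feature_mode = "hidden_activations"))
  expect_equal(ncol(XH), 5)
  w <- waves$saturated; w$model <- NULL
  expect_error(build_cluster_matrix(blocks, w,
                                    cluster_config(feature_mode = "hidden_activations")),
               "model")
})

test_that("well-separated blobs are recovered exactly", {
  withr::with_seed(5, {
    centers <- matrix(rnorm(3 * 8), 3, 8) * 10
    lab <- rep(1:3, each = 50)
    X <- centers[lab, ] + matrix(rnorm(150 * 8), 150, 8)
  })
  colnames(X) <- paste0("f", 1:8)
  sol <- two_stage_cluster(X)
  expect_equal(sol$k, 3)
  expect_equal(mclust::adjustedRandIndex(sol$assignments, lab), 1)
  # duplicating every row leaves the pattern intact
  sol2 <- two_stage_cluster(X[rep(1:150, 2), ], cluster_config(k_override = 3))
  expect_equal(mclust::adjustedRandIndex(sol2$assignments[1:150], lab), 1)
  expect_identical(sol2$assignments[1:150], sol2$assignments[151:300])
})

test_that("cluster assignments are invariant to feature column order", {
  gen <- generate_dataset(default_study_config(n_participants = 80), seed = 6)
  std <- standardize(gen$raw)
  blocks <- assemble_blocks(std)
  waves <- run_prediction_waves(blocks, std$health_index,
                                fast_net(seed = 3, max_epochs = 150))
  X <- build_cluster_matrix(blocks, waves$saturated)
  perm_blocks <- structure(lapply(unclass(blocks), function(m)
    m[, rev(seq_len(ncol(m))), drop = FALSE]), class = "predictor_blocks")
  Xp <- build_cluster_matrix(perm_blocks, waves$saturated)
  expect_identical(colnames(X), colnames(Xp))
  expect_identical(two_stage_cluster(X)$assignments,
                   two_stage_cluster(Xp)$assignments)
})

test_that("degenerate clustering inputs are handled explicitly", {
  X <- matrix(1, 20, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_warning(sol <- two_stage_cluster(X), "identical")
  expect_equal(sol$k, 1)
  expect_error(cluster_config(k_override = 9, k_max = 8), "outside")
  expect_error(two_stage_cluster(matrix(rnorm(4), 2, 2),
                                 cluster_config(k_min = 2)), "at least")
})

test_that("engagement ordering labels groups by descending index mean", {
  withr::with_seed(9, {
    lab <- rep(1:2, each = 30)
    idx <- c(rnorm(30, 1, 0.5), rnorm(30, -1, 0.5))
    X <- cbind(f1 = idx + rnorm(60, 0, 0.1), f2 = rnorm(60))
  })
  sol <- two_stage_cluster(X, cluster_config(k_override = 2))
  sol <- engagement_ordering(sol, idx)
  expect_identical(sol$labels, c("high", "low"))
  expect_gt(sol$engagement_d[1], 0)
  expect_lt(sol$engagement_d[2], 0)
  expect_true(all(diff(sol$engagement_mean) < 0))
  # index means of relabeled assignments match the stored order
  m <- tapply(idx, sol$assignments, mean)
  expect_equal(as.numeric(m), sol$engagement_mean)

  one <- suppressWarnings(two_stage_cluster(matrix(1, 20, 2,
                                                   dimnames = list(NULL, c("a", "b")))))
  one <- engagement_ordering(one, rnorm(20))
  expect_identical(one$labels, "all")
  expect_true(is.na(one$engagement_d))
})

test_that("descending engagement shifts give strictly decreasing engagement d", {
  groups <- list(group_spec("g1", 0.3, engagement_shift = 1),
                 group_spec("g2", 0.3, engagement_shift = 0.3),
                 group_spec("g3", 0.3, engagement_shift = -0.5),
                 group_spec("g4", 0.1, engagement_shift = -1.5))
  for (s in 1:3) {
    gen <- generate_dataset(simulation_config(2000, groups), seed = s)
    std <- standardize(gen$raw)
    lab <- gen$truth$group_labels
    sol <- structure(list(assignments = lab, k = 4L, sizes = tabulate(lab, 4),
                          centroids = matrix(0, 4, 1), heights = numeric(0),
                          config = cluster_config()),
                     class = "cluster_solution")
    sol <- engagement_ordering(sol, std$health_index)
    expect_true(all(diff(sol$engagement_d) < 0))
  }
})

test_that("salience profiling flags |d| >= threshold against the pooled rest", {
  gen <- generate_dataset(default_study_config(n_participants = 211), seed = 8)
  std <- standardize(gen$raw)
  blocks <- assemble_blocks(std)
  waves <- run_prediction_waves(blocks, std$health_index,
                                fast_net(seed = 4, max_epochs = 200))
  sol <- engagement_ordering(
    two_stage_cluster(build_cluster_matrix(blocks, waves$saturated)),
    std$health_index)
  sal <- salience_profile(sol, std, blocks)
  expect_equal(dim(sal$d_matrix), c(145L, sol$k))
  expect_identical(sal$salient_mask,
                   !is.na(sal$d_matrix) & abs(sal$d_matrix) >= 0.5)
  # spot-check one cell against a direct computation
  v <- "beh_clubbing_t2"
  g <- which(sal$labels == "low")
  M <- do.call(cbind, unclass(blocks))
  expect_equal(sal$d_matrix[v, g],
               cohens_d(M[sol$assignments == g, v],
                        M[sol$assignments != g, v]))
  # size-weighted group means recompose the overall mean for every variable
  for (v in c("beh_walk_t2", "cog_smoking_pbc", "pers_self_eff")) {
    gm <- vapply(seq_len(sol$k), function(g)
      mean(M[sol$assignments == g, v]), numeric(1))
    expect_lt(abs(sum(sol$sizes * gm) / sum(sol$sizes) - mean(M[, v])), 1e-9)
  }
  # group-vs-rest d values cannot all share one sign
  expect_true(any(sol$engagement_d > 0) && any(sol$engagement_d < 0))

  one <- suppressWarnings(two_stage_cluster(matrix(1, nrow(M), 2,
                                                   dimnames = list(NULL, c("a", "b")))))
  expect_error(salience_profile(one, std, blocks), "k >= 2")
})

test_that("the salience table blanks sub-threshold cells", {
  gen <- generate_dataset(default_study_config(n_participants = 120), seed = 12)
  std <- standardize(gen$raw)
  blocks <- assemble_blocks(std)
  waves <- run_prediction_waves(blocks, std$health_index,
                                fast_net(seed = 5, max_epochs = 150))
  sol <- engagement_ordering(
    two_stage_cluster(build_cluster_matrix(blocks, waves$saturated)),
    std$health_index)
  sal <- salience_profile(sol, std, blocks)
  tab <- salience_table(sal)
  full <- salience_table(sal, full = TRUE)
  expect_identical(tab$variable, unname(unlist(profile_vars <- sal$sections)))
  g1 <- sal$labels[1]
  blank <- tab[[g1]] == ""
  expect_true(all(abs(full[[g1]][blank]) < 0.5 | is.na(full[[g1]][blank])))
  expect_true(all(abs(full[[g1]][!blank]) >= 0.5))
})
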