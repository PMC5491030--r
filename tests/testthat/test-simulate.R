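test_that("default study config reproduces the design group sizes", {
  cfg <- default_study_config()
  props <- vapply(cfg$groups, `[[`, numeric(1), "proportion")
  expect_lt(abs(sum(props) - 1), 1e-9)
  expect_equal(milieu:::quota_sizes(211, props), c(92L, 50L, 64L, 5L))
  shifts <- vapply(cfg$groups, `[[`, numeric(1), "engagement_shift")
  expect_true(all(diff(shifts) < 0))  # high > moderate > low > very_low
  gen <- generate_dataset(cfg, seed = 4)
  expect_equal(unname(table(gen$truth$group_labels)),
               array(c(92L, 50L, 64L, 5L)))
})

test_that("generation is deterministic and writes byte-identical CSVs", {
  cfg <- default_study_config(n_participants = 60)
  g1 <- generate_dataset(cfg, seed = 11)
  g2 <- generate_dataset(cfg, seed = 11)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_raw(g1$raw, p1); write_raw(g2$raw, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  g3 <- generate_dataset(cfg, seed = 12)
  expect_false(identical(g1$raw$followup_counts, g3$raw$followup_counts))
})

test_that("generated values respect the schema ranges for every seed", {
  for (s in c(1, 7, 23)) {
    gen <- generate_dataset(default_study_config(n_participants = 80), seed = s)
    counts <- cbind(gen$raw$baseline_counts, gen$raw$followup_counts)
    expect_true(all(counts >= 0) && all(counts == round(counts)))
    expect_true(all(gen$raw$cognitions >= 1 & gen$raw$cognitions <= 7))
  }
  # rounded-Gaussian link too
  cfg <- simulation_config(60, list(group_spec("all", 1)),
                           count_link = "rounded_gaussian")
  gen <- generate_dataset(cfg, seed = 5)
  counts <- cbind(gen$raw$baseline_counts, gen$raw$followup_counts)
  expect_true(all(counts >= 0) && all(counts == round(counts)))
})

test_that("config validation rejects degenerate inputs", {
  expect_error(simulation_config(100, list(group_spec("a", 0.6),
                                           group_spec("b", 0.2)),
                                 noise_sd = 0.5),
               "sum to 1")
  expect_error(simulation_config(6, list(group_spec("a", 0.5),
                                         group_spec("b", 0.5))),
               "at least 4 per group")
  expect_error(simulation_config(100, list(group_spec("a", 1)), noise_sd = 0),
               "noise_sd")
  tiny <- simulation_config(40, list(group_spec("a", 0.99),
                                     group_spec("b", 0.01)))
  expect_error(generate_dataset(tiny, seed = 1), "expected size 0")
})

test_that("a group's expected health index increases with its engagement shift", {
  means <- vapply(c(-1, 0, 1), function(shift) {
    groups <- list(group_spec("probe", 0.5, engagement_shift = shift),
                   group_spec("ref", 0.5, engagement_shift = 0))
    gen <- generate_dataset(simulation_config(400, groups), seed = 21)
    std <- standardize(gen$raw)
    mean(std$health_index[gen$truth$group_labels == 1])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("with no planted signal, lifestyle counts are unrelated to the index", {
  # conflict = 0 and nonlinearity = 0: the lifestyle latent is independent of
  # the health propensity, so activity counts carry no index information,
  # marginally or given the activity's cognitions.
  cfg <- simulation_config(3000, list(group_spec("all", 1)),
                           nonlinearity_strength = 0)
  gen <- generate_dataset(cfg, seed = 31)
  std <- standardize(gen$raw)
  for (b in c("clubbing", "visit_friend", "walk")) {
    act <- std$z_followup[, paste0("beh_", b, "_t2")]
    expect_lt(abs(cor(act, std$health_index)), 0.06)
    cogs <- std$z_cognitions[, paste0("cog_", b, "_",
                                      milieu:::COGNITION_CONSTRUCTS)]
    pcor <- cor(resid(lm(act ~ cogs)), resid(lm(std$health_index ~ cogs)))
    expect_lt(abs(pcor), 0.06)
  }
})

test_that("noise-free linear-link data make the index learnable from cognitions", {
  # With vanishing measurement noise, cognitions loading only on the health
  # propensity, and the linear count channel, OLS of the index on the health
  # cognition block approaches R^2 = 1 (rounding is the only noise left).
  cfg <- simulation_config(
    1500,
    list(group_spec("all", 1,
                    cognition_loadings = list(health_cognitions = 1,
                                              lifestyle_cognitions = 0))),
    noise_sd = 0.05, count_link = "rounded_gaussian",
    nonlinearity_strength = 0)
  gen <- generate_dataset(cfg, seed = 3)
  catalog <- gen$raw$catalog
  hcols <- paste0("beh_", milieu:::health_names(catalog), "_t2")
  zf <- scale(gen$raw$followup_counts[, hcols])
  rcols <- paste0("beh_", milieu:::risk_names(catalog), "_t2")
  zf[, rcols] <- -zf[, rcols]
  idx <- rowMeans(zf)
  cog_block <- gen$raw$cognitions[
    , as.vector(t(outer(paste0("cog_", milieu:::health_names(catalog), "_"),
                        milieu:::COGNITION_CONSTRUCTS, paste0)))]
  expect_gt(summary(lm(idx ~ cog_block))$r.squared, 0.95)
})

test_that("planted increments are recovered by an OLS oracle on the latent factors", {
  inc <- c(health_cognitions = 0.18, personality = 0, lifestyle = 0.24,
           baseline_health = 0.29)
  res <- t(vapply(1:5, function(s) {
    gen <- generate_dataset(incremental_config(1500, inc), seed = s)
    y <- standardize(gen$raw)$health_index
    f <- gen$truth$factors
    r2 <- function(k) summary(lm(y ~ f[, seq_len(k), drop = FALSE]))$r.squared
    c(r2(1), r2(2) - r2(1), r2(3) - r2(2), r2(4) - r2(3))
  }, numeric(4)))
  expect_lt(max(abs(colMeans(res) - inc)), 0.05)
})

test_that("simulation configs round-trip through YAML", {
  cfg <- default_study_config(n_participants = 100, seed = 17)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  g1 <- generate_dataset(cfg, seed = 5)
  g2 <- generate_dataset(back, seed = 5)
  expect_equal(g1$raw$followup_counts, g2$raw$followup_counts)
  expect_equal(g1$raw$cognitions, g2$raw$cognitions)
})
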