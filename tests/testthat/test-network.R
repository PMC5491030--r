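test_that("forward pass matches scalar hand computation", {
  net <- structure(list(
    W1 = matrix(c(0.5, 0.1, -0.25, 0.3), 2, 2),
    b1 = c(0.1, -0.2), w2 = c(1, 2), b2 = 0.5,
    activation = "tanh", columns = c("a", "b"),
    x_center = c(a = 0, b = 0), x_scale = c(a = 1, b = 1),
    y_center = 0, y_scale = 1), class = "milieu_net")
  x <- matrix(c(1, -1), 1, 2, dimnames = list(NULL, c("a", "b")))
  h1 <- tanh(1 * 0.5 + (-1) * 0.1 + 0.1)
  h2 <- tanh(1 * (-0.25) + (-1) * 0.3 + (-0.2))
  expect_equal(predict(net, x), h1 * 1 + h2 * 2 + 0.5, tolerance = 1e-12)

  # zero weights, zero bias -> all predictions 0
  net$W1[] <- 0; net$b1[] <- 0; net$w2[] <- 0; net$b2 <- 0
  expect_equal(predict(net, matrix(rnorm(10), 5, 2,
                                   dimnames = list(NULL, c("a", "b")))),
               rep(0, 5))
  # width mismatch is a shape error
  expect_error(predict(net, matrix(0, 2, 3)), "columns")
})

test_that("a noise-free linear map is learned nearly perfectly", {
  withr::with_seed(1, {
    X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("x", 1:4)))
  })
  y <- X[, 2]
  net <- train_network(X, y, fast_net(seed = 2))
  val <- milieu:::validation_split(scale(y)[, 1], 0.2,
                                   derive_seed(2, "validation_split"))
  pred <- predict(net, X[val, , drop = FALSE])
  r2 <- 1 - sum((y[val] - pred)^2) / sum((y[val] - mean(y[val]))^2)
  expect_gte(r2, 0.99)
})

test_that("training is deterministic and invariant to column order", {
  withr::with_seed(3, {
    X <- matrix(rnorm(600), 120, 5, dimnames = list(NULL, paste0("v", 1:5)))
    y <- X %*% rnorm(5) + rnorm(120, 0, 0.5)
  })
  y <- as.numeric(y)
  cfg <- fast_net(seed = 9)
  n1 <- train_network(X, y, cfg)
  n2 <- train_network(X, y, cfg)
  expect_identical(n1$W1, n2$W1)
  expect_identical(predict(n1, X), predict(n2, X))
  perm <- c(4, 2, 5, 1, 3)
  n3 <- train_network(X[, perm], y, cfg)
  expect_equal(predict(n3, X), predict(n1, X), tolerance = 1e-12)
})

test_that("training errors are informative", {
  X <- matrix(numeric(0), 10, 0)
  expect_error(train_network(X, rnorm(10)), "zero predictor columns")
  X2 <- matrix(rnorm(20), 10, 2)
  expect_error(train_network(X2, rnorm(9)), "row counts differ")
  expect_error(train_network(X2, rnorm(10),
                             network_config(validation_fraction = 0.5)),
               "fewer than 10 training rows")
})

test_that("run_prediction_waves returns the six named waves", {
  gen <- generate_dataset(default_study_config(n_participants = 60), seed = 2)
  std <- standardize(gen$raw)
  blocks <- assemble_blocks(std)
  waves <- run_prediction_waves(blocks, std$health_index,
                                fast_net(seed = 1, max_epochs = 150))
  expect_s3_class(waves, "wave_set")
  expect_length(waves, 6)
  expect_identical(names(waves),
                   c("health_cognitions", "personality",
                     "lifestyle_cognitions", "lifestyle_activities",
                     "baseline_health", "saturated"))
  expect_identical(waves[[6]]$wave_name, "saturated")
  for (w in waves) {
    expect_length(w$estimates, 60)
    expect_true(is.finite(w$r_with_target))
  }
})

test_that("waves find planted signal and ignore empty blocks", {
  # only baseline_health carries signal
  withr::with_seed(8, {
    n <- 500
    u <- rnorm(n)
    base <- matrix(u, n, 5) + matrix(rnorm(n * 5, 0, 0.7), n, 5)
    colnames(base) <- paste0("beh_h", 1:5, "_t1")
    mk <- function(p, prefix) {
      m <- matrix(rnorm(n * p), n, p)
      colnames(m) <- paste0(prefix, seq_len(p))
      m
    }
    blocks <- structure(list(health_cognitions = mk(8, "hc"),
                             personality = mk(5, "pers"),
                             lifestyle_cognitions = mk(10, "lc"),
                             lifestyle_activities = mk(6, "la"),
                             baseline_health = base),
                        class = "predictor_blocks")
    y <- u + rnorm(n, 0, 0.6)
  })
  waves <- run_prediction_waves(blocks, y, fast_net(seed = 4))
  expect_gte(abs(waves$baseline_health$r_with_target), 0.6)
  expect_lte(abs(waves$personality$r_with_target), 0.15)
})

test_that("the saturated wave is not dominated by any single wave", {
  # the saturated model sees a superset of inputs; exact dominance is not
  # guaranteed for a nonconvex fit, hence the 0.1 tolerance
  for (s in 1:3) {
    gen <- generate_dataset(default_study_config(seed = s), seed = s)
    std <- standardize(gen$raw)
    waves <- run_prediction_waves(assemble_blocks(std), std$health_index,
                                  network_config(seed = s, restarts = 2))
    r <- vapply(waves, `[[`, numeric(1), "r_with_target")
    expect_gte(r[["saturated"]], max(r[1:5]) - 0.1)
  }
})

test_that("waves find no signal in a permuted target", {
  gen <- generate_dataset(
    simulation_config(500, default_study_config()$groups,
                      nonlinearity_strength = 0.25), seed = 2)
  std <- standardize(gen$raw)
  blocks <- assemble_blocks(std)
  for (ps in 1:2) {
    yperm <- milieu:::with_seed(ps, sample(std$health_index))
    waves <- run_prediction_waves(blocks, yperm,
                                  network_config(seed = ps, restarts = 2))
    expect_lte(max(abs(vapply(waves, `[[`, numeric(1), "r_with_target"))),
               0.25)
  }
})

test_that("networks serialize to JSON and restore identically", {
  withr::with_seed(5, {
    X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- as.numeric(X %*% c(1, -1, 0.5) + rnorm(100, 0, 0.3))
  })
  net <- train_network(X, y, fast_net(seed = 6, max_epochs = 200))
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(predict(back, X), predict(net, X), tolerance = 1e-12)
})
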