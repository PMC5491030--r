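# Programmatic fixtures shared across test files.

# A small catalog: 2 health behaviors (one reverse-coded) + 3 lifestyle.
tiny_catalog <- function() {
  behavior_catalog(data.frame(
    name = c("exercise", "smoking", "reading", "clubbing", "tidying"),
    label = c("Engage in exercise", "Avoid smoking", "Read for pleasure",
              "Go clubbing", "Tidy room"),
    is_health = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    is_risk = c(FALSE, TRUE, FALSE, FALSE, FALSE)))
}

# A deterministic tiny raw dataset on a given catalog. Count columns are a
# per-column constant plus a strictly increasing row ramp, so every column is
# guaranteed nonconstant.
tiny_raw <- function(n = 6, catalog = tiny_catalog(), seed = 42) {
  B <- nrow(catalog$behaviors)
  withr::with_seed(seed, {
    count_mat <- function(suffix) {
      m <- matrix(rep(rpois(B, 4), each = n), n, B) + seq_len(n)
      dimnames(m) <- list(NULL, paste0("beh_", catalog$behaviors$name, suffix))
      m
    }
    raw_dataset(
      pid = sprintf("P%02d", seq_len(n)),
      baseline_counts = count_mat("_t1"),
      cognitions = matrix(
        round(runif(n * 4 * B, 1, 7), 3), n, 4 * B,
        dimnames = list(NULL, milieu:::cognition_colnames(catalog))),
      personality = matrix(
        round(rnorm(n * 5), 3), n, 5,
        dimnames = list(NULL, paste0("pers_", milieu:::PERSONALITY_SCALES))),
      followup_counts = count_mat("_t2"),
      catalog = catalog)
  })
}

# Build a wave_set directly from an estimate matrix (columns = the five
# block waves, in order), bypassing network training, for regression tests.
fake_wave_set <- function(est, y) {
  nms <- c("health_cognitions", "personality", "lifestyle_cognitions",
           "lifestyle_activities", "baseline_health")
  stopifnot(ncol(est) == 5)
  colnames(est) <- nms
  waves <- lapply(nms, function(wn) {
    structure(list(wave_name = wn, estimates = est[, wn],
                   r_with_target = suppressWarnings(cor(est[, wn], y)),
                   model = NULL),
              class = "wave_result")
  })
  names(waves) <- nms
  waves$saturated <- structure(
    list(wave_name = "saturated", estimates = rowMeans(est),
         r_with_target = cor(rowMeans(est), y), model = NULL),
    class = "wave_result")
  structure(waves[c(nms, "saturated")], class = "wave_set")
}

# Explicit normal-equations OLS (intercept included): the independent oracle
# for regression results.
ols_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  beta <- solve(crossprod(X1), crossprod(X1, y))
  fitted <- X1 %*% beta
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(beta = as.numeric(beta), r2 = 1 - ss_res / ss_tot)
}

# Fast network settings for unit tests (overridable defaults).
fast_net <- function(seed = 1, ...) {
  args <- list(seed = seed, restarts = 2, max_epochs = 500, patience = 30)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(network_config, args)
}
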