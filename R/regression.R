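## Incremental-validity analysis: Pearson correlations of each wave's
## estimates with the actual health-behavior index, and a four-step
## hierarchical OLS regression of the index on the wave estimates:
##   step 1  health-cognitions estimate
##   step 2  + personality estimate
##   step 3  + lifestyle-cognitions and lifestyle-activities estimates
##   step 4  + baseline-health estimate
## Reported per step: cumulative R^2 and adjusted R^2, the change in both
## (significance is tested with the standard F-change on unadjusted R^2),
## and standardized betas for every predictor currently in the model.

HIER_STEPS <- list(
  step1 = "health_cognitions",
  step2 = "personality",
  step3 = c("lifestyle_cognitions", "lifestyle_activities"),
  step4 = "baseline_health")

#' Correlate wave estimates with the actual index
#'
#' @param waves a `wave_set` from [run_prediction_waves()].
#' @param y the health-behavior index.
#' @return named numeric vector of Pearson correlations for the five
#'   non-saturated waves, in block order.
#' @export
correlate_waves <- function(waves, y) {
  stopifnot(inherits(waves, "wave_set"))
  nms <- setdiff(WAVE_NAMES, "saturated")
  vapply(nms, function(wn) safe_cor(waves[[wn]]$estimates, y, wn), numeric(1))
}

## Matrix of the five non-saturated wave estimates, in entry order.
wave_estimate_matrix <- function(waves) {
  nms <- setdiff(WAVE_NAMES, "saturated")
  est <- vapply(nms, function(wn) waves[[wn]]$estimates,
                numeric(length(waves[[1]]$estimates)))
  colnames(est) <- nms
  est
}

#' Hierarchical regression of the index on the wave estimates
#'
#' Ordinary least squares (with intercept) at each of the four entry steps.
#' The adjusted R-squared is `1 - (1 - R2) (n - 1) / (n - p - 1)`; the
#' F-change statistic for a step entering `q` predictors into a model with
#' `p` predictors total is `((R2 - R2_prev) / q) / ((1 - R2) / (n - p - 1))`.
#' Both the adjusted and the unadjusted R-squared change are reported; the
#' F test always uses the unadjusted difference. Betas are standardized.
#'
#' @param waves a `wave_set` (the saturated wave is ignored here).
#' @param y the health-behavior index.
#' @param kappa_warn condition-number threshold above which a collinearity
#'   warning is emitted (the fit proceeds; `lm` resolves rank deficiency by
#'   aliasing).
#' @return an object of class `hier_regression`: per-wave correlations
#'   (`r`), a list of `steps` (each with `predictors`, `r2`, `adj_r2`,
#'   `delta_r2`, `delta_adj_r2`, `f_change`, `df`, `p_value`, `betas`), the
#'   per-step beta matrix (`beta_matrix`), and the `final` model summary.
#' @export
hierarchical_regression <- function(waves, y, kappa_warn = 1e8) {
  stopifnot(inherits(waves, "wave_set"))
  est <- wave_estimate_matrix(waves)
  n <- length(y)
  if (n <= ncol(est) + 1L) stop("n must exceed the number of predictors + 1",
                                call. = FALSE)
  est_z <- zscore_columns(est, "wave estimates")
  y_z <- as.numeric(scale(y))

  kap <- kappa(cbind(1, est_z), exact = TRUE)
  if (kap > kappa_warn) {
    warning("wave estimates are nearly collinear (condition number ",
            signif(kap, 3), "); betas are unstable", call. = FALSE)
  }

  steps <- vector("list", length(HIER_STEPS))
  names(steps) <- names(HIER_STEPS)
  entered <- character(0)
  r2_prev <- 0; adj_prev <- 0; p_prev <- 0L
  beta_matrix <- matrix(NA_real_, ncol(est), length(HIER_STEPS),
                        dimnames = list(colnames(est), names(HIER_STEPS)))

  for (k in seq_along(HIER_STEPS)) {
    entering <- HIER_STEPS[[k]]
    entered <- c(entered, entering)
    Xk <- est_z[, entered, drop = FALSE]
    fit <- stats::lm(y_z ~ Xk)
    r2 <- summary(fit)$r.squared
    p_k <- length(entered)
    adj <- 1 - (1 - r2) * (n - 1) / (n - p_k - 1)
    q <- length(entering)
    df2 <- n - p_k - 1L
    f_change <- ((r2 - r2_prev) / q) / ((1 - r2) / df2)
    p_value <- stats::pf(f_change, q, df2, lower.tail = FALSE)
    betas <- stats::coef(fit)[-1]
    names(betas) <- entered
    betas[is.na(betas)] <- 0   # aliased under exact collinearity
    beta_matrix[entered, k] <- betas
    steps[[k]] <- list(step_index = k, predictors = entered,
                       entering = entering,
                       r2 = r2, adj_r2 = adj,
                       delta_r2 = r2 - r2_prev,
                       delta_adj_r2 = adj - adj_prev,
                       f_change = f_change, df = c(q, df2),
                       p_value = p_value, betas = betas)
    r2_prev <- r2; adj_prev <- adj; p_prev <- p_k
  }

  final_fit <- steps[[length(steps)]]
  final <- list(adj_r2 = final_fit$adj_r2,
                r2 = final_fit$r2,
                f = (final_fit$r2 / ncol(est)) /
                  ((1 - final_fit$r2) / (n - ncol(est) - 1)),
                df = c(ncol(est), n - ncol(est) - 1L),
                p_value = stats::pf((final_fit$r2 / ncol(est)) /
                                      ((1 - final_fit$r2) / (n - ncol(est) - 1)),
                                    ncol(est), n - ncol(est) - 1,
                                    lower.tail = FALSE))

  structure(list(r = correlate_waves(waves, y), steps = steps,
                 beta_matrix = beta_matrix, final = final, n = n),
            class = "hier_regression")
}

sig_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ""))
}

#' Render the hierarchical regression as a report table
#'
#' One row per predictor type: its correlation with the index, the
#' cumulative adjusted R-squared and adjusted R-squared change at the step
#' where it entered, and its standardized beta at each step it was in the
#' model, with `**`/`***` significance markers at p < .01 / p < .001.
#'
#' @param hr a `hier_regression`.
#' @return a data.frame ready for TSV/JSON emission.
#' @export
regression_table <- function(hr) {
  stopifnot(inherits(hr, "hier_regression"))
  rows <- list()
  for (k in seq_along(hr$steps)) {
    st <- hr$steps[[k]]
    for (i in seq_along(st$entering)) {
      wn <- st$entering[i]
      last <- i == length(st$entering)
      rows[[wn]] <- data.frame(
        step = k, predictor = wn,
        r = round(unname(hr$r[wn]), 3),
        adj_r2 = if (last) round(st$adj_r2, 3) else NA_real_,
        adj_r2_change = if (last) round(st$delta_adj_r2, 3) else NA_real_,
        r2_change = if (last) round(st$delta_r2, 3) else NA_real_,
        f_change = if (last) round(st$f_change, 2) else NA_real_,
        p_change = if (last) signif(st$p_value, 3) else NA_real_,
        sig = if (last) sig_stars(st$p_value) else "",
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  for (k in seq_along(hr$steps)) {
    tab[[paste0("beta_step", k)]] <- round(hr$beta_matrix[tab$predictor, k], 3)
  }
  rownames(tab) <- NULL
  tab
}

#' @export
print.hier_regression <- function(x, ...) {
  cat("hierarchical regression (n = ", x$n, ")\n", sep = "")
  print(regression_table(x), row.names = FALSE)
  cat(sprintf("final model: adj R2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$final$adj_r2, x$final$df[1], x$final$df[2], x$final$f,
              x$final$p_value))
  invisible(x)
}
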