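## Feed-forward regression network with early stopping, and the six
## prediction "waves" (one per predictor block plus the saturated model).
##
## The network is a single-hidden-layer perceptron (tanh hidden units,
## linear output) trained by full-batch gradient descent with an adaptive
## ("bold driver") step size under mean-squared-error loss. A seeded,
## target-stratified validation split drives patience-based early stopping;
## the best-validation weights over several seeded restarts are kept.
## Everything is deterministic given (data, config): initialization seeds are
## derived from the config seed and the *sorted* input column names, so
## estimates are invariant to predictor column order.

#' Network training configuration
#'
#' @param hidden_units number of tanh hidden units (default 5).
#' @param activation hidden activation, `"tanh"` (default) or `"logistic"`;
#'   the output unit is always linear.
#' @param max_epochs maximum full-batch epochs per restart (default 2000).
#' @param learning_rate initial step size for the adaptive optimizer.
#' @param validation_fraction fraction of rows held out for early stopping
#'   (default 0.2); the split is stratified on target quartiles.
#' @param patience epochs without validation improvement before stopping
#'   (default 50).
#' @param restarts number of seeded restarts; the restart with the best
#'   validation error wins (default 5).
#' @param seed master seed for splits and initialization.
#' @return an object of class `network_config`.
#' @export
network_config <- function(hidden_units = 5L, activation = c("tanh", "logistic"),
                           max_epochs = 2000L, learning_rate = 0.05,
                           validation_fraction = 0.2, patience = 50L,
                           restarts = 5L, seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(hidden_units >= 1, max_epochs >= 1, learning_rate > 0,
            validation_fraction > 0, validation_fraction < 1, patience >= 1,
            restarts >= 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 activation = activation,
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience),
                 restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "network_config")
}

act_fun <- function(name) {
  if (name == "tanh") tanh else function(x) 1 / (1 + exp(-x))
}
act_deriv <- function(name) {
  if (name == "tanh") function(a) 1 - a^2 else function(a) a * (1 - a)
}

## Validation indices, stratified on target quartiles so early stopping is
## stable at small n.
validation_split <- function(y, fraction, seed) {
  n <- length(y)
  qs <- stats::quantile(y, c(0.25, 0.5, 0.75), type = 7)
  strata <- findInterval(y, unique(qs)) + 1L
  with_seed(seed, {
    val <- integer(0)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      k <- round(length(idx) * fraction)
      if (k > 0) val <- c(val, sample(idx, k))
    }
    sort(val)
  })
}

forward_pass <- function(W1, b1, w2, b2, X, act) {
  A <- act(sweep(X %*% W1, 2L, b1, `+`))
  list(A = A, yhat = as.numeric(A %*% w2 + b2))
}

#' Train the regression network
#'
#' @param X numeric predictor matrix (rows = participants); columns should be
#'   standardized and named.
#' @param y numeric target vector (the health-behavior index).
#' @param config a [network_config()].
#' @return an object of class `milieu_net` holding the weights of the
#'   best-validation restart and training metadata (`epochs`, `val_mse`,
#'   `restart`, `seed`).
#' @export
train_network <- function(X, y, config = network_config()) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("X has zero predictor columns", call. = FALSE)
  if (nrow(X) != length(y)) stop("X and y row counts differ", call. = FALSE)
  ord <- order(colnames(X) %||% as.character(seq_len(ncol(X))))
  X <- X[, ord, drop = FALSE]

  ## internal standardization (stored so predict() maps back)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  y_ctr <- mean(y)
  y_scl <- stats::sd(y)
  if (y_scl == 0) y_scl <- 1
  ys <- (y - y_ctr) / y_scl

  n <- nrow(Xs)
  split_seed <- derive_seed(config$seed, "validation_split")
  val_idx <- validation_split(ys, config$validation_fraction, split_seed)
  if (n - length(val_idx) < 10L) {
    stop("validation split leaves fewer than 10 training rows", call. = FALSE)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- Xs[tr_idx, , drop = FALSE]; ytr <- ys[tr_idx]
  Xva <- Xs[val_idx, , drop = FALSE]; yva <- ys[val_idx]

  col_tag <- paste(colnames(X) %||% "unnamed", collapse = "|")
  best <- NULL
  for (r in seq_len(config$restarts)) {
    init_seed <- derive_seed(config$seed, paste0("init:", r, ":", col_tag))
    fit <- train_once(Xtr, ytr, Xva, yva, config, init_seed, r)
    if (is.null(best) || fit$val_mse < best$val_mse) best <- fit
  }

  structure(list(W1 = best$W1, b1 = best$b1, w2 = best$w2, b2 = best$b2,
                 activation = config$activation,
                 columns = colnames(X),
                 x_center = ctr, x_scale = scl,
                 y_center = y_ctr, y_scale = y_scl,
                 epochs = best$epochs, val_mse = best$val_mse,
                 restart = best$restart, seed = config$seed,
                 config = config),
            class = "milieu_net")
}

train_once <- function(Xtr, ytr, Xva, yva, config, init_seed, restart) {
  p <- ncol(Xtr); H <- config$hidden_units
  act <- act_fun(config$activation)
  dact <- act_deriv(config$activation)

  w <- with_seed(init_seed, {
    list(W1 = matrix(stats::rnorm(p * H, 0, 1 / sqrt(p)), p, H),
         b1 = stats::rnorm(H, 0, 0.1),
         w2 = stats::rnorm(H, 0, 1 / sqrt(H)),
         b2 = 0)
  })

  ntr <- nrow(Xtr)
  nva <- nrow(Xva)
  lr <- config$learning_rate
  fw <- forward_pass(w$W1, w$b1, w$w2, w$b2, Xtr, act)
  tr_mse <- mean((fw$yhat - ytr)^2)
  val_stats <- function(w) {
    e2 <- (forward_pass(w$W1, w$b1, w$w2, w$b2, Xva, act)$yhat - yva)^2
    c(mean(e2), stats::sd(e2) / sqrt(nva))
  }
  vs <- val_stats(w)
  best <- c(w, list(val_mse = vs[1], epochs = 0L, restart = restart))
  stall <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    err <- fw$yhat - ytr                       # n
    dA <- outer(err, w$w2) * dact(fw$A)        # n x H
    g <- list(W1 = crossprod(Xtr, dA) / ntr,
              b1 = colSums(dA) / ntr,
              w2 = as.numeric(crossprod(fw$A, err)) / ntr,
              b2 = mean(err))
    if (!all(vapply(g, function(x) all(is.finite(x)), logical(1)))) {
      stop("non-finite gradient at restart ", restart, ", epoch ", epoch,
           call. = FALSE)
    }

    cand <- list(W1 = w$W1 - 2 * lr * g$W1, b1 = w$b1 - 2 * lr * g$b1,
                 w2 = w$w2 - 2 * lr * g$w2, b2 = w$b2 - 2 * lr * g$b2)
    fw_cand <- forward_pass(cand$W1, cand$b1, cand$w2, cand$b2, Xtr, act)
    cand_mse <- mean((fw_cand$yhat - ytr)^2)
    if (!is.finite(cand_mse)) {
      stop("non-finite loss at restart ", restart, ", epoch ", epoch,
           call. = FALSE)
    }

    if (cand_mse <= tr_mse) {                  # bold driver: accept & grow
      w <- cand; fw <- fw_cand; tr_mse <- cand_mse
      lr <- lr * 1.1
    } else {                                   # reject & shrink
      lr <- lr * 0.5
      if (lr < 1e-12) break
    }

    vs <- val_stats(w)
    ## a record only counts if it beats the best by a fraction of the
    ## validation MSE's standard error: chance fluctuations on
    ## noise-dominated problems then neither reset the patience counter nor
    ## drag the kept weights toward a spurious late minimum
    if (vs[1] < best$val_mse - 0.5 * vs[2]) {
      best <- c(w, list(val_mse = vs[1], epochs = epoch, restart = restart))
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  best
}

#' Predict from a trained network
#'
#' Deterministic forward pass. If `X` has column names they are matched to
#' the training columns (any order); otherwise the width must match.
#'
#' @param object a `milieu_net`.
#' @param X predictor matrix.
#' @param ... unused.
#' @return numeric vector of predicted index values, one per row of `X`.
#' @export
predict.milieu_net <- function(object, X, ...) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !is.null(object$columns)) {
    missing <- setdiff(object$columns, colnames(X))
    if (length(missing)) {
      stop("X lacks training columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    X <- X[, object$columns, drop = FALSE]
  } else if (ncol(X) != length(object$x_center)) {
    stop("X has ", ncol(X), " columns; model expects ",
         length(object$x_center), call. = FALSE)
  }
  Xs <- scale(X, center = object$x_center, scale = object$x_scale)
  fw <- forward_pass(object$W1, object$b1, object$w2, object$b2, Xs,
                     act_fun(object$activation))
  fw$yhat * object$y_scale + object$y_center
}

#' @export
print.milieu_net <- function(x, ...) {
  cat("feed-forward net: ", length(x$x_center), "-", ncol(x$W1), "-1 (",
      x$activation, "), best restart ", x$restart, ", ", x$epochs,
      " epochs, val MSE ", signif(x$val_mse, 4), "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a trained network as JSON
#'
#' @param model a `milieu_net`.
#' @param path JSON path.
#' @return `path` invisibly; `read_network` returns the restored model.
#' @export
write_network <- function(model, path) {
  stopifnot(inherits(model, "milieu_net"))
  payload <- model[c("W1", "b1", "w2", "b2", "activation", "columns",
                     "x_center", "x_scale", "y_center", "y_scale",
                     "epochs", "val_mse", "restart", "seed")]
  payload$W1 <- as.data.frame(payload$W1)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  p <- jsonlite::fromJSON(path)
  p$W1 <- as.matrix(p$W1)
  dimnames(p$W1) <- NULL
  p$x_center <- unlist(p$x_center); p$x_scale <- unlist(p$x_scale)
  names(p$x_center) <- p$columns; names(p$x_scale) <- p$columns
  structure(p, class = "milieu_net")
}

WAVE_NAMES <- c("health_cognitions", "personality", "lifestyle_cognitions",
                "lifestyle_activities", "baseline_health", "saturated")

#' Run the six prediction waves
#'
#' Trains one network per predictor block ("test waves") and a sixth,
#' saturated network on all block columns concatenated, each predicting the
#' health-behavior index. Per-participant estimates come from the
#' early-stopped network applied to all rows; with
#' `holdout_estimates = TRUE`, estimates are instead cross-validated
#' (k-fold, each row predicted by a network that never trained on it).
#'
#' @param blocks a `predictor_blocks` object.
#' @param y the health-behavior index.
#' @param config a [network_config()]; per-wave seeds are derived from its
#'   seed and the wave name.
#' @param holdout_estimates use k-fold cross-validated estimates
#'   (sensitivity mode; default `FALSE`).
#' @param folds number of folds in holdout mode.
#' @return an object of class `wave_set`: a named list of six `wave_result`
#'   objects (`wave_name`, `estimates`, `r_with_target`, `model`).
#' @export
run_prediction_waves <- function(blocks, y, config = network_config(),
                                 holdout_estimates = FALSE, folds = 5L) {
  stopifnot(inherits(blocks, "predictor_blocks"))
  inputs <- c(unclass(blocks), list(saturated = do.call(cbind, unclass(blocks))))
  names(inputs) <- WAVE_NAMES
  waves <- lapply(WAVE_NAMES, function(wn) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("wave:", wn))
    X <- inputs[[wn]]
    res <- tryCatch({
      if (holdout_estimates) {
        est <- crossval_estimates(X, y, cfg, folds)
        model <- train_network(X, y, cfg)
      } else {
        model <- train_network(X, y, cfg)
        est <- predict(model, X)
      }
      list(model = model, est = est)
    }, error = function(e) {
      stop("wave '", wn, "': ", conditionMessage(e), call. = FALSE)
    })
    structure(list(wave_name = wn, estimates = res$est,
                   r_with_target = safe_cor(res$est, y, wn),
                   model = res$model),
              class = "wave_result")
  })
  names(waves) <- WAVE_NAMES
  structure(waves, class = "wave_set")
}

crossval_estimates <- function(X, y, config, folds) {
  n <- nrow(X)
  fold_id <- with_seed(derive_seed(config$seed, "cv_folds"),
                       sample(rep_len(seq_len(folds), n)))
  est <- numeric(n)
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("fold:", f))
    m <- train_network(X[!hold, , drop = FALSE], y[!hold], cfg)
    est[hold] <- predict(m, X[hold, , drop = FALSE])
  }
  est
}

#' @export
print.wave_set <- function(x, ...) {
  r <- vapply(x, `[[`, numeric(1), "r_with_target")
  cat("prediction waves (r with target):\n")
  for (nm in names(r)) cat(sprintf("  %-22s %+ .3f\n", nm, r[nm]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
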