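## Two-stage cluster analysis of predictor-target patterns and Cohen's-d
## salience profiling.
##
## Stage 1 builds a Ward (ward.D2 on Euclidean distance) tree over the
## participant feature matrix and selects the number of clusters by the
## largest relative jump in merge heights within a candidate range; stage 2
## refines the Ward cut with k-means started from the cut's centroids
## (deterministic: fixed starting centers, no random restarts). Groups are
## then ordered by mean health-behavior index, labeled (high, moderate, low,
## very_low, ...), and profiled variable-by-variable with Cohen's d of each
## group against the remaining sample; |d| >= 0.50 flags a salient variable.

#' Clustering configuration
#'
#' @param feature_mode what to cluster: `"predictors_plus_estimate"`
#'   (default; all standardized predictor columns plus the re-standardized
#'   saturated-wave estimate), `"predictors_only"`, or `"hidden_activations"`
#'   (the saturated network's hidden-layer outputs per participant).
#' @param k_min,k_max candidate range for the number of clusters
#'   (default 2..8).
#' @param k_override fixed k, bypassing selection (must lie in the range);
#'   clustering solutions are ultimately judged by interpretability, so an
#'   override is a first-class option.
#' @param refine_with_kmeans run the k-means refinement stage
#'   (default `TRUE`).
#' @param min_cluster_size smallest admissible cluster (default 1; small but
#'   interpretable clusters are retained).
#' @param seed seed reserved for stochastic variants.
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(feature_mode = c("predictors_plus_estimate",
                                            "predictors_only",
                                            "hidden_activations"),
                           k_min = 2L, k_max = 8L, k_override = NULL,
                           refine_with_kmeans = TRUE,
                           min_cluster_size = 1L, seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(k_min >= 1, k_max >= k_min, min_cluster_size >= 1)
  if (!is.null(k_override) && (k_override < k_min || k_override > k_max)) {
    stop("k_override (", k_override, ") outside k range [", k_min, ", ",
         k_max, "]", call. = FALSE)
  }
  structure(list(feature_mode = feature_mode, k_min = as.integer(k_min),
                 k_max = as.integer(k_max), k_override = k_override,
                 refine_with_kmeans = isTRUE(refine_with_kmeans),
                 min_cluster_size = as.integer(min_cluster_size),
                 seed = as.integer(seed)),
            class = "cluster_config")
}

#' Build the feature matrix for clustering
#'
#' All columns are re-standardized; columns are ordered by name so the
#' solution is invariant to input column order.
#'
#' @param blocks a `predictor_blocks`.
#' @param saturated the saturated `wave_result` (needed unless
#'   `feature_mode = "predictors_only"`).
#' @param config a [cluster_config()].
#' @return numeric feature matrix (participants x features).
#' @export
build_cluster_matrix <- function(blocks, saturated = NULL,
                                 config = cluster_config()) {
  stopifnot(inherits(blocks, "predictor_blocks"))
  X <- do.call(cbind, unclass(blocks))
  if (config$feature_mode == "hidden_activations") {
    if (is.null(saturated) || is.null(saturated$model)) {
      stop("hidden_activations mode requires the saturated wave's model",
           call. = FALSE)
    }
    m <- saturated$model
    Xs <- scale(X[, m$columns, drop = FALSE], center = m$x_center,
                scale = m$x_scale)
    A <- act_fun(m$activation)(sweep(Xs %*% m$W1, 2L, m$b1, `+`))
    colnames(A) <- paste0("hidden_", seq_len(ncol(A)))
    X <- A
  } else if (config$feature_mode == "predictors_plus_estimate") {
    if (is.null(saturated)) {
      stop("predictors_plus_estimate mode requires the saturated wave",
           call. = FALSE)
    }
    X <- cbind(X, saturated_estimate = saturated$estimates)
  }
  X <- X[, order(colnames(X)), drop = FALSE]
  zscore_columns(X, "cluster features")
}

## k by the largest relative jump in Ward merge heights within [k_min, k_max].
select_k <- function(heights, k_min, k_max, n) {
  ks <- seq.int(max(2L, k_min), min(k_max, n - 1L))
  ## cutting into k clusters undoes the merge at height[n - k + 1]; compare
  ## it with the merge just below it
  ratio <- vapply(ks, function(k) {
    hi <- heights[n - k + 1L]
    lo <- heights[n - k]
    if (lo <= 0) Inf else hi / lo
  }, numeric(1))
  ks[which.max(ratio)]
}

#' Two-stage cluster analysis
#'
#' @param X feature matrix from [build_cluster_matrix()] (or any numeric
#'   matrix with one row per participant).
#' @param config a [cluster_config()].
#' @return an object of class `cluster_solution`: `assignments` (1..k,
#'   relabeled by descending size), `k`, `sizes`, `centroids`, the Ward merge
#'   `heights`, and the `config` used.
#' @export
two_stage_cluster <- function(X, config = cluster_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L * config$k_min) {
    stop("need at least 2 * k_min rows", call. = FALSE)
  }
  d <- stats::dist(X)
  if (all(d < 1e-12)) {
    warning("all rows identical; returning a single cluster", call. = FALSE)
    return(structure(list(assignments = rep(1L, n), k = 1L, sizes = n,
                          centroids = matrix(colMeans(X), 1,
                                             dimnames = list(NULL, colnames(X))),
                          heights = numeric(0), config = config),
                     class = "cluster_solution"))
  }
  tree <- stats::hclust(d, method = "ward.D2")
  k <- config$k_override %||%
    select_k(tree$height, config$k_min, config$k_max, n)
  cut <- stats::cutree(tree, k = k)

  centroids <- centroid_matrix(X, cut, k)
  assign <- cut
  if (config$refine_with_kmeans && k > 1L) {
    km <- suppressWarnings(stats::kmeans(X, centers = centroids,
                                         iter.max = 100L, algorithm = "Lloyd"))
    assign <- km$cluster
    centroids <- km$centers
  }

  sizes <- tabulate(assign, k)
  if (any(sizes < config$min_cluster_size)) {
    warning("cluster(s) below min_cluster_size retained: sizes ",
            paste(sizes, collapse = ", "), call. = FALSE)
  }
  ## stable output: relabel by descending size (ties: first occurrence)
  ord <- order(-sizes, match(seq_len(k), unique(assign)))
  relabel <- match(seq_len(k), ord)
  assign <- relabel[assign]
  centroids <- centroids[ord, , drop = FALSE]
  rownames(centroids) <- NULL

  structure(list(assignments = as.integer(assign), k = as.integer(k),
                 sizes = tabulate(assign, k),
                 centroids = centroids, heights = tree$height,
                 config = config),
            class = "cluster_solution")
}

centroid_matrix <- function(X, assign, k) {
  out <- matrix(NA_real_, k, ncol(X), dimnames = list(NULL, colnames(X)))
  for (g in seq_len(k)) out[g, ] <- colMeans(X[assign == g, , drop = FALSE])
  out
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("two-stage cluster solution: k = ", x$k, ", sizes ",
      paste(x$sizes, collapse = "/", sep = ""), "\n", sep = "")
  if (!is.null(x$labels)) {
    cat("engagement order:", paste(x$labels, collapse = " > "), "\n")
    cat("engagement d:", paste(round(x$engagement_d, 2), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cohen's d of a group against the rest of the sample
#'
#' `d = (mean(group) - mean(rest)) / s_pooled`, with the classical pooled
#' standard deviation `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' Positive d means the group exceeds the rest. If the pooled SD is zero the
#' result is 0 for equal means and signed infinity otherwise.
#'
#' @param group_values numeric vector (length >= 2).
#' @param rest_values numeric vector (length >= 2).
#' @return Cohen's d.
#' @export
cohens_d <- function(group_values, rest_values) {
  n1 <- length(group_values); n2 <- length(rest_values)
  if (n1 < 2L || n2 < 2L) {
    stop("cohens_d needs at least 2 values in each sample", call. = FALSE)
  }
  s_pooled <- sqrt(((n1 - 1) * stats::var(group_values) +
                      (n2 - 1) * stats::var(rest_values)) / (n1 + n2 - 2))
  diff <- mean(group_values) - mean(rest_values)
  if (s_pooled == 0) {
    if (diff == 0) return(0)
    return(sign(diff) * Inf)
  }
  diff / s_pooled
}

#' Order clusters by health-behavior engagement
#'
#' Ranks groups by descending mean health-behavior index, assigns labels from
#' the ordered vocabulary (high, moderate, low, very_low, then `group_5`,
#' ...), relabels the solution in that order, and computes each group's
#' engagement effect size (Cohen's d of the group's index values against the
#' other groups combined). Mean ties are broken by descending group size
#' (with a message).
#'
#' @param solution a `cluster_solution`.
#' @param health_index the health-behavior index vector.
#' @return the solution with `assignments`, `sizes`, `centroids` reordered by
#'   engagement and new fields `labels`, `engagement_mean`, `engagement_d`.
#' @export
engagement_ordering <- function(solution, health_index) {
  stopifnot(inherits(solution, "cluster_solution"))
  k <- solution$k
  if (k == 1L) {
    solution$labels <- "all"
    solution$engagement_mean <- mean(health_index)
    solution$engagement_d <- NA_real_
    return(solution)
  }
  means <- vapply(seq_len(k), function(g)
    mean(health_index[solution$assignments == g]), numeric(1))
  if (anyDuplicated(round(means, 12))) {
    message("engagement ties broken by descending group size")
  }
  ord <- order(-means, -solution$sizes)
  relabel <- match(seq_len(k), ord)
  solution$assignments <- as.integer(relabel[solution$assignments])
  solution$sizes <- solution$sizes[ord]
  solution$centroids <- solution$centroids[ord, , drop = FALSE]
  solution$engagement_mean <- means[ord]
  vocab <- switch(min(k, 4),
                  "all",
                  c("high", "low"),
                  c("high", "moderate", "low"),
                  c("high", "moderate", "low", "very_low"))
  solution$labels <- c(vocab, paste0("group_", seq_len(max(0, k - 4)) + 4L))[seq_len(k)]
  solution$engagement_d <- vapply(seq_len(k), function(g) {
    if (solution$sizes[g] < 2L || sum(solution$sizes[-g]) < 2L) return(NA_real_)
    cohens_d(health_index[solution$assignments == g],
             health_index[solution$assignments != g])
  }, numeric(1))
  solution
}

## The profiled variable set: all predictor columns, sectioned as in the
## standard report (health cognitions, personality, lifestyle cognitions,
## lifestyle activities, baseline health behaviors).
profile_variables <- function(blocks) {
  lapply(unclass(blocks), colnames)
}

#' Cohen's-d salience profile of a cluster solution
#'
#' For every group and every predictor variable, computes Cohen's d of the
#' group against all other groups combined, and flags |d| >= `threshold` as
#' salient. Groups with fewer than 2 members get `NA` (with a warning): a
#' group-vs-rest d is undefined there.
#'
#' @param solution a `cluster_solution` (ideally engagement-ordered).
#' @param std the `standardized_dataset` the solution was built from.
#' @param blocks the `predictor_blocks` (defines the variable set and its
#'   sectioning).
#' @param threshold salience threshold on |d| (default 0.50).
#' @return an object of class `salience_profile`: `d_matrix` (variables x
#'   groups), `salient_mask`, `threshold`, `sections`, plus the solution's
#'   labels and sizes.
#' @export
salience_profile <- function(solution, std, blocks, threshold = 0.50) {
  stopifnot(inherits(solution, "cluster_solution"),
            inherits(std, "standardized_dataset"))
  if (solution$k < 2L) {
    stop("salience requires k >= 2: with a single group there is no 'rest'",
         call. = FALSE)
  }
  if (length(solution$assignments) != length(std$health_index)) {
    stop("solution and dataset have different participant counts",
         call. = FALSE)
  }
  sections <- profile_variables(blocks)
  vars <- unlist(sections, use.names = FALSE)
  M <- do.call(cbind, unclass(blocks))[, vars, drop = FALSE]
  k <- solution$k
  if (any(solution$sizes < 2L)) {
    warning("group(s) of size < 2: their d values are undefined (NA)",
            call. = FALSE)
  }
  d_matrix <- matrix(NA_real_, length(vars), k,
                     dimnames = list(vars, solution$labels %||%
                                       paste0("group_", seq_len(k))))
  for (g in seq_len(k)) {
    ing <- solution$assignments == g
    if (sum(ing) < 2L || sum(!ing) < 2L) next
    d_matrix[, g] <- vapply(vars, function(v)
      cohens_d(M[ing, v], M[!ing, v]), numeric(1))
  }
  structure(list(d_matrix = d_matrix,
                 salient_mask = !is.na(d_matrix) & abs(d_matrix) >= threshold,
                 threshold = threshold,
                 sections = sections,
                 labels = colnames(d_matrix),
                 sizes = solution$sizes),
            class = "salience_profile")
}

#' @export
print.salience_profile <- function(x, ...) {
  cat("salience profile: ", nrow(x$d_matrix), " variables x ",
      ncol(x$d_matrix), " groups; ", sum(x$salient_mask, na.rm = TRUE),
      " salient cells at |d| >= ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Render the salience profile as a report table
#'
#' Variables as rows (grouped into the five predictor sections), groups as
#' columns. Sub-threshold d values are blanked, as in the conventional
#' report; use `full = TRUE` (or the companion full-matrix file written by
#' [run_pipeline()]) for all values.
#'
#' @param profile a `salience_profile`.
#' @param full emit all d values instead of blanking sub-threshold cells.
#' @param digits rounding for the d values.
#' @return a data.frame with columns `section`, `variable`, then one column
#'   per group.
#' @export
salience_table <- function(profile, full = FALSE, digits = 2) {
  stopifnot(inherits(profile, "salience_profile"))
  rows <- data.frame(
    section = rep(names(profile$sections),
                  vapply(profile$sections, length, integer(1))),
    variable = unlist(profile$sections, use.names = FALSE),
    stringsAsFactors = FALSE)
  d <- round(profile$d_matrix[rows$variable, , drop = FALSE], digits)
  for (g in colnames(d)) {
    col <- d[, g]
    if (!full) {
      shown <- ifelse(!is.na(col) & abs(col) >= profile$threshold,
                      formatC(col, format = "f", digits = digits), "")
      rows[[g]] <- shown
    } else {
      rows[[g]] <- col
    }
  }
  rownames(rows) <- NULL
  rows
}
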