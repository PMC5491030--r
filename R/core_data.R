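## Core data module: the raw participant-level dataset (two-week behavior
## frequency counts at baseline and follow-up, per-behavior cognition scores,
## personality scales), its CSV interface, column-wise standardization with
## risk-behavior reversal, the composite health-behavior index, and the five
## predictor blocks.

#' Construct a raw participant-level dataset
#'
#' @param pid character or integer participant identifiers.
#' @param baseline_counts n x B matrix of nonnegative integer counts (times
#'   each behavior was performed in the two weeks before baseline); columns
#'   named `beh_<name>_t1`.
#' @param cognitions n x 4B matrix of cognition construct scores on 1--7
#'   scales, columns `cog_<name>_<construct>` with constructs ordered
#'   intention, attitude, norm, pbc within behavior.
#' @param personality n x 5 matrix of personality scale scores, columns
#'   `pers_locus`, `pers_acs_preocc`, `pers_acs_hesit`, `pers_esteem`,
#'   `pers_self_eff`.
#' @param followup_counts n x B matrix of follow-up counts, columns
#'   `beh_<name>_t2`.
#' @param catalog the `behavior_catalog` the matrices follow.
#' @return an object of class `raw_dataset`.
#' @export
raw_dataset <- function(pid, baseline_counts, cognitions, personality,
                        followup_counts, catalog) {
  stopifnot(inherits(catalog, "behavior_catalog"))
  n <- length(pid)
  mats <- list(baseline_counts = as.matrix(baseline_counts),
               cognitions = as.matrix(cognitions),
               personality = as.matrix(personality),
               followup_counts = as.matrix(followup_counts))
  for (nm in names(mats)) {
    if (nrow(mats[[nm]]) != n) {
      stop("row count of ", nm, " (", nrow(mats[[nm]]),
           ") does not match number of participants (", n, ")", call. = FALSE)
    }
  }
  x <- structure(c(list(pid = pid), mats, list(catalog = catalog)),
                 class = "raw_dataset")
  validate_raw(x)
  x
}

validate_raw <- function(x) {
  counts <- cbind(x$baseline_counts, x$followup_counts)
  if (anyNA(counts) || anyNA(x$cognitions) || anyNA(x$personality)) {
    stop("missing values are not allowed; impute or drop before loading",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1L, ]
    stop("behavior counts must be nonnegative integers; offending value at row ",
         bad[1L], ", column '", colnames(counts)[bad[2L]], "'", call. = FALSE)
  }
  if (any(x$cognitions < 1 | x$cognitions > 7)) {
    bad <- which(x$cognitions < 1 | x$cognitions > 7, arr.ind = TRUE)[1L, ]
    stop("cognition scores must lie in [1, 7]; offending value at row ",
         bad[1L], ", column '", colnames(x$cognitions)[bad[2L]], "'",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat("raw dataset: ", length(x$pid), " participants, ",
      nrow(x$catalog$behaviors), " behaviors\n", sep = "")
  invisible(x)
}

#' Number of participants in a dataset
#' @param x a `raw_dataset` or `standardized_dataset`.
#' @return integer participant count.
#' @export
n_participants <- function(x) {
  if (inherits(x, "raw_dataset")) return(length(x$pid))
  if (inherits(x, "standardized_dataset")) return(length(x$health_index))
  stop("unsupported object", call. = FALSE)
}

#' Load a raw dataset from CSV
#'
#' The CSV must carry a header with exactly the schema columns for `catalog`:
#' `pid`; `beh_<name>_t1` and `beh_<name>_t2` integer counts;
#' `cog_<name>_intention|attitude|norm|pbc` decimals in \[1, 7\]; and the five
#' `pers_*` personality scores. Column order is free; row order is preserved.
#'
#' @param path CSV path.
#' @param catalog a `behavior_catalog` (default: the 28-behavior catalog).
#' @return a validated `raw_dataset`.
#' @export
load_raw <- function(path, catalog = default_catalog()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  want <- schema_columns(catalog)
  missing <- setdiff(want, names(df))
  extra <- setdiff(names(df), want)
  if (length(missing) || length(extra)) {
    stop("CSV schema mismatch.",
         if (length(missing)) paste0(" Missing columns: ",
                                     paste(missing, collapse = ", "), "."),
         if (length(extra)) paste0(" Unexpected columns: ",
                                   paste(extra, collapse = ", "), "."),
         call. = FALSE)
  }
  beh <- catalog$behaviors$name
  take <- function(cols) {
    m <- as.matrix(df[, cols, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- NULL
    m
  }
  raw_dataset(pid = as.character(df$pid),
              baseline_counts = take(paste0("beh_", beh, "_t1")),
              cognitions = take(cognition_colnames(catalog)),
              personality = take(paste0("pers_", PERSONALITY_SCALES)),
              followup_counts = take(paste0("beh_", beh, "_t2")),
              catalog = catalog)
}

#' Write a raw dataset to CSV
#'
#' Inverse of [load_raw()]: emits the documented schema so that a written
#' dataset reloads to identical matrices.
#'
#' @param raw a `raw_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_raw <- function(raw, path) {
  stopifnot(inherits(raw, "raw_dataset"))
  df <- data.frame(pid = raw$pid, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df,
              as.data.frame(raw$baseline_counts, check.names = FALSE),
              as.data.frame(raw$cognitions, check.names = FALSE),
              as.data.frame(raw$personality, check.names = FALSE),
              as.data.frame(raw$followup_counts, check.names = FALSE))
  df <- df[, schema_columns(raw$catalog)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize a raw dataset and build the health-behavior index
#'
#' Every variable is z-scored column-wise (sample n - 1 standard deviation).
#' The baseline and follow-up frequency columns of reverse-coded risk
#' behaviors (by default: smoking, getting drunk, eating fast food) are then
#' multiplied by -1 so that larger values always mean healthier behavior.
#' The composite health-behavior index is the row mean of the five reversed
#' follow-up health-behavior z-scores; it is the analysis target.
#'
#' Cognition scores are not sign-reversed by default: items for risk
#' behaviors are worded as avoidance ("avoid smoking"), so their scores
#' already point in the healthy direction. Set `reverse_cognitions = TRUE`
#' for instruments whose risk-behavior cognitions are worded toward the risk
#' behavior itself.
#'
#' @param raw a `raw_dataset`.
#' @param catalog the behavior catalog (defaults to the dataset's own).
#' @param reverse_cognitions also reverse the four cognition columns of each
#'   risk behavior (default `FALSE`).
#' @return an object of class `standardized_dataset` with elements
#'   `z_baseline`, `z_cognitions`, `z_personality`, `z_followup` (matrices)
#'   and `health_index` (numeric vector).
#' @export
standardize <- function(raw, catalog = raw$catalog,
                        reverse_cognitions = FALSE) {
  stopifnot(inherits(raw, "raw_dataset"))
  z_baseline <- zscore_columns(raw$baseline_counts, "baseline counts")
  z_cognitions <- zscore_columns(raw$cognitions, "cognitions")
  z_personality <- zscore_columns(raw$personality, "personality")
  z_followup <- zscore_columns(raw$followup_counts, "follow-up counts")

  risk <- risk_names(catalog)
  flip <- function(m, cols) {
    hit <- colnames(m) %in% cols
    m[, hit] <- -m[, hit]
    m
  }
  z_baseline <- flip(z_baseline, paste0("beh_", risk, "_t1"))
  z_followup <- flip(z_followup, paste0("beh_", risk, "_t2"))
  if (isTRUE(reverse_cognitions)) {
    z_cognitions <- flip(z_cognitions,
                         as.vector(outer(paste0("cog_", risk, "_"),
                                         COGNITION_CONSTRUCTS, paste0)))
  }

  health_cols <- paste0("beh_", health_names(catalog), "_t2")
  health_index <- rowMeans(z_followup[, health_cols, drop = FALSE])

  structure(list(pid = raw$pid,
                 z_baseline = z_baseline,
                 z_cognitions = z_cognitions,
                 z_personality = z_personality,
                 z_followup = z_followup,
                 health_index = health_index,
                 catalog = catalog,
                 reverse_cognitions = isTRUE(reverse_cognitions)),
            class = "standardized_dataset")
}

#' @export
print.standardized_dataset <- function(x, ...) {
  cat("standardized dataset: ", length(x$health_index), " participants; ",
      "health index mean ", signif(mean(x$health_index), 3),
      ", sd ", signif(stats::sd(x$health_index), 3), "\n", sep = "")
  invisible(x)
}

#' Assemble the five predictor blocks
#'
#' Splits the standardized columns into the five predictor types used as
#' network inputs: behavior-specific health cognitions (4 constructs x health
#' behaviors), personality scales, lifestyle cognitions, ongoing lifestyle
#' activity frequencies at follow-up, and baseline health-behavior
#' frequencies. The five follow-up health columns are excluded from every
#' block -- they form the target index only. For the default catalog the
#' block widths are 20, 5, 92, 23, 5.
#'
#' @param std a `standardized_dataset`.
#' @param catalog the behavior catalog (defaults to the dataset's own).
#' @return an object of class `predictor_blocks`: a named list of matrices
#'   in the fixed order `health_cognitions`, `personality`,
#'   `lifestyle_cognitions`, `lifestyle_activities`, `baseline_health`.
#' @export
assemble_blocks <- function(std, catalog = std$catalog) {
  stopifnot(inherits(std, "standardized_dataset"))
  health <- health_names(catalog)
  life <- lifestyle_names(catalog)
  cog_cols <- function(behaviors) {
    as.vector(t(outer(paste0("cog_", behaviors, "_"),
                      COGNITION_CONSTRUCTS, paste0)))
  }
  blocks <- list(
    health_cognitions = std$z_cognitions[, cog_cols(health), drop = FALSE],
    personality = std$z_personality,
    lifestyle_cognitions = std$z_cognitions[, cog_cols(life), drop = FALSE],
    lifestyle_activities = std$z_followup[, paste0("beh_", life, "_t2"),
                                          drop = FALSE],
    baseline_health = std$z_baseline[, paste0("beh_", health, "_t1"),
                                     drop = FALSE])
  structure(blocks, class = "predictor_blocks")
}

#' @export
print.predictor_blocks <- function(x, ...) {
  w <- vapply(unclass(x), ncol, integer(1))
  cat("predictor blocks:", paste(names(w), w, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Block widths
#' @param blocks a `predictor_blocks` object.
#' @return named integer vector of column counts.
#' @export
block_widths <- function(blocks) {
  vapply(unclass(blocks), ncol, integer(1))
}
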