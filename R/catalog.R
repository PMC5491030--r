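## Behavior catalog: the declarative list of behaviors a study measures.
## The default catalog holds the 28 study behaviors: 5 health-related
## (3 of them risk behaviors that are reverse-coded in the analysis) and
## 23 other lifestyle activities.

COGNITION_CONSTRUCTS <- c("intention", "attitude", "norm", "pbc")
PERSONALITY_SCALES <- c("locus", "acs_preocc", "acs_hesit", "esteem", "self_eff")

#' Construct a behavior catalog
#'
#' A behavior catalog is an ordered table of behaviors with two flags:
#' `is_health` marks the focal health behaviors whose follow-up frequencies
#' form the composite health-behavior index, and `is_risk` marks health
#' behaviors that are reverse-coded (multiplied by -1 after z-scoring) so
#' that higher index values always mean healthier behavior.
#'
#' @param behaviors data.frame with columns `name` (unique snake_case slugs),
#'   `label` (display text), `is_health`, `is_risk` (logicals).
#' @return an object of class `behavior_catalog`.
#' @export
behavior_catalog <- function(behaviors) {
  stopifnot(is.data.frame(behaviors),
            all(c("name", "label", "is_health", "is_risk") %in% names(behaviors)))
  behaviors$name <- as.character(behaviors$name)
  behaviors$label <- as.character(behaviors$label)
  behaviors$is_health <- as.logical(behaviors$is_health)
  behaviors$is_risk <- as.logical(behaviors$is_risk)
  if (anyDuplicated(behaviors$name)) {
    stop("behavior names must be unique", call. = FALSE)
  }
  if (any(behaviors$is_risk & !behaviors$is_health)) {
    stop("is_risk behaviors must also be is_health", call. = FALSE)
  }
  if (sum(behaviors$is_health) < 1L) {
    stop("catalog needs at least one health behavior", call. = FALSE)
  }
  structure(list(behaviors = behaviors), class = "behavior_catalog")
}

#' The default 28-behavior catalog
#'
#' Five health behaviors (exercising, smoking, getting drunk, eating fruit,
#' eating fast food -- the latter three reverse-coded as risk behaviors) and
#' twenty-three other lifestyle activities measured over two-week windows.
#'
#' @return a `behavior_catalog` with 28 rows.
#' @export
default_catalog <- function() {
  read_catalog(system.file("extdata", "default_catalog.json",
                           package = "milieu", mustWork = TRUE))
}

#' Read a behavior catalog from JSON
#'
#' The JSON interface is a list of records with fields `name`, `label`,
#' `is_health`, `is_risk`, so users can define behavior sets other than the
#' default 28.
#'
#' @param path path to a catalog JSON file.
#' @return a `behavior_catalog`.
#' @export
read_catalog <- function(path) {
  behavior_catalog(jsonlite::fromJSON(path))
}

#' Write a behavior catalog to JSON
#'
#' @param catalog a `behavior_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "behavior_catalog"))
  jsonlite::write_json(catalog$behaviors, path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.behavior_catalog <- function(x, ...) {
  b <- x$behaviors
  cat("behavior catalog: ", nrow(b), " behaviors (",
      sum(b$is_health), " health, ", sum(b$is_risk), " reverse-coded risk)\n",
      sep = "")
  invisible(x)
}

health_names <- function(catalog) {
  b <- catalog$behaviors
  b$name[b$is_health]
}

lifestyle_names <- function(catalog) {
  b <- catalog$behaviors
  b$name[!b$is_health]
}

risk_names <- function(catalog) {
  b <- catalog$behaviors
  b$name[b$is_risk]
}

## Expected CSV column names for a catalog, in schema order.
schema_columns <- function(catalog) {
  beh <- catalog$behaviors$name
  c("pid",
    paste0("beh_", beh, "_t1"),
    as.vector(t(outer(paste0("cog_", beh, "_"), COGNITION_CONSTRUCTS, paste0))),
    paste0("pers_", PERSONALITY_SCALES),
    paste0("beh_", beh, "_t2"))
}

cognition_colnames <- function(catalog) {
  as.vector(t(outer(paste0("cog_", catalog$behaviors$name, "_"),
                    COGNITION_CONSTRUCTS, paste0)))
}
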