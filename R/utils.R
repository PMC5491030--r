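#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules: deterministic seed derivation,
## RNG-preserving evaluation, and column-wise standardization.

MERSENNE31 <- 2147483647  # 2^31 - 1; all derived seeds stay below this

#' Derive a reproducible child seed from a master seed and a stage label
#'
#' Stage-level seeds are polynomial rolling hashes of the label combined with
#' the master seed, reduced modulo 2^31 - 1 so they are always valid R
#' integer seeds. Changing unrelated configuration therefore never perturbs
#' another stage's stream.
#'
#' @param master integer master seed.
#' @param label character scalar naming the consumer (e.g. `"wave:personality"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label),
            length(label) == 1L)
  h <- as.double(master %% MERSENNE31)
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% MERSENNE31
  }
  as.integer(h %% (MERSENNE31 - 2) + 1)
}

## Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Column-wise z-scores with the sample (n - 1) standard deviation.
## Errors on zero-variance columns rather than dropping them silently.
zscore_columns <- function(x, what = "matrix") {
  x <- as.matrix(x)
  sds <- apply(x, 2L, stats::sd)
  bad <- which(!is.finite(sds) | sds == 0)
  if (length(bad) > 0L) {
    stop("zero-variance column(s) in ", what, ": ",
         paste(colnames(x)[bad], collapse = ", "), call. = FALSE)
  }
  scaled <- scale(x, center = TRUE, scale = sds)
  out <- matrix(as.numeric(scaled), nrow = nrow(x), dimnames = dimnames(x))
  out
}

## Pearson correlation that fails loudly on zero variance.
safe_cor <- function(a, b, label = "vector") {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance estimates for ", label, call. = FALSE)
  }
  stats::cor(a, b)
}
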