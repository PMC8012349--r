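# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' One user-facing seed is expanded into independent named substreams so that
#' adding a new generator or stage never shifts the random numbers consumed by
#' another. The derivation is a small multiplicative hash kept below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stream character name of the substream.
#' @return an integer seed usable with [set.seed()].
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% m
  as.integer((h * 48271) %% (m - 1) + 1)
}

# stop() with a consistent error class so callers/tests can distinguish
# configuration errors from runtime failures.
invalid_config <- function(msg) {
  stop(errorCondition(msg, class = c("flavoromics_invalid_config", "error")))
}

assert_config <- function(cond, msg) {
  if (!isTRUE(cond)) invalid_config(msg)
}

# Column-wise sample SD with the n-1 denominator, NA-aware.
col_sd <- function(x) apply(x, 2L, stats::sd, na.rm = TRUE)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Attribute scale registry: hedonic attributes live on [-100, 100] (GHIS),
# intensity attributes on [0, 100] (GSIS).
HEDONIC_ATTRIBUTES <- c("liking", "texture_liking")
INTENSITY_ATTRIBUTES <- c("sweetness", "sourness", "flavor_intensity")
ALL_ATTRIBUTES <- c(HEDONIC_ATTRIBUTES, INTENSITY_ATTRIBUTES)

attribute_bounds <- function(attribute) {
  lo <- ifelse(attribute %in% HEDONIC_ATTRIBUTES, -100, 0)
  hi <- rep(100, length(attribute))
  cbind(lo = lo, hi = hi)
}
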