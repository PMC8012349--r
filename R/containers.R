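# Core data containers. Deliberately lightweight S3: a validated data.frame
# for panel ratings, and list-of-matrix containers for chemical data, mirroring
# how metabolomics feature tables are usually carried around.

#' Construct a validated panel-ratings table
#'
#' Long-format consumer-panel records. Hedonic attributes (`liking`,
#' `texture_liking`) live on the bidirectional hedonic scale `[-100, 100]`;
#' intensity attributes (`sweetness`, `sourness`, `flavor_intensity`) on the
#' intensity scale `[0, 100]`.
#'
#' @param df data.frame with columns `panelist_id`, `session_id`, `sample_id`,
#'   `attribute`, `score`.
#' @return the data.frame with class `panel_ratings` prepended.
#' @export
panel_ratings <- function(df) {
  required <- c("panelist_id", "session_id", "sample_id", "attribute", "score")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("panel ratings are missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(df$score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$score))))
    stop("non-numeric score in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  unknown <- setdiff(unique(df$attribute), ALL_ATTRIBUTES)
  if (length(unknown)) {
    stop("unknown attribute(s): ", paste(unknown, collapse = ", "))
  }
  b <- attribute_bounds(df$attribute)
  bad <- which(df$score < b[, "lo"] | df$score > b[, "hi"])
  if (length(bad)) {
    stop(sprintf("score out of range for its scale in row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  key <- paste(df$session_id, df$panelist_id, df$sample_id, df$attribute)
  if (anyDuplicated(key)) {
    stop("duplicated (panelist, sample, attribute) record within a session, first at row ",
         which(duplicated(key))[1])
  }
  class(df) <- unique(c("panel_ratings", class(df)))
  df
}

#' Construct a validated chemical matrix
#'
#' @param abundance numeric samples x compounds matrix; `NA` marks undetected
#'   values (the detection mask is derived from, and kept consistent with, the
#'   `NA` pattern when `detected` is not supplied).
#' @param samples data.frame with `sample_id` and `period` (one period per
#'   sample).
#' @param compounds data.frame with `compound_id` and `class`.
#' @param detected optional logical matrix of the same shape as `abundance`.
#' @return an object of class `chem_matrix`.
#' @export
chem_matrix <- function(abundance, samples, compounds, detected = NULL) {
  abundance <- as.matrix(abundance)
  stopifnot(nrow(abundance) == nrow(samples),
            ncol(abundance) == nrow(compounds),
            all(c("sample_id", "period") %in% names(samples)),
            all(c("compound_id", "class") %in% names(compounds)))
  if (anyDuplicated(compounds$compound_id)) stop("compound_ids must be unique")
  if (anyDuplicated(samples$sample_id)) stop("sample_ids must be unique")
  if (is.null(detected)) detected <- !is.na(abundance)
  detected <- as.matrix(detected)
  stopifnot(identical(dim(detected), dim(abundance)))
  abundance[!detected] <- NA_real_
  if (any(abundance < 0, na.rm = TRUE)) {
    stop("detected abundances must be non-negative")
  }
  dimnames(abundance) <- list(samples$sample_id, compounds$compound_id)
  dimnames(detected) <- dimnames(abundance)
  structure(list(abundance = abundance,
                 samples = as.data.frame(samples),
                 compounds = as.data.frame(compounds),
                 detected = detected),
            class = "chem_matrix")
}

#' @export
print.chem_matrix <- function(x, ...) {
  cat(sprintf("<chem_matrix> %d samples x %d compounds, %d period(s); %.1f%% detected\n",
              nrow(x$abundance), ncol(x$abundance),
              length(unique(x$samples$period)), 100 * mean(x$detected)))
  invisible(x)
}

#' @export
dim.chem_matrix <- function(x) dim(x$abundance)
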