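# Reading and writing the plain-text interchange formats. The synthetic
# generator writes the same dialects these readers accept, so round-trips are
# exact to numeric precision.

read_delim_checked <- function(path, dialect = ",", required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Read a long-format sensory ratings table
#'
#' Expects columns `panelist_id`, `session_id`, `sample_id`, `attribute`,
#' `score`. Scores are validated against the attribute's scale
#' (`[-100, 100]` hedonic, `[0, 100]` intensity); violations are rejected
#' with the offending row numbers.
#'
#' @param path file path.
#' @param dialect field delimiter, `","` or `"\t"`.
#' @return a [panel_ratings()] data.frame.
#' @export
read_sensory <- function(path, dialect = ",") {
  df <- read_delim_checked(path, dialect,
                           c("panelist_id", "session_id", "sample_id",
                             "attribute", "score"))
  df$score <- suppressWarnings(as.numeric(df$score))
  panel_ratings(df)
}

#' @rdname read_sensory
#' @param ratings a [panel_ratings()] table.
#' @export
write_sensory <- function(ratings, path, dialect = ",") {
  utils::write.table(as.data.frame(ratings), path, sep = dialect,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a sample-by-compound chemical matrix
#'
#' The wide CSV has `sample_id` and `period` columns followed by one column
#' per compound; empty cells are undetected values. Compound classes travel
#' in a companion two-column table (`compound_id`, `class`); absent companion
#' columns default to class `"other"`.
#'
#' @param path abundance CSV path.
#' @param compound_info optional path to the compound class table.
#' @param dialect field delimiter.
#' @return a [chem_matrix()].
#' @export
read_chemicals <- function(path, compound_info = NULL, dialect = ",") {
  df <- read_delim_checked(path, dialect, c("sample_id", "period"))
  ids <- setdiff(names(df), c("sample_id", "period"))
  if (!length(ids)) stop(path, ": no compound columns found")
  ab <- as.matrix(df[ids])
  if (!is.numeric(ab)) {
    bad <- which(!apply(ab, 1, function(r) all(is.na(r) | !is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric abundance in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  neg <- which(apply(ab, 1, function(r) any(r < 0, na.rm = TRUE)))
  if (length(neg)) {
    stop("negative abundance in row(s): ", paste(utils::head(neg, 5), collapse = ", "))
  }
  cls <- rep("other", length(ids))
  if (!is.null(compound_info)) {
    info <- read_delim_checked(compound_info, dialect, c("compound_id", "class"))
    cls <- info$class[match(ids, info$compound_id)]
    cls[is.na(cls)] <- "other"
  }
  chem_matrix(ab,
              data.frame(sample_id = as.character(df$sample_id),
                         period = as.character(df$period),
                         stringsAsFactors = FALSE),
              data.frame(compound_id = ids, class = cls, stringsAsFactors = FALSE))
}

#' @rdname read_chemicals
#' @param chem a [chem_matrix()].
#' @param compound_info_path optional path for the class table.
#' @export
write_chemicals <- function(chem, path, compound_info_path = NULL, dialect = ",") {
  df <- data.frame(sample_id = chem$samples$sample_id,
                   period = chem$samples$period,
                   chem$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = dialect, row.names = FALSE, quote = FALSE,
                     na = "")
  if (!is.null(compound_info_path)) {
    utils::write.table(chem$compounds, compound_info_path, sep = dialect,
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a genotype dosage matrix with its marker map
#'
#' @param path samples x markers dosage CSV (first column `sample_id`).
#' @param map_path marker map CSV with `marker_id`, `linkage_group`, `position`.
#' @param dialect field delimiter.
#' @return a `genotype_matrix` list.
#' @export
read_genotypes <- function(path, map_path, dialect = ",") {
  df <- read_delim_checked(path, dialect, "sample_id")
  G <- as.matrix(df[setdiff(names(df), "sample_id")])
  rownames(G) <- df$sample_id
  if (any(!(G %in% c(0, 1, 2, NA)))) stop("dosages must be 0, 1, 2 or missing")
  map <- read_delim_checked(map_path, dialect,
                            c("marker_id", "linkage_group", "position"))
  if (any(map$position < 0)) stop("marker positions must be non-negative")
  structure(list(G = G, map = map, phenotype = NULL,
                 sample_ids = rownames(G)),
            class = "genotype_matrix")
}
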