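#' Autoscale a chemical matrix within each measurement period
#'
#' Multi-batch chemical quantifications carry technical offsets between
#' measurement periods. Autoscaling (z-scoring) each compound within each
#' period centers all periods to mean 0 and SD 1 so they can be merged.
#' The SD uses the sample (n-1) denominator. Undetected (`NA`) values are
#' excluded from the mean/SD computation and stay `NA` in the output (see
#' [impute_scaled()] for the imputation used ahead of correlation/PLS).
#' Compounds with fewer than two detected values or zero variance within a
#' period are dropped from that period with a warning and logged in the
#' `dropped` element.
#'
#' @param chem a [chem_matrix()].
#' @return an object of class `scaled_matrix`: list with `values` (z-score
#'   matrix, `NA` where undetected or dropped), `samples`, `compounds`,
#'   `scaling` (per compound x period means/SDs), `dropped`.
#' @export
autoscale_by_period <- function(chem) {
  stopifnot(inherits(chem, "chem_matrix"))
  periods <- unique(chem$samples$period)
  z <- chem$abundance
  z[] <- NA_real_
  scaling <- list(); dropped <- list()
  for (p in periods) {
    rows <- chem$samples$period == p
    sub <- chem$abundance[rows, , drop = FALSE]
    m <- colMeans(sub, na.rm = TRUE)
    s <- col_sd(sub)
    n_det <- colSums(!is.na(sub))
    ok <- n_det >= 2 & !is.na(s) & s > 0
    if (any(!ok & n_det > 0)) {
      bad <- colnames(sub)[!ok & n_det > 0]
      warning(sprintf("period %s: dropping %d compound(s) with < 2 detected values or zero variance: %s",
                      p, length(bad), paste(utils::head(bad, 5), collapse = ", ")),
              call. = FALSE)
      dropped[[p]] <- data.frame(period = p, compound_id = bad,
                                 stringsAsFactors = FALSE)
    }
    zk <- sweep(sweep(sub, 2, m), 2, s, "/")
    zk[, !ok] <- NA_real_
    z[rows, ] <- zk
    scaling[[p]] <- data.frame(period = p, compound_id = colnames(sub),
                               mean = m, sd = s, n_detected = n_det,
                               retained = ok, row.names = NULL,
                               stringsAsFactors = FALSE)
  }
  structure(list(values = z,
                 samples = chem$samples,
                 compounds = chem$compounds,
                 scaling = do.call(rbind, scaling),
                 dropped = if (length(dropped)) do.call(rbind, dropped) else NULL),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("<scaled_matrix> %d samples x %d compounds over %d period(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$period))))
  invisible(x)
}

# Period-level presence: a compound counts as present in a period when it was
# retained there by autoscaling (>= 2 detected values, nonzero variance).
period_presence <- function(scaled) {
  sc <- scaled$scaling
  periods <- unique(scaled$samples$period)
  pres <- sapply(periods, function(p) {
    r <- sc[sc$period == p, ]
    r$retained[match(scaled$compounds$compound_id, r$compound_id)]
  })
  pres[is.na(pres)] <- FALSE
  dimnames(pres) <- list(scaled$compounds$compound_id, periods)
  pres
}

#' Merge autoscaled periods into one analysis matrix
#'
#' In `"common"` mode only compounds present (retained by scaling) in every
#' period are kept -- the cross-period intersection the downstream
#' correlation, clustering and selection analyses are built on. `"union"`
#' keeps everything. An intersection report counts retained compounds by
#' chemical class.
#'
#' @param scaled a `scaled_matrix` from [autoscale_by_period()].
#' @param mode `"common"` or `"union"`.
#' @return a `scaled_matrix` restricted to the selected compounds, with an
#'   `intersection_report` attribute (data.frame of class counts).
#' @export
merge_periods <- function(scaled, mode = c("common", "union")) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  mode <- match.arg(mode)
  periods <- unique(scaled$samples$period)
  if (length(periods) < 2) stop("merge_periods() needs at least two periods")
  pres <- period_presence(scaled)
  keep <- if (mode == "common") rowSums(pres) == ncol(pres) else rowSums(pres) > 0
  if (!any(keep)) {
    stop("no compound is present in every period; the period compound sets are disjoint")
  }
  out <- scaled
  out$values <- scaled$values[, keep, drop = FALSE]
  out$compounds <- scaled$compounds[keep, , drop = FALSE]
  report <- as.data.frame(table(class = out$compounds$class),
                          stringsAsFactors = FALSE)
  names(report) <- c("class", "n")
  attr(out, "intersection_report") <- report
  attr(out, "mode") <- mode
  out
}

#' Impute remaining missing z-scores
#'
#' Undetected values surviving the merge are filled with the minimum observed
#' z-score of the compound within the sample's period -- a
#' "below-detection-limit" convention -- so that correlation and PLS inputs
#' are complete. `method = "zero"` fills with 0 (the period mean) instead.
#'
#' @param scaled a `scaled_matrix`.
#' @param method `"min"` or `"zero"`.
#' @return the `scaled_matrix` with complete `values`.
#' @export
impute_scaled <- function(scaled, method = c("min", "zero")) {
  method <- match.arg(method)
  v <- scaled$values
  for (p in unique(scaled$samples$period)) {
    rows <- scaled$samples$period == p
    sub <- v[rows, , drop = FALSE]
    for (j in which(colSums(is.na(sub)) > 0)) {
      fill <- if (method == "min") {
        if (all(is.na(sub[, j]))) 0 else min(sub[, j], na.rm = TRUE)
      } else 0
      sub[is.na(sub[, j]), j] <- fill
    }
    v[rows, ] <- sub
  }
  scaled$values <- v
  scaled
}
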