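#' Per-period PLS models and VIP scores
#'
#' Fits one NIPALS PLS model per measurement period, regressing a sensory
#' response on the period's autoscaled compounds plus texture liking (a
#' sensory covariate that enters the predictor block but is never reported as
#' a candidate compound). Compounds not detected in a period are excluded
#' from that period's model; sporadic within-period missing values are
#' filled by the period-minimum z-score convention.
#'
#' @param scaled a `scaled_matrix` from [autoscale_by_period()] (unmerged, so
#'   period-specific compounds participate in their own periods).
#' @param means a `sensory_means` table.
#' @param response `"sweetness"` or `"liking"`.
#' @param ncomp PLS components per model (default 3).
#' @param include_texture add texture liking to the predictor block?
#' @return list of class `period_vip`: per period a list with `model`, `vip`
#'   (named vector over that period's variables), `n`; plus `response`.
#' @export
fit_period_pls <- function(scaled, means, response = c("sweetness", "liking"),
                           ncomp = 3, include_texture = TRUE) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  response <- match.arg(response)
  wide <- sensory_means_wide(means)
  pres <- period_presence(scaled)
  periods <- colnames(pres)
  fits <- list()
  for (p in periods) {
    rows <- which(scaled$samples$period == p)
    ids <- scaled$samples$sample_id[rows]
    keep <- intersect(ids, wide$sample_id)
    rows <- rows[ids %in% keep]
    comp_in <- rownames(pres)[pres[, p]]
    Xp <- scaled$values[rows, comp_in, drop = FALSE]
    ## period-minimum imputation for sporadic missingness
    for (j in which(colSums(is.na(Xp)) > 0)) {
      Xp[is.na(Xp[, j]), j] <- min(Xp[, j], na.rm = TRUE)
    }
    wrow <- match(scaled$samples$sample_id[rows], wide$sample_id)
    if (include_texture && "texture_liking" %in% names(wide)) {
      tex <- as.numeric(scale(wide$texture_liking[wrow]))
      Xp <- cbind(Xp, texture_liking = tex)
    }
    y <- wide[[response]][wrow]
    model <- fit_pls_nipals(Xp, y, ncomp = ncomp)
    fits[[p]] <- list(model = model, vip = vip_scores(model), n = length(y))
  }
  structure(list(periods = fits, response = response, ncomp = ncomp),
            class = "period_vip")
}

#' Cross-period consensus selection by VIP
#'
#' A variable is selected when its VIP exceeds `threshold` in at least
#' `min_periods` of the periods in which it was modeled; periods where the
#' compound was not detected contribute no vote. Applied to the volatile
#' candidates only -- sugars, acids and the texture covariate are reported
#' but never counted as selected volatiles.
#'
#' @param vips either a `period_vip` object or a numeric matrix/data.frame of
#'   VIP scores (variables x periods, `NA` = not modeled in that period).
#' @param threshold VIP cutoff (default 1.0; the vote requires `VIP > threshold`).
#' @param min_periods minimum passing periods.
#' @param candidates optional character vector restricting the selectable set
#'   (e.g. volatile compound ids).
#' @return data.frame of class `consensus_table`: per variable the VIP per
#'   period, `n_pass`, `n_modeled`, `selected`.
#' @export
consensus_selection <- function(vips, threshold = 1.0, min_periods = 2,
                                candidates = NULL) {
  vmat <- if (inherits(vips, "period_vip")) {
    vars <- unique(unlist(lapply(vips$periods, function(f) names(f$vip))))
    sapply(vips$periods, function(f) f$vip[match(vars, names(f$vip))]) |>
      matrix(nrow = length(vars),
             dimnames = list(vars, names(vips$periods)))
  } else as.matrix(vips)
  if (min_periods > ncol(vmat)) {
    invalid_config(sprintf("min_periods = %d exceeds the number of periods (%d)",
                           min_periods, ncol(vmat)))
  }
  n_pass <- rowSums(vmat > threshold, na.rm = TRUE)
  n_modeled <- rowSums(!is.na(vmat))
  selected <- n_pass >= min_periods
  if (!is.null(candidates)) selected <- selected & rownames(vmat) %in% candidates
  out <- data.frame(variable = rownames(vmat), vmat, n_pass = n_pass,
                    n_modeled = n_modeled, selected = selected,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("consensus_table", class(out))
  out
}

#' Test a volatile's effect on a response controlling for total sugars
#'
#' Multiple linear regression `response ~ volatile + total_sugars`; the
#' two-sided t-test on the volatile slope asks whether the volatile carries
#' signal beyond the sugars. Volatiles nearly collinear with the sugars
#' (|r| > 0.999) are flagged non-identifiable.
#'
#' @param volatile autoscaled volatile abundances.
#' @param response sensory response values (sample means).
#' @param total_sugars per-sample total sugars (autoscaled or raw).
#' @return one-row data.frame: `beta`, `se`, `t`, `p`, `n`, `identifiable`.
#' @export
sugar_independence_test <- function(volatile, response, total_sugars) {
  ok <- stats::complete.cases(volatile, response, total_sugars)
  v <- volatile[ok]; y <- response[ok]; s <- total_sugars[ok]
  if (length(y) < 4) stop("need at least 4 complete observations")
  if (abs(stats::cor(v, s)) > 0.999) {
    return(data.frame(beta = NA_real_, se = NA_real_, t = NA_real_,
                      p = NA_real_, n = length(y), identifiable = FALSE))
  }
  fit <- stats::lm(y ~ v + s)
  co <- summary(fit)$coefficients["v", ]
  data.frame(beta = co[["Estimate"]], se = co[["Std. Error"]],
             t = co[["t value"]], p = co[["Pr(>|t|)"]], n = length(y),
             identifiable = TRUE)
}

#' Full selection of sweetness/liking-enhancing volatiles
#'
#' The package's headline procedure: per-period PLS (3 components), VIP
#' consensus over periods (VIP > 1 in at least 2 of 3 by default), then for
#' every consensus volatile a sugar-independence t-test on the merged data
#' with Bonferroni correction over the tested volatile family. The final
#' "independent enhancer" set is the consensus volatiles with adjusted
#' p < `alpha`.
#'
#' @param scaled a `scaled_matrix` (unmerged).
#' @param chem the originating [chem_matrix()] (for raw total sugars).
#' @param means a `sensory_means` table.
#' @param response `"sweetness"` or `"liking"`.
#' @param ncomp,threshold,min_periods,alpha procedure parameters.
#' @return data.frame of class `selection_report`: volatile id, per-period
#'   VIPs, consensus flag, `beta`, `t`, `p_adj`, `independent` flag; the
#'   fitted `period_vip` object rides along as attribute `"fits"`.
#' @export
select_enhancers <- function(scaled, chem, means,
                             response = c("sweetness", "liking"),
                             ncomp = 3, threshold = 1.0, min_periods = 2,
                             alpha = 0.05) {
  response <- match.arg(response)
  fits <- fit_period_pls(scaled, means, response, ncomp = ncomp)
  volatile_ids <- scaled$compounds$compound_id[
    !scaled$compounds$class %in% c("sugar", "acid")]
  cons <- consensus_selection(fits, threshold, min_periods,
                              candidates = volatile_ids)
  tested <- cons$variable[cons$selected]

  wide <- sensory_means_wide(means)
  sug_ids <- chem$compounds$compound_id[chem$compounds$class == "sugar"]
  totsug <- rowSums(chem$abundance[, sug_ids, drop = FALSE], na.rm = TRUE)
  z_sug <- numeric(length(totsug))
  for (p in unique(chem$samples$period)) {
    i <- chem$samples$period == p
    z_sug[i] <- (totsug[i] - mean(totsug[i])) / stats::sd(totsug[i])
  }
  names(z_sug) <- chem$samples$sample_id
  rows <- match(scaled$samples$sample_id, wide$sample_id)
  y <- wide[[response]][rows]

  tests <- lapply(tested, function(id) {
    v <- scaled$values[, id]
    sugar_independence_test(v, y, z_sug[scaled$samples$sample_id])
  })
  tt <- if (length(tests)) do.call(rbind, tests) else
    data.frame(beta = numeric(), se = numeric(), t = numeric(), p = numeric(),
               n = integer(), identifiable = logical())
  p_adj <- stats::p.adjust(tt$p, "bonferroni")

  out <- cons[cons$variable %in% volatile_ids, , drop = FALSE]
  m <- match(out$variable, tested)
  out$beta <- tt$beta[m]
  out$t <- tt$t[m]
  out$p_adj <- p_adj[m]
  out$independent <- !is.na(out$p_adj) & out$p_adj < alpha & out$selected
  attr(out, "fits") <- fits
  attr(out, "response") <- response
  attr(out, "alpha") <- alpha
  class(out) <- c("selection_report", "data.frame")
  out
}

#' @export
print.selection_report <- function(x, ...) {
  if (is.null(x$selected)) return(NextMethod())  # column-subset views
  cat(sprintf("<selection_report> response: %s; %d consensus volatiles, %d sugar-independent\n",
              attr(x, "response") %||% "?", sum(x$selected), sum(x$independent)))
  print.data.frame(utils::head(x[x$selected, ], 25), digits = 3)
  invisible(x)
}
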