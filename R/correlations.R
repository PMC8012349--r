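#' All-pairs Pearson correlations with multiplicity control
#'
#' Correlates every pair of columns of the combined analysis matrix (merged
#' autoscaled compounds plus sensory attribute means), reporting Pearson r,
#' the two-sided p-value from the t distribution, and both
#' Benjamini-Hochberg (FDR) and Bonferroni adjusted p-values over all tested
#' pairs. Pairs with fewer than `min_n` complete observations are excluded
#' and logged in the `excluded` attribute.
#'
#' @param x numeric samples x variables matrix (or data.frame).
#' @param min_n minimum complete observations per pair.
#' @return data.frame of class `correlation_table`: `var1`, `var2`, `r`, `n`,
#'   `p`, `p_bh`, `p_bonf`.
#' @export
pairwise_correlations <- function(x, min_n = 5) {
  x <- as.matrix(x)
  vars <- colnames(x)
  stopifnot(!is.null(vars))
  pairs <- utils::combn(length(vars), 2)
  n_obs <- crossprod(!is.na(x))
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  i <- pairs[1, ]; j <- pairs[2, ]
  rn <- r[cbind(i, j)]
  nn <- n_obs[cbind(i, j)]
  keep <- nn >= min_n & !is.na(rn)
  excluded <- data.frame(var1 = vars[i[!keep]], var2 = vars[j[!keep]],
                         n = nn[!keep], stringsAsFactors = FALSE)
  i <- i[keep]; j <- j[keep]; rn <- rn[keep]; nn <- nn[keep]
  tstat <- rn * sqrt((nn - 2) / pmax(1 - rn^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), nn - 2, lower.tail = FALSE)
  out <- data.frame(var1 = vars[i], var2 = vars[j], r = rn, n = nn, p = p,
                    p_bh = stats::p.adjust(p, "BH"),
                    p_bonf = stats::p.adjust(p, "bonferroni"),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  class(out) <- c("correlation_table", class(out))
  out
}

#' Count significant correlations
#'
#' @param corr a `correlation_table`.
#' @param alpha significance threshold (default 0.01).
#' @param adjust which p-value column to threshold: `"bh"`, `"bonferroni"`,
#'   or `"raw"`.
#' @return integer count.
#' @export
count_significant <- function(corr, alpha = 0.01, adjust = c("bh", "bonferroni", "raw")) {
  adjust <- match.arg(adjust)
  col <- switch(adjust, bh = "p_bh", bonferroni = "p_bonf", raw = "p")
  sum(corr[[col]] < alpha, na.rm = TRUE)
}

#' Combine merged chemistry and sensory means into one analysis matrix
#'
#' @param merged an imputed, merged `scaled_matrix`.
#' @param means a `sensory_means` table.
#' @return numeric matrix (samples x variables) plus a `"classes"` attribute
#'   labelling each column (chemical class or `"sensory"`).
#' @export
analysis_matrix <- function(merged, means) {
  wide <- sensory_means_wide(means)
  common <- intersect(merged$samples$sample_id, wide$sample_id)
  if (!length(common)) stop("no overlapping samples between chemistry and sensory means")
  chem_v <- merged$values[match(common, merged$samples$sample_id), , drop = FALSE]
  sens_v <- as.matrix(wide[match(common, wide$sample_id),
                           setdiff(names(wide), "sample_id"), drop = FALSE])
  out <- cbind(chem_v, sens_v)
  rownames(out) <- common
  attr(out, "classes") <- c(merged$compounds$class,
                            rep("sensory", ncol(sens_v)))
  out
}
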