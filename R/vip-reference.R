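#' Published reference VIP table for strawberry flavor compounds
#'
#' Per-period VIP scores for sweetness and liking models, with
#' Bonferroni-adjusted sugar-independence p-values, for 26 compounds (3
#' sugars and 23 volatiles) as printed in the summary table of a seven-year
#' strawberry sensory-chemical study. Periods 1-3 correspond to the
#' 2011-2012, 2013-2015 and 2016-2017 measurement periods. Missing VIPs mean
#' the compound was not retained for that response or not detected in that
#' period; sugars carry no independence p-value. It serves as a desk-scale
#' worked example for [consensus_selection()] and the independence
#' thresholding.
#'
#' @return data.frame with columns `compound`, `class`, `vip_sweetness_1..3`,
#'   `p_adj_sweetness`, `vip_liking_1..3`, `p_adj_liking`.
#' @export
#' @examples
#' ref <- vip_reference()
#' counts <- vip_reference_counts(ref)
#' counts$sweetness_selected  # 20 volatiles
vip_reference <- function() {
  path <- system.file("extdata", "reference_vip_table.csv",
                      package = "flavoromics", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Selection counts from the reference VIP table
#'
#' Applies the consensus rule (VIP > `threshold` in at least `min_periods`
#' periods) to the sweetness and liking VIP columns of the reference table,
#' restricted to volatiles (sugars are reported in the table but are not
#' candidate enhancers), and thresholds the adjusted p-values at `alpha`.
#'
#' @param ref the [vip_reference()] table (or a table with its layout).
#' @param threshold,min_periods consensus parameters.
#' @param alpha level for the sugar-independence flag.
#' @return list with `sweetness_selected`, `liking_selected`,
#'   `both_selected`, `sweetness_independent`, `liking_independent`, and the
#'   selected id vectors.
#' @export
vip_reference_counts <- function(ref = vip_reference(), threshold = 1.0,
                                 min_periods = 2, alpha = 0.05) {
  volatiles <- ref$compound[ref$class != "sugar"]
  sel_for <- function(resp) {
    v <- as.matrix(ref[paste0("vip_", resp, "_", 1:3)])
    rownames(v) <- ref$compound
    cons <- consensus_selection(v, threshold, min_periods,
                                candidates = volatiles)
    sel <- cons$variable[cons$selected]
    p <- ref[[paste0("p_adj_", resp)]]
    indep <- ref$compound[!is.na(p) & p < alpha & ref$compound %in% sel]
    list(selected = sel, independent = indep)
  }
  sw <- sel_for("sweetness"); lk <- sel_for("liking")
  list(sweetness_selected = length(sw$selected),
       liking_selected = length(lk$selected),
       both_selected = length(intersect(sw$selected, lk$selected)),
       sweetness_independent = length(sw$independent),
       liking_independent = length(lk$independent),
       sweetness_ids = sw$selected, liking_ids = lk$selected,
       sweetness_independent_ids = sw$independent)
}
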