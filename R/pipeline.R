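#' Run the full sensory-chemical analysis pipeline
#'
#' Orchestrates the stages end to end: ingest (or simulate) the data, fit
#' panelist-adjusted sensory means, autoscale and merge the chemical periods,
#' compute the correlation table, network and supported dendrogram, run the
#' VIP consensus selection for sweetness and liking, and optionally the
#' predictive benchmark and the single-marker association scan. Every
#' intermediate is written to `outdir` as plain text (CSV / GraphML / Newick
#' / JSON) and a run report with stage counts and the parameter echo is
#' returned and written as JSON.
#'
#' @param config either a YAML file path or a list with elements:
#'   `simulate` (arguments for [sim_config()]) or `inputs` (paths `sensory`,
#'   `chemicals`, `compound_info`, optionally `genotypes`, `marker_map`);
#'   `outdir`; `seed`; optional `stages` (logical toggles `correlations`,
#'   `network`, `clustering`, `selection`, `benchmark`, `genetics`);
#'   optional parameter blocks `selection` (`ncomp`, `threshold`,
#'   `min_periods`, `alpha`), `network` (`alpha`, `adjust`), `clustering`
#'   (`n_boot`, `scale_factors`), `benchmark` (passed to
#'   [benchmark_config()]), `means_method`.
#' @return a `run_report` list (invisibly writes artifacts).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  t0 <- Sys.time()
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  stages <- utils::modifyList(
    list(correlations = TRUE, network = TRUE, clustering = TRUE,
         selection = TRUE, benchmark = FALSE, genetics = NULL),
    config$stages %||% list())
  stage <- "setup"
  report <- list(seed = seed, parameters = config[setdiff(names(config), "outdir")],
                 version = as.character(utils::packageVersion("flavoromics")))
  fail <- function(e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    ## ---- ingest / simulate --------------------------------------------
    stage <- "ingest"
    geno <- NULL
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% seed
      cfg <- do.call(sim_config, sim_args)
      truth <- simulate_truth(cfg)
      ratings <- generate_sensory_panel(cfg, truth)
      chem <- generate_chemical_matrix(cfg, truth)
      if (isTRUE(stages$genetics)) geno <- generate_genotypes(cfg, truth)
      write_truth(truth, file.path(outdir, "truth.json"))
      write_sensory(ratings, file.path(outdir, "ratings.csv"))
      write_chemicals(chem, file.path(outdir, "chemicals.csv"),
                      file.path(outdir, "compounds.csv"))
    } else {
      inp <- config$inputs %||% stop("config needs `simulate` or `inputs`")
      ratings <- read_sensory(inp$sensory)
      chem <- read_chemicals(inp$chemicals, inp$compound_info)
      if (!is.null(inp$genotypes)) geno <- read_genotypes(inp$genotypes, inp$marker_map)
      truth <- NULL
    }

    ## ---- sensory means -------------------------------------------------
    stage <- "sensory_means"
    means <- fit_panelist_adjusted_means(ratings,
                                         method = config$means_method %||% "mixed")
    utils::write.csv(as.data.frame(means),
                     file.path(outdir, "sensory_means.csv"), row.names = FALSE)
    ac <- attribute_correlations(means)
    utils::write.csv(ac, file.path(outdir, "attribute_correlations.csv"),
                     row.names = FALSE)

    ## ---- harmonize ------------------------------------------------------
    stage <- "harmonize"
    scaled <- autoscale_by_period(chem)
    merged <- impute_scaled(merge_periods(scaled, "common"))
    amat <- analysis_matrix(merged, means)
    report$counts <- list(samples = nrow(chem$abundance),
                          compounds = ncol(chem$abundance),
                          common_compounds = ncol(merged$values),
                          common_volatiles = sum(!merged$compounds$class %in%
                                                   c("sugar", "acid")))

    ## ---- correlations / network / clustering ---------------------------
    corr <- NULL
    if (isTRUE(stages$correlations)) {
      stage <- "correlations"
      corr <- pairwise_correlations(amat)
      utils::write.csv(corr, file.path(outdir, "correlation_table.csv"),
                       row.names = FALSE)
      report$counts$significant_correlations <-
        count_significant(corr, alpha = 0.01, adjust = "bh")
    }
    if (isTRUE(stages$network) && !is.null(corr)) {
      stage <- "network"
      np <- utils::modifyList(list(alpha = 0.05, adjust = "bonferroni"),
                              config$network %||% list())
      classes <- stats::setNames(attr(amat, "classes"), colnames(amat))
      net <- build_network(corr, np$alpha, np$adjust, classes)
      write_network(net, file.path(outdir, "network.graphml"),
                    file.path(outdir, "network_edges.csv"))
      report$counts$network_nodes <- nrow(net$nodes)
      report$counts$network_edges <- nrow(net$edges)
    }
    if (isTRUE(stages$clustering)) {
      stage <- "clustering"
      cp <- utils::modifyList(list(n_boot = 500,
                                   scale_factors = seq(0.5, 1.4, by = 0.1)),
                              config$clustering %||% list())
      boot <- bootstrap_cluster(amat, n_boot = cp$n_boot,
                                scale_factors = cp$scale_factors,
                                seed = substream_seed(seed, "clustering"))
      write_dendrogram_newick(boot, file.path(outdir, "dendrogram.nwk"))
      utils::write.csv(boot$support, file.path(outdir, "cluster_support.csv"),
                       row.names = FALSE)
    }

    ## ---- selection ------------------------------------------------------
    selections <- list()
    if (isTRUE(stages$selection)) {
      stage <- "selection"
      sp <- utils::modifyList(list(ncomp = 3, threshold = 1.0,
                                   min_periods = 2, alpha = 0.05),
                              config$selection %||% list())
      for (resp in c("sweetness", "liking")) {
        sel <- select_enhancers(scaled, chem, means, resp, sp$ncomp,
                                sp$threshold, sp$min_periods, sp$alpha)
        utils::write.csv(as.data.frame(sel),
                         file.path(outdir, sprintf("selection_%s.csv", resp)),
                         row.names = FALSE)
        selections[[resp]] <- sel
        report$counts[[paste0("selected_", resp)]] <- sum(sel$selected)
        report$counts[[paste0("independent_", resp)]] <- sum(sel$independent)
      }
    }

    ## ---- benchmark ------------------------------------------------------
    if (isTRUE(stages$benchmark)) {
      stage <- "benchmark"
      bp <- config$benchmark %||% list()
      bp$seed <- bp$seed %||% substream_seed(seed, "benchmark")
      bcfg <- do.call(benchmark_config, bp)
      wide <- sensory_means_wide(means)
      rows <- match(merged$samples$sample_id, wide$sample_id)
      y <- wide$sweetness[rows]
      bench <- nested_cv_evaluate(merged$values, y, bcfg)
      base <- baseline_sugars_acids(merged$values, y, bcfg)
      bench$summary <- rbind(base$summary, bench$summary)
      utils::write.csv(bench$summary, file.path(outdir, "benchmark.csv"),
                       row.names = FALSE)
      report$benchmark <- bench$summary
    }

    ## ---- genetics -------------------------------------------------------
    if (!is.null(geno)) {
      stage <- "genetics"
      bc <- boxcox_transform(geno$phenotype)
      assoc <- single_marker_scan(geno, bc$transformed)
      utils::write.csv(assoc, file.path(outdir, "association.csv"),
                       row.names = FALSE)
      report$counts$significant_markers <- sum(assoc$p_bh < 0.05)
      report$boxcox_lambda <- bc$lambda
    }

    stage <- "report"
    report$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    report$selections <- lapply(selections, function(s)
      s$variable[s$selected])
    jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    class(report) <- "run_report"
    report
  }, error = fail)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  utils::str(x$counts)
  invisible(x)
}

#' Simulate a study and score recovery of the planted structure
#'
#' Generates one synthetic study, runs the selection procedure (and, when
#' genotypes are enabled, the single-marker scan on the raw phenotype) and
#' scores the result against the truth registry: sensitivity of the
#' sugar-independent enhancer set, count of false-positive volatiles, and the
#' error of the estimated QTL variance fraction. Sample means use the fast
#' per-sample average (with ~100 raters per sample the panelist adjustment
#' changes means by a fraction of a rating unit).
#'
#' @param config a [sim_config()].
#' @param genotypes also score QTL variance recovery?
#' @param response response scored for enhancer recovery.
#' @param means_method passed to [fit_panelist_adjusted_means()].
#' @return list of class `recovery_summary`: `sensitivity`, `n_recovered`,
#'   `false_positives`, `selected_ids`, `truth_ids`, and when scored,
#'   `qtl_r2`, `qtl_error`.
#' @export
simulate_and_recover <- function(config, genotypes = TRUE,
                                 response = "sweetness",
                                 means_method = "raw") {
  stopifnot(inherits(config, "sim_config"))
  truth <- simulate_truth(config)
  ratings <- generate_sensory_panel(config, truth)
  chem <- generate_chemical_matrix(config, truth)
  means <- fit_panelist_adjusted_means(ratings, method = means_method)
  scaled <- autoscale_by_period(chem)
  sel <- select_enhancers(scaled, chem, means, response)
  hit <- sel$variable[sel$independent]
  out <- list(sensitivity = if (length(truth$enhancer_ids))
    length(intersect(hit, truth$enhancer_ids)) / length(truth$enhancer_ids) else NA,
    n_recovered = length(intersect(hit, truth$enhancer_ids)),
    false_positives = length(setdiff(hit, truth$enhancer_ids)),
    n_consensus = sum(sel$selected),
    selected_ids = hit, truth_ids = truth$enhancer_ids)
  if (genotypes) {
    geno <- generate_genotypes(config, truth)
    scan <- single_marker_scan(geno)
    out$qtl_r2 <- scan$r2[scan$marker_id == geno$causal_marker]
    out$qtl_error <- out$qtl_r2 - config$qtl_variance
  }
  class(out) <- "recovery_summary"
  out
}

#' Replicate the recovery study over many seeds
#'
#' @param config a [sim_config()]; its seed is replaced per replicate.
#' @param n_reps number of replicates.
#' @param seed master seed for the replicate substreams.
#' @param ... passed to [simulate_and_recover()].
#' @return data.frame with one row per replicate.
#' @export
recovery_study <- function(config, n_reps = 50, seed = 1, ...) {
  rows <- lapply(seq_len(n_reps), function(k) {
    cfg <- config
    cfg$seed <- substream_seed(seed, paste0("recovery_", k))
    r <- simulate_and_recover(cfg, ...)
    data.frame(replicate = k, sensitivity = r$sensitivity,
               n_recovered = r$n_recovered,
               false_positives = r$false_positives,
               n_consensus = r$n_consensus,
               qtl_r2 = r$qtl_r2 %||% NA_real_)
  })
  do.call(rbind, rows)
}
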