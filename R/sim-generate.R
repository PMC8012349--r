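#' Generate consumer-panel ratings for a synthetic study
#'
#' Samples are served in sessions of `samples_per_session` (never crossing a
#' measurement period); each session recruits its own set of
#' `n_panelists_per_session` consumers, who rate every sample of their session
#' on all five attributes. A rating is the sample's true mean (from the truth
#' registry) plus the panelist's random intercept plus rating noise, clipped
#' to the attribute's scale. The realized clipping fraction is attached as
#' attribute `"clip_fraction"` so users can keep it negligible.
#'
#' @param config a [sim_config()].
#' @param truth the matching [simulate_truth()] registry.
#' @return a [panel_ratings()] data.frame.
#' @export
generate_sensory_panel <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(substream_seed(config$seed, "panel"))

  ## sessions: chunk samples within period into balanced groups, so that
  ## period remainders never produce a session below the 3-sample floor
  sess <- integer(config$n_samples)
  s0 <- 0L
  for (p in config$period_labels) {
    idx <- which(truth$samples$period == p)
    k <- max(1L, ceiling(length(idx) / config$samples_per_session))
    base <- length(idx) %/% k
    extra <- length(idx) - k * base
    sizes <- c(rep(base + 1L, extra), rep(base, k - extra))
    sess[idx] <- s0 + rep(seq_len(k), times = sizes)
    s0 <- s0 + k
  }
  n_sessions <- max(sess)

  rows <- vector("list", n_sessions)
  n_clip <- 0L; n_tot <- 0L
  for (s in seq_len(n_sessions)) {
    samples <- truth$samples$sample_id[sess == s]
    panelists <- sprintf("S%03dP%03d", s, seq_len(config$n_panelists_per_session))
    offset <- stats::rnorm(config$n_panelists_per_session, 0, config$panelist_sd)
    grid <- expand.grid(panelist = seq_along(panelists), sample_id = samples,
                        attribute = ALL_ATTRIBUTES, stringsAsFactors = FALSE)
    mu <- truth$sample_means[cbind(grid$sample_id, grid$attribute)]
    raw <- mu + offset[grid$panelist] +
      stats::rnorm(nrow(grid), 0, config$rating_noise_sd)
    b <- attribute_bounds(grid$attribute)
    score <- clip(raw, b[, "lo"], b[, "hi"])
    n_clip <- n_clip + sum(score != raw)
    n_tot <- n_tot + length(raw)
    rows[[s]] <- data.frame(panelist_id = panelists[grid$panelist],
                            session_id = sprintf("sess%03d", s),
                            sample_id = grid$sample_id,
                            attribute = grid$attribute,
                            score = score,
                            stringsAsFactors = FALSE)
  }
  out <- panel_ratings(do.call(rbind, rows))
  attr(out, "clip_fraction") <- n_clip / n_tot
  out
}

#' Generate the multi-period chemical matrix
#'
#' Packages the truth registry's abundances (log-normal, spanning well over a
#' 70-fold range for the most variable volatiles) into a [chem_matrix()],
#' applying the detection mask: core volatiles are detected everywhere, the
#' remaining volatiles are absent from one or more whole periods and sporadically
#' undetected within the periods where they occur. Undetected cells are `NA`,
#' never zero.
#'
#' @inheritParams generate_sensory_panel
#' @return a [chem_matrix()].
#' @export
generate_chemical_matrix <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  ab <- truth$abundance
  ab[!truth$detected] <- NA_real_
  chem_matrix(ab, truth$samples, truth$compounds, truth$detected)
}

#' Generate a genotype matrix and an ester-like phenotype
#'
#' Markers are drawn under Hardy-Weinberg equilibrium (dosage 0/1/2). The
#' phenotype is an additive effect of the single causal marker plus
#' right-skewed log-normal noise; the additive effect is scaled analytically
#' so that the causal marker explains `qtl_variance` of the phenotypic
#' variance at the configured allele frequency: for allele frequency `p` and
#' additive effect `a`, the genetic variance is `2 p (1 - p) a^2`.
#'
#' @inheritParams generate_sensory_panel
#' @return a list of class `genotype_matrix` with elements `G` (samples x
#'   markers dosage matrix), `map` (marker, linkage_group, position),
#'   `phenotype`, `causal_marker`, `sample_ids`.
#' @export
generate_genotypes <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  assert_config(config$allele_freq > 0 && config$allele_freq < 1,
                "`allele_freq` must lie strictly within (0, 1)")
  set.seed(substream_seed(config$seed, "genotypes"))
  n <- config$n_geno_samples
  m <- config$n_markers
  marker_ids <- sprintf("M%03d", seq_len(m))
  freqs <- stats::runif(m, 0.1, 0.9)
  causal <- 1L
  freqs[causal] <- config$allele_freq

  G <- sapply(freqs, function(p) stats::rbinom(n, 2L, p))
  dimnames(G) <- list(sprintf("G%04d", seq_len(n)), marker_ids)

  ## log-normal noise, variance known in closed form
  mu_ln <- 3; sd_ln <- 0.5
  var_noise <- (exp(sd_ln^2) - 1) * exp(2 * mu_ln + sd_ln^2)
  q <- config$qtl_variance
  p <- config$allele_freq
  a <- if (q > 0) sqrt(q / (1 - q) * var_noise / (2 * p * (1 - p))) else 0
  pheno <- a * G[, causal] + stats::rlnorm(n, mu_ln, sd_ln)

  map <- data.frame(marker_id = marker_ids,
                    linkage_group = sprintf("LG%d", ((seq_len(m) - 1L) %% 7L) + 1L),
                    position = round(stats::runif(m, 0, 120), 2),
                    stringsAsFactors = FALSE)
  map <- map[order(map$linkage_group, map$position), ]

  structure(list(G = G, map = map, phenotype = pheno,
                 causal_marker = marker_ids[causal],
                 additive_effect = a,
                 sample_ids = rownames(G)),
            class = "genotype_matrix")
}

#' Simulate a complete study
#'
#' Convenience wrapper: truth registry, panel ratings, chemical matrix and
#' (optionally) genotypes from one configuration.
#'
#' @param config a [sim_config()].
#' @param genotypes generate the genotype/phenotype set as well?
#' @return a list with `truth`, `ratings`, `chem`, and optionally `geno`.
#' @export
simulate_study <- function(config, genotypes = FALSE) {
  truth <- simulate_truth(config)
  out <- list(truth = truth,
              ratings = generate_sensory_panel(config, truth),
              chem = generate_chemical_matrix(config, truth))
  if (genotypes) out$geno <- generate_genotypes(config, truth)
  out
}
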