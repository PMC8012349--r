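#' Configuration for the synthetic flavor-study generator
#'
#' Builds and validates the configuration that fully determines a synthetic
#' study: a consumer panel rating samples on bounded hedonic/intensity scales,
#' a multi-period chemical matrix of volatiles, sugars and acids, and a
#' genotype/phenotype set with one planted QTL. All randomness downstream is a
#' deterministic function of `seed` (expanded into named substreams, see
#' [substream_seed()]).
#'
#' Defaults emulate a seven-year fresh-strawberry consumer study: 148 samples
#' split over three measurement periods (54/49/45), sessions of 3-5 samples
#' rated by about 100 consumers each, 113 volatiles of which 59 are detected
#' in every period, sugars explaining 40% of sample-level sweetness variance
#' (30% of liking), and three planted volatile enhancers each contributing
#' 10% of sweetness variance (8% of liking) independently of sugars.
#'
#' @param n_samples number of fruit samples.
#' @param n_panelists_per_session consumers recruited per tasting session.
#' @param samples_per_session samples served per session (3-5).
#' @param panelist_sd SD of the panelist random intercept, rating units.
#' @param rating_noise_sd SD of the residual rating noise, rating units.
#' @param n_volatiles number of volatile compounds.
#' @param n_core_volatiles volatiles detected in every period and sample.
#' @param n_periods number of technical measurement periods.
#' @param period_labels labels for the periods; free strings.
#' @param period_weights relative sizes of the periods.
#' @param batch_shift_sd SD of per-compound period offsets, log-abundance units.
#' @param volatile_sd_range range of per-compound idiosyncratic log-SD.
#' @param chem_noise_sd measurement noise SD (log scale) for a single replicate.
#' @param n_replicates technical replicates averaged per chemical value.
#' @param detect_prob per-sample detection probability for non-core volatiles
#'   within the periods where they occur.
#' @param n_enhancers number of planted sweetness/liking-enhancing volatiles.
#' @param enhancer_effect fraction of sweetness variance per enhancer.
#' @param liking_enhancer_effect fraction of liking variance per enhancer.
#' @param sugar_effect fraction of sweetness variance from total sugars.
#' @param liking_sugar_effect fraction of liking variance from total sugars.
#' @param texture_effect fraction of liking variance from texture liking.
#' @param temperature_effect fraction of sweetness variance from the soil
#'   temperature trend (enters with a negative slope); 0 disables the trend.
#' @param n_latent_pathways latent metabolic pathway factors generating
#'   correlated ester/aldehyde clusters.
#' @param sugar_cor target glucose-fructose correlation.
#' @param n_markers markers in the genotype matrix.
#' @param n_geno_samples individuals in the genotype/phenotype set.
#' @param qtl_variance fraction of phenotypic variance explained by the
#'   planted marker, in `[0, 1)`.
#' @param allele_freq allele frequency of the causal marker, in `(0, 1)`.
#' @param seed integer master seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 24, n_volatiles = 12, n_core_volatiles = 8,
#'                   n_panelists_per_session = 10, seed = 1)
sim_config <- function(n_samples = 148,
                       n_panelists_per_session = 100,
                       samples_per_session = 4,
                       panelist_sd = 10,
                       rating_noise_sd = 15,
                       n_volatiles = 113,
                       n_core_volatiles = 59,
                       n_periods = 3,
                       period_labels = NULL,
                       period_weights = NULL,
                       batch_shift_sd = 0.5,
                       volatile_sd_range = c(0.4, 1.2),
                       chem_noise_sd = 0.15,
                       n_replicates = 3,
                       detect_prob = 0.9,
                       n_enhancers = 3,
                       enhancer_effect = 0.10,
                       liking_enhancer_effect = 0.08,
                       sugar_effect = 0.40,
                       liking_sugar_effect = 0.30,
                       texture_effect = 0.20,
                       temperature_effect = 0.05,
                       n_latent_pathways = 6,
                       sugar_cor = 0.9,
                       n_markers = 100,
                       n_geno_samples = 300,
                       qtl_variance = 0.15,
                       allele_freq = 0.5,
                       seed = 1) {
  cfg <- as.list(environment())

  counts <- c("n_samples", "n_panelists_per_session", "samples_per_session",
              "n_volatiles", "n_core_volatiles", "n_periods", "n_replicates",
              "n_markers", "n_geno_samples")
  for (nm in counts) {
    assert_config(is.numeric(cfg[[nm]]) && length(cfg[[nm]]) == 1L && cfg[[nm]] >= 1,
                  sprintf("`%s` must be a count >= 1", nm))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  assert_config(samples_per_session >= 3 && samples_per_session <= 5,
                "`samples_per_session` must be between 3 and 5")
  assert_config(n_enhancers >= 0, "`n_enhancers` must be >= 0")
  cfg$n_enhancers <- as.integer(n_enhancers)
  assert_config(n_core_volatiles <= n_volatiles,
                "`n_core_volatiles` cannot exceed `n_volatiles`")
  assert_config(n_latent_pathways >= 0 && n_latent_pathways <= n_volatiles,
                "`n_latent_pathways` must lie in [0, n_volatiles]")
  assert_config(panelist_sd >= 0 && rating_noise_sd >= 0,
                "rating-scale SDs must be non-negative")

  fracs <- c("enhancer_effect", "liking_enhancer_effect", "sugar_effect",
             "liking_sugar_effect", "texture_effect", "temperature_effect",
             "qtl_variance")
  for (nm in fracs) {
    assert_config(cfg[[nm]] >= 0 && cfg[[nm]] < 1,
                  sprintf("`%s` must be a variance fraction in [0, 1)", nm))
  }
  sw_total <- sugar_effect + n_enhancers * enhancer_effect + temperature_effect
  assert_config(sw_total < 1,
                "sweetness variance fractions (sugars + enhancers + temperature) must sum to < 1")
  lk_total <- liking_sugar_effect + n_enhancers * liking_enhancer_effect +
    texture_effect + temperature_effect
  assert_config(lk_total < 1, "liking variance fractions must sum to < 1")
  assert_config(allele_freq > 0 && allele_freq < 1,
                "`allele_freq` must lie strictly within (0, 1)")
  assert_config(sugar_cor > 0 && sugar_cor < 1, "`sugar_cor` must lie in (0, 1)")

  if (is.null(period_labels)) {
    period_labels <- if (n_periods == 3) {
      c("2011-2012", "2013-2015", "2016-2017")
    } else {
      sprintf("period_%d", seq_len(n_periods))
    }
  }
  assert_config(length(period_labels) == n_periods,
                "`period_labels` must have length `n_periods`")
  if (is.null(period_weights)) {
    period_weights <- if (n_periods == 3) c(54, 49, 45) else rep(1, n_periods)
  }
  assert_config(length(period_weights) == n_periods && all(period_weights > 0),
                "`period_weights` must be positive and match `n_periods`")
  cfg$period_labels <- as.character(period_labels)
  cfg$period_weights <- period_weights / sum(period_weights)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d samples, %d periods (%s)\n", x$n_samples, x$n_periods,
              paste(x$period_labels, collapse = ", ")))
  cat(sprintf("  %d volatiles (%d core), %d enhancers at %.2f sweetness variance each\n",
              x$n_volatiles, x$n_core_volatiles, x$n_enhancers, x$enhancer_effect))
  cat(sprintf("  sugars: %.2f of sweetness variance; seed %d\n",
              x$sugar_effect, x$seed))
  invisible(x)
}
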