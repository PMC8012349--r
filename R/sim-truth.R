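#' Generate the ground-truth registry of a synthetic flavor study
#'
#' Draws every latent quantity of the simulated study -- period assignment,
#' latent pathway factors, compound parameters, log abundances, the detection
#' mask, planted enhancer identities and slopes, sugar slopes, the temperature
#' covariate and the noise-free per-sample sensory means -- and records them
#' in a registry used both by the data generators and by parameter-recovery
#' tests.
#'
#' Planted effects act on the per-period autoscaled (z-scored) abundances, so
#' effect sizes are invariant to period batch offsets. The sample-level
#' residual of each sensory attribute is orthogonalized in-sample against the
#' registered drivers; jointly regressing the noise-free means on those
#' drivers therefore returns the registered slopes exactly, which is what the
#' recovery tests check. Enhancers are drawn from volatiles outside the latent
#' pathway clusters so that "planted" remains identifiable: a pathway partner
#' of an enhancer would carry a genuinely nonzero sugar-independent effect.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_truth`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "truth"))
  n <- config$n_samples
  nv <- config$n_volatiles

  ## ---- samples, periods, temperature covariate -------------------------
  sizes <- diff(round(cumsum(c(0, config$period_weights)) * n))
  sizes[config$n_periods] <- n - sum(sizes[-config$n_periods])
  period <- rep(config$period_labels, times = sizes)
  sample_id <- sprintf("S%03d", seq_len(n))
  temp_c <- round(stats::runif(n, 15, 25), 1)  # five-day mean soil temp, deg C

  ## ---- compound table --------------------------------------------------
  sugars <- c("glucose", "fructose", "sucrose")
  acids <- c("malic_acid", "citric_acid")
  vol_ids <- sprintf("V%03d", seq_len(nv))
  classes <- sample(c("ester", "aldehyde", "ketone", "alcohol", "lactone",
                      "terpene", "furan", "other"),
                    nv, replace = TRUE,
                    prob = c(0.45, 0.12, 0.10, 0.08, 0.05, 0.06, 0.04, 0.10))
  compounds <- data.frame(
    compound_id = c(sugars, acids, vol_ids),
    class = c(rep("sugar", 3), rep("acid", 2), classes),
    stringsAsFactors = FALSE
  )

  ## ---- latent pathway structure ---------------------------------------
  pathway <- rep(NA_integer_, nv)
  loading <- rep(0, nv)
  if (config$n_latent_pathways > 0) {
    pool <- which(classes %in% c("ester", "aldehyde", "ketone"))
    for (l in seq_len(config$n_latent_pathways)) {
      avail <- setdiff(pool, which(!is.na(pathway)))
      ## clustered volatiles live inside the always-detected core, so cluster
      ## growth is capped by the remaining core budget
      budget <- config$n_core_volatiles - config$n_enhancers -
        sum(!is.na(pathway))
      if (length(avail) < 2 || budget < 2) break
      size <- min(length(avail), budget, sample(4:8, 1))
      members <- sample(avail, size)
      pathway[members] <- l
      loading[members] <- stats::runif(size, 0.7, 1.1)
    }
  }

  ## ---- enhancers: unclustered core volatiles ---------------------------
  unclustered <- which(is.na(pathway))
  assert_config(length(unclustered) >= config$n_enhancers,
                "not enough unclustered volatiles to plant enhancers")
  enhancer_idx <- sort(sample(unclustered, config$n_enhancers))
  enhancer_ids <- vol_ids[enhancer_idx]

  ## core volatiles: always detected; must contain pathway members and
  ## enhancers so that the common-compound intersection keeps the structure.
  required <- union(which(!is.na(pathway)), enhancer_idx)
  assert_config(length(required) <= config$n_core_volatiles,
                "`n_core_volatiles` too small to hold pathway members and enhancers")
  core_idx <- sort(c(required,
                     sample(setdiff(seq_len(nv), required),
                            config$n_core_volatiles - length(required))))

  ## ---- log abundances --------------------------------------------------
  mu <- stats::rnorm(nv, log(300), 1.2)
  idio_sd <- stats::runif(nv, config$volatile_sd_range[1], config$volatile_sd_range[2])
  delta <- matrix(stats::rnorm(nv * config$n_periods, 0, config$batch_shift_sd),
                  nrow = nv, dimnames = list(vol_ids, config$period_labels))
  fac <- matrix(stats::rnorm(n * max(1L, config$n_latent_pathways)), nrow = n)
  meas_sd <- config$chem_noise_sd / sqrt(config$n_replicates)
  L <- matrix(0, n, nv, dimnames = list(sample_id, vol_ids))
  per_idx <- match(period, config$period_labels)
  for (j in seq_len(nv)) {
    f <- if (!is.na(pathway[j])) loading[j] * fac[, pathway[j]] else 0
    L[, j] <- mu[j] + f + delta[j, per_idx] +
      stats::rnorm(n, 0, idio_sd[j]) + stats::rnorm(n, 0, meas_sd)
  }

  ## sugars (mg scale): glucose-fructose strongly correlated via a shared
  ## latent sugar factor; sucrose moderately so. Acids independent-ish.
  u <- stats::rnorm(n)
  a_gf <- sqrt(config$sugar_cor)
  z_glu <- a_gf * u + sqrt(1 - a_gf^2) * stats::rnorm(n)
  z_fru <- a_gf * u + sqrt(1 - a_gf^2) * stats::rnorm(n)
  z_suc <- sqrt(0.4) * u + sqrt(0.6) * stats::rnorm(n)
  sugar_log <- cbind(glucose = log(2000) + 0.35 * z_glu,
                     fructose = log(2200) + 0.35 * z_fru,
                     sucrose = log(1200) + 0.55 * z_suc)
  sugar_delta <- matrix(stats::rnorm(3 * config$n_periods, 0, config$batch_shift_sd / 2),
                        nrow = 3, dimnames = list(sugars, config$period_labels))
  for (j in 1:3) sugar_log[, j] <- sugar_log[, j] + sugar_delta[j, per_idx]
  acid_log <- cbind(malic_acid = log(250) + 0.30 * stats::rnorm(n),
                    citric_acid = log(700) + 0.30 * stats::rnorm(n))

  abundance <- cbind(exp(sugar_log), exp(acid_log), exp(L))
  colnames(abundance) <- compounds$compound_id

  ## ---- detection mask --------------------------------------------------
  detected <- matrix(TRUE, n, ncol(abundance),
                     dimnames = dimnames(abundance))
  noncore <- setdiff(seq_len(nv), core_idx)
  for (j in noncore) {
    n_absent <- sample(seq_len(config$n_periods - 1L), 1)
    absent <- sample(config$period_labels, n_absent)
    col <- 5L + j
    detected[period %in% absent, col] <- FALSE
    present <- which(!(period %in% absent))
    miss <- present[stats::runif(length(present)) > config$detect_prob]
    ## keep at least 3 detected values per present period for scaling
    for (p in setdiff(config$period_labels, absent)) {
      pp <- intersect(present, which(period == p))
      drop <- intersect(miss, pp)
      if (length(pp) - length(drop) < 3) drop <- utils::head(drop, length(pp) - 3)
      detected[drop, col] <- FALSE
    }
  }

  ## ---- drivers on the autoscaled scale ---------------------------------
  z_by_period <- function(x) {
    out <- numeric(n)
    for (p in config$period_labels) {
      i <- period == p
      out[i] <- (x[i] - mean(x[i])) / stats::sd(x[i])
    }
    out
  }
  total_sugars <- rowSums(abundance[, sugars])
  z_sug <- z_by_period(total_sugars)
  z_enh <- sapply(enhancer_ids, function(id) z_by_period(abundance[, id]))
  if (config$n_enhancers == 0) z_enh <- matrix(0, n, 0)
  z_temp <- as.numeric(scale(temp_c))
  z_acid <- z_by_period(rowSums(abundance[, acids]))
  z_tex <- stats::rnorm(n)
  z_tex <- as.numeric(scale(z_tex))

  orth_resid <- function(drivers) {
    e <- stats::rnorm(n)
    if (ncol(drivers) > 0) e <- stats::lm.fit(cbind(1, drivers), e)$residuals
    as.numeric(scale(e))
  }

  ## ---- noise-free sample means -----------------------------------------
  sw_sd <- 12; lk_sd <- 15
  d_sw <- cbind(sugars = z_sug, z_enh, temp = z_temp)
  colnames(d_sw) <- c("total_sugars", enhancer_ids, "temperature")
  b_sw <- c(sqrt(config$sugar_effect),
            rep(sqrt(config$enhancer_effect), config$n_enhancers),
            -sqrt(config$temperature_effect)) * sw_sd
  res_sw <- 1 - config$sugar_effect - config$n_enhancers * config$enhancer_effect -
    config$temperature_effect
  sweetness <- 40 + as.numeric(d_sw %*% b_sw) + sw_sd * sqrt(res_sw) * orth_resid(d_sw)

  tex_sd <- 15
  texture <- 30 + tex_sd * z_tex

  d_lk <- cbind(d_sw[, c("total_sugars", enhancer_ids), drop = FALSE],
                texture = z_tex, temperature = z_temp)
  b_lk <- c(sqrt(config$liking_sugar_effect),
            rep(sqrt(config$liking_enhancer_effect), config$n_enhancers),
            sqrt(config$texture_effect),
            -sqrt(config$temperature_effect)) * lk_sd
  res_lk <- 1 - config$liking_sugar_effect -
    config$n_enhancers * config$liking_enhancer_effect -
    config$texture_effect - config$temperature_effect
  liking <- 25.8 + as.numeric(d_lk %*% b_lk) + lk_sd * sqrt(res_lk) * orth_resid(d_lk)

  sour_sd <- 10
  sourness <- 30 + sour_sd * (sqrt(0.3) * z_acid +
                                sqrt(0.7) * orth_resid(cbind(z_acid)))
  sw_signal <- as.numeric(scale(d_sw %*% b_sw))
  fl_sd <- 10
  flavor <- 45 + fl_sd * (0.75 * sw_signal +
                            sqrt(1 - 0.75^2) * orth_resid(cbind(sw_signal)))

  sample_means <- cbind(liking = liking, texture_liking = texture,
                        sweetness = sweetness, sourness = sourness,
                        flavor_intensity = flavor)
  rownames(sample_means) <- sample_id

  slopes <- list(
    sweetness = stats::setNames(b_sw, colnames(d_sw)),
    liking = stats::setNames(b_lk, colnames(d_lk))
  )

  structure(list(
    config = config,
    samples = data.frame(sample_id = sample_id, period = period,
                         temp_c = temp_c, stringsAsFactors = FALSE),
    compounds = compounds,
    abundance = abundance,
    detected = detected,
    period_offsets = delta,
    pathway = data.frame(compound_id = vol_ids, pathway = pathway,
                         loading = loading, stringsAsFactors = FALSE),
    core_ids = vol_ids[core_idx],
    enhancer_ids = enhancer_ids,
    slopes = slopes,
    drivers = list(sweetness = d_sw, liking = d_lk),
    sample_means = sample_means,
    qtl = data.frame(marker_id = "M001", variance_fraction = config$qtl_variance,
                     allele_freq = config$allele_freq, stringsAsFactors = FALSE)
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat(sprintf("  %d samples x %d compounds; enhancers: %s\n",
              nrow(x$samples), nrow(x$compounds),
              paste(x$enhancer_ids, collapse = ", ")))
  cat(sprintf("  planted sweetness slopes (rating units / SD): %s\n",
              paste(sprintf("%.2f", x$slopes$sweetness), collapse = ", ")))
  invisible(x)
}

#' Write / read a truth registry as JSON
#'
#' Matrices are stored dense; this is intended for small study-sized objects.
#' @param truth a `sim_truth`.
#' @param path file path.
#' @return `path`, invisibly (for the writer); a list (for the reader).
#' @export
write_truth <- function(truth, path) {
  x <- truth
  x$config <- unclass(x$config)
  jsonlite::write_json(unclass(x), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
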