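test_that("noise-free panel reproduces the true sample means exactly", {
  cfg <- tiny_config(panelist_sd = 0, rating_noise_sd = 0)
  truth <- simulate_truth(cfg)
  ratings <- generate_sensory_panel(cfg, truth)
  for (a in c("sweetness", "liking")) {
    sub <- ratings[ratings$attribute == a, ]
    got <- tapply(sub$score, sub$sample_id, mean)
    b <- attribute_bounds(a)
    want <- pmin(pmax(truth$sample_means[names(got), a], b[, "lo"]), b[, "hi"])
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("scores are clipped to the attribute scales, even for off-scale true means", {
  cfg <- tiny_config()
  truth <- simulate_truth(cfg)
  truth$sample_means[, "sweetness"] <- 120  # off-scale intensity
  truth$sample_means[, "liking"] <- -150    # off-scale hedonic
  ratings <- generate_sensory_panel(cfg, truth)
  sw <- ratings$score[ratings$attribute == "sweetness"]
  lk <- ratings$score[ratings$attribute == "liking"]
  expect_true(all(sw <= 100 & sw >= 0))
  expect_true(all(lk >= -100 & lk <= 100))
  expect_gt(attr(ratings, "clip_fraction"), 0)
})

test_that("panelist and noise variance components are recovered by method of moments", {
  cfg <- sim_config(seed = 5)  # 148 samples, 100 panelists, sd 10 / 15
  truth <- simulate_truth(cfg)
  ratings <- generate_sensory_panel(cfg, truth)
  sub <- ratings[ratings$attribute == "sourness", ]  # mild clipping
  ## balanced within each session: interaction mean squares estimate the
  ## noise variance; panelist-mean variance minus noise/m gives panelist var
  est_e <- c(); est_b <- c()
  for (s in unique(sub$session_id)) {
    d <- sub[sub$session_id == s, ]
    X <- tapply(d$score, list(d$panelist_id, d$sample_id), mean)
    expect_gte(ncol(X), 3)  # session design floor
    r <- sweep(sweep(X, 1, rowMeans(X)), 2, colMeans(X)) + mean(X)
    est_e <- c(est_e, sum(r^2) / ((nrow(X) - 1) * (ncol(X) - 1)))
    est_b <- c(est_b, stats::var(rowMeans(X)) - mean(est_e) / ncol(X))
  }
  expect_lt(abs(mean(est_e) - cfg$rating_noise_sd^2) / cfg$rating_noise_sd^2, 0.2)
  expect_lt(abs(mean(est_b) - cfg$panelist_sd^2) / cfg$panelist_sd^2, 0.2)
})

test_that("zero batch shift leaves per-period compound means equal", {
  cfg <- tiny_config(batch_shift_sd = 0, volatile_sd_range = c(0.05, 0.05),
                     chem_noise_sd = 0, n_samples = 90, n_latent_pathways = 0)
  truth <- simulate_truth(cfg)
  chem <- generate_chemical_matrix(cfg, truth)
  id <- truth$core_ids[1]
  means <- tapply(log(chem$abundance[, id]), chem$samples$period, mean,
                  na.rm = TRUE)
  expect_lt(max(means) - min(means), 0.1)
})

test_that("default abundances span at least a 70-fold range for some volatile", {
  cfg <- sim_config(seed = 3)
  truth <- simulate_truth(cfg)
  chem <- generate_chemical_matrix(cfg, truth)
  vol <- chem$compounds$compound_id[!chem$compounds$class %in% c("sugar", "acid")]
  fold <- apply(chem$abundance[, vol], 2,
                function(v) max(v, na.rm = TRUE) / min(v, na.rm = TRUE))
  expect_gte(max(fold, na.rm = TRUE), 70)
})

test_that("compounds sharing a latent factor decorrelate only through noise", {
  ## closed form: log-abundances a_i = mu_a + la*f + e_a, b likewise; as the
  ## idiosyncratic noise goes to zero their correlation goes to 1
  cfg <- tiny_config(n_latent_pathways = 1, volatile_sd_range = c(1e-4, 1e-4),
                     chem_noise_sd = 0, n_samples = 60)
  truth <- simulate_truth(cfg)
  members <- truth$pathway$compound_id[!is.na(truth$pathway$pathway)]
  expect_gte(length(members), 2)
  chem <- generate_chemical_matrix(cfg, truth)
  sc <- autoscale_by_period(chem)
  r <- cor(sc$values[, members[1]], sc$values[, members[2]],
           use = "complete.obs")
  expect_gt(abs(r), 0.999)
})

test_that("genotypes follow Hardy-Weinberg and the null marker explains nothing", {
  cfg <- tiny_config(n_geno_samples = 20000, allele_freq = 0.5, qtl_variance = 0)
  truth <- simulate_truth(cfg)
  geno <- generate_genotypes(cfg, truth)
  freq <- table(factor(geno$G[, 1], levels = 0:2)) / nrow(geno$G)
  expect_equal(as.numeric(freq), c(0.25, 0.5, 0.25), tolerance = 0.03)
  scan <- single_marker_scan(geno)
  expect_lt(scan$r2[scan$marker_id == geno$causal_marker], 0.002)
})

test_that("identical configuration gives bitwise-identical outputs", {
  a <- simulate_study(tiny_config(seed = 99), genotypes = TRUE)
  b <- simulate_study(tiny_config(seed = 99), genotypes = TRUE)
  expect_identical(a$chem$abundance, b$chem$abundance)
  expect_identical(a$ratings$score, b$ratings$score)
  expect_identical(a$geno$G, b$geno$G)
  expect_identical(a$truth$sample_means, b$truth$sample_means)
  c2 <- simulate_study(tiny_config(seed = 100))
  expect_false(identical(a$chem$abundance, c2$chem$abundance))
})

test_that("registered slopes are recovered exactly from noise-free sample means", {
  for (seed in 1:3) {
    truth <- simulate_truth(tiny_config(seed = seed, n_samples = 40))
    for (resp in c("sweetness", "liking")) {
      d <- truth$drivers[[resp]]
      fit <- stats::lm.fit(cbind(1, d), truth$sample_means[, resp])
      expect_equal(unname(fit$coefficients[-1]),
                   unname(truth$slopes[[resp]]), tolerance = 1e-6)
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(sugar_effect = 0.7, enhancer_effect = 0.15),
               "sum to < 1")
  expect_error(sim_config(n_panelists_per_session = 0), "count >= 1")
  expect_error(sim_config(allele_freq = 1), "strictly within")
  expect_error(sim_config(n_latent_pathways = 20, n_volatiles = 10),
               "n_volatiles")
  expect_error(sim_config(samples_per_session = 6), "between 3 and 5")
})
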