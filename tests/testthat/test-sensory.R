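make_ratings <- function(panelist, sample, score, attribute = "sweetness") {
  panel_ratings(data.frame(panelist_id = panelist, session_id = "s1",
                           sample_id = sample, attribute = attribute,
                           score = score, stringsAsFactors = FALSE))
}

test_that("a single panelist yields the raw sample means", {
  r <- make_ratings("P1", c("A", "B", "C"), c(10, 20, 30))
  m <- fit_panelist_adjusted_means(r)
  expect_equal(m$mean, c(10, 20, 30))
  expect_true(all(m$single_rater))
})

test_that("balanced panelist offsets are absorbed by the mixed model", {
  ## two panelists with offsets +5 / -5 rating all three samples: the
  ## adjusted means equal the raw sample means (hand solution of the
  ## balanced two-way model)
  truth <- c(A = 30, B = 50, C = 70)
  r <- make_ratings(rep(c("P1", "P2"), each = 3),
                    rep(names(truth), 2),
                    c(truth + 5, truth - 5))
  m <- fit_panelist_adjusted_means(r)
  expect_equal(m$mean, unname(truth), tolerance = 1e-6)
})

test_that("REML variance components match a profiled-likelihood oracle", {
  ## unbalanced 4 panelists x 4 samples with missing cells
  set.seed(3)
  grid <- expand.grid(panelist = sprintf("P%d", 1:4),
                      sample = sprintf("S%d", 1:4),
                      stringsAsFactors = FALSE)
  grid <- grid[-c(2, 7, 11, 16), ]
  mu <- c(S1 = 20, S2 = 35, S3 = 50, S4 = 65)
  off <- c(P1 = -6, P2 = -2, P3 = 3, P4 = 5)
  grid$score <- mu[grid$sample] + off[grid$panelist] + rnorm(nrow(grid), 0, 4)
  r <- panel_ratings(data.frame(panelist_id = grid$panelist, session_id = "s1",
                                sample_id = grid$sample,
                                attribute = "sweetness", score = grid$score))
  m <- fit_panelist_adjusted_means(r)
  vc <- attr(m, "variance_components")
  lambda_pkg <- vc$panelist_var / vc$residual_var

  X <- stats::model.matrix(~ 0 + sample, grid)
  Z <- stats::model.matrix(~ 0 + panelist, grid)
  obj <- function(ll) reml_loglik(grid$score, X, Z, exp(ll))
  lambda_oracle <- exp(stats::optimize(obj, c(-10, 5), maximum = TRUE,
                                       tol = 1e-10)$maximum)
  expect_equal(lambda_pkg, lambda_oracle, tolerance = 1e-4)
})

test_that("adjusted mean contrasts are invariant to a constant panelist shift", {
  truth <- c(A = 30, B = 50, C = 70)
  base <- make_ratings(rep(c("P1", "P2", "P3"), each = 3),
                       rep(names(truth), 3),
                       c(truth + 4, truth, truth - 4))
  shifted <- base
  shifted$score[shifted$panelist_id == "P2"] <-
    shifted$score[shifted$panelist_id == "P2"] + 25
  m1 <- fit_panelist_adjusted_means(base)
  m2 <- fit_panelist_adjusted_means(shifted)
  expect_equal(diff(m1$mean), diff(m2$mean), tolerance = 1e-6)
})

test_that("Spearman correlations match the rank formula", {
  ## rank differences d^2 = (1,1,1,1,0): rho = 1 - 6*4/(5*24) = 0.8
  wide <- data.frame(sample_id = sprintf("S%d", 1:5),
                     liking = c(1, 2, 3, 4, 5),
                     sweetness = c(2, 1, 4, 3, 5))
  ac <- attribute_correlations(wide, control = "none")
  expect_equal(ac$rho[ac$attr1 == "liking" & ac$attr2 == "sweetness"], 0.8)
  ## and a perfect monotone pair
  wide$sweetness <- c(10, 20, 25, 30, 90)
  ac2 <- attribute_correlations(wide, control = "none")
  expect_equal(ac2$rho[1], 1)
})

test_that("partial correlation reduces to the marginal when controls are orthogonal", {
  expect_equal(flavoromics:::partial_cor(0.6, 0, 0), 0.6)
  expect_equal(flavoromics:::partial_cor(1, 0.3, 0.3),
               (1 - 0.09) / (1 - 0.09))  # self-correlation stays 1
  ## numerically: x, y, z with z orthogonal to both on ranks
  set.seed(1)
  n <- 40
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  z <- stats::residuals(stats::lm(rnorm(n) ~ rank(x) + rank(y)))
  wide <- data.frame(sample_id = seq_len(n), liking = x, sourness = y,
                     sweetness = z)
  ac <- attribute_correlations(wide)
  row <- ac[ac$attr1 == "liking" & ac$attr2 == "sourness", ]
  expect_equal(row$partial_rho, cor(rank(x), rank(y)), tolerance = 0.02)
})

test_that("a constant attribute yields missing correlations, not zero", {
  wide <- data.frame(sample_id = sprintf("S%d", 1:6),
                     liking = rnorm(6), sweetness = rep(5, 6))
  ac <- attribute_correlations(wide)
  expect_true(is.na(ac$rho[ac$attr1 == "liking" & ac$attr2 == "sweetness"]))
})

test_that("temperature trends match closed-form OLS", {
  d <- data.frame(genotype = "g1", temperature = c(17, 18, 19),
                  sweetness = c(30, 20, 10))
  tr <- temperature_trend(d, "sweetness")
  expect_equal(tr$slope[tr$genotype == "g1"], -10)
  flat <- data.frame(genotype = "g1", temperature = c(17, 18, 19),
                     sweetness = c(12, 12, 12))
  expect_equal(temperature_trend(flat, "sweetness")$slope[1], 0)
  single <- data.frame(genotype = "g1", temperature = 17, sweetness = 12)
  expect_error(temperature_trend(single, "sweetness"), "slope undefined")
})

test_that("a planted negative temperature effect is detected in most replicates", {
  signs <- vapply(1:100, function(k) {
    truth <- simulate_truth(tiny_config(seed = 1000 + k, n_samples = 40,
                                        temperature_effect = 0.08))
    d <- data.frame(genotype = "all", temperature = truth$samples$temp_c,
                    sweetness = truth$sample_means[, "sweetness"])
    temperature_trend(d, "sweetness")$slope[2]
  }, numeric(1))
  expect_gte(mean(signs < 0), 0.95)
})
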