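test_that("a perfect univariate relation is fit exactly with one component", {
  x <- matrix(seq(-2, 2, length.out = 12), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- 2 * x[, 1]
  m <- fit_pls_nipals(x, y, ncomp = 1)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  expect_equal(m$fitted, y, tolerance = 1e-10)
  expect_equal(unname(vip_scores(m)), 1)  # p = 1 forces VIP = 1
})

test_that("NIPALS agrees with the eigen-decomposition reference on random instances", {
  set.seed(21)
  for (k in 1:100) {
    n <- sample(8:15, 1); p <- sample(3:6, 1)
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    A <- min(3, p)
    m1 <- fit_pls_nipals(X, y, A)
    m2 <- fit_pls_eigen(X, y, A)
    expect_equal(m1$fitted, m2$fitted, tolerance = 1e-8)
  }
})

test_that("NIPALS agrees with an established PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(22)
  X <- matrix(rnorm(30 * 6), 30, dimnames = list(NULL, sprintf("x%d", 1:6)))
  y <- rnorm(30)
  m <- fit_pls_nipals(X, y, 3, scale_y = FALSE)
  mo <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  expect_equal(predict(m, X), unname(predict(mo, X)$predict[, 1, 3]),
               tolerance = 1e-10)
  expect_equal(unname(vip_scores(m)), unname(mixOmics::vip(mo)[, 3]),
               tolerance = 1e-10)
})

test_that("at full rank PLS saturates to the OLS projection", {
  set.seed(23)
  X <- matrix(rnorm(20 * 4), 20, dimnames = list(NULL, sprintf("x%d", 1:4)))
  y <- rnorm(20)
  m <- fit_pls_nipals(X, y, ncomp = 4)
  ols <- stats::lm(y ~ X)
  expect_equal(m$fitted, unname(stats::fitted(ols)), tolerance = 1e-8)
  expect_error(fit_pls_nipals(X, y, ncomp = 5), "rank")
})

test_that("component scores are orthogonal and R2 is monotone in A", {
  set.seed(24)
  X <- matrix(rnorm(25 * 8), 25)
  y <- X[, 1] + rnorm(25)
  m <- fit_pls_nipals(X, y, 4)
  g <- crossprod(m$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  r2 <- vapply(1:4, function(a) fit_pls_nipals(X, y, a)$r_squared, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("the VIP sum-of-squares identity holds and matches term-by-term evaluation", {
  set.seed(25)
  X <- matrix(rnorm(6 * 3), 6, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(6)
  m <- fit_pls_nipals(X, y, 2)
  v <- vip_scores(m)
  expect_equal(sum(v^2), 3, tolerance = 1e-6)
  ## term-by-term evaluation of the formula from the model pieces
  for (j in 1:3) {
    num <- 0
    for (a in 1:2) {
      w_norm <- m$weights[j, a]^2 / sum(m$weights[, a]^2)
      num <- num + m$ss_comp[a] * w_norm
    }
    expect_equal(unname(v[j]), unname(sqrt(3 * num / sum(m$ss_comp))),
                 tolerance = 1e-10)
  }
})

test_that("the consensus rule reproduces printed-table behavior", {
  vips <- rbind(sucrose_like = c(2.17, 2.10, 0.27),
                weak = c(0.9, 0.95, 1.05),
                absent = c(NA, 1.34, 1.44),
                zero = c(0, 0, 0))
  colnames(vips) <- paste0("p", 1:3)
  cons <- consensus_selection(vips)
  expect_true(cons$selected[cons$variable == "sucrose_like"])
  expect_true(cons$selected[cons$variable == "absent"])  # 2 of 2 modeled
  expect_false(cons$selected[cons$variable == "weak"])
  expect_false(cons$selected[cons$variable == "zero"])
  expect_error(consensus_selection(vips, min_periods = 4), "exceeds")
  all_zero <- consensus_selection(vips["zero", , drop = FALSE])
  expect_identical(sum(all_zero$selected), 0L)
})

test_that("the sugar-independence test matches the normal-equations oracle", {
  ## toy n = 6 with planted volatile slope 1.5
  v <- c(-1.2, -0.5, 0.1, 0.4, 0.9, 1.6)
  s <- c(0.3, -0.8, 1.1, -0.2, 0.6, -1.0)
  e <- c(0.05, -0.1, 0.08, -0.03, 0.02, -0.02)
  y <- 10 + 1.5 * v + 0.8 * s + e
  got <- sugar_independence_test(v, y, s)
  Xm <- cbind(1, v, s)
  beta <- solve(crossprod(Xm), crossprod(Xm, y))
  resid <- y - Xm %*% beta
  s2 <- sum(resid^2) / (6 - 3)
  se <- sqrt(s2 * solve(crossprod(Xm))[2, 2])
  expect_equal(got$beta, unname(beta[2, 1]), tolerance = 1e-10)
  expect_equal(got$t, unname(beta[2, 1] / se), tolerance = 1e-10)
  expect_equal(got$p,
               unname(2 * stats::pt(abs(beta[2, 1] / se), 3, lower.tail = FALSE)),
               tolerance = 1e-12)
})

test_that("a volatile orthogonal to response and sugars has a null slope", {
  set.seed(26)
  n <- 24
  s <- rnorm(n); y <- 2 * s + rnorm(n)
  v <- stats::residuals(stats::lm(rnorm(n) ~ y + s))
  got <- sugar_independence_test(v, y, s)
  expect_lt(abs(got$beta), 1e-10)
  expect_equal(got$p, 1, tolerance = 1e-6)
  ## collinear volatile flagged non-identifiable
  flag <- sugar_independence_test(s, y, s)
  expect_false(flag$identifiable)
})

test_that("selection is invariant to period relabeling", {
  cfg <- tiny_config(seed = 31, n_samples = 36)
  truth <- simulate_truth(cfg)
  chem <- generate_chemical_matrix(cfg, truth)
  ratings <- generate_sensory_panel(cfg, truth)
  means <- fit_panelist_adjusted_means(ratings, method = "raw")
  sel1 <- select_enhancers(autoscale_by_period(chem), chem, means)
  relab <- chem
  relab$samples$period <- paste0("X_", relab$samples$period)
  sel2 <- select_enhancers(autoscale_by_period(relab), relab, means)
  expect_identical(sel1$variable[sel1$selected], sel2$variable[sel2$selected])
  expect_equal(sel1$p_adj, sel2$p_adj, tolerance = 1e-12)
})

test_that("the full selection recovers planted enhancers on one study", {
  cfg <- sim_config(seed = 77)
  rec <- simulate_and_recover(cfg, genotypes = FALSE)
  expect_equal(rec$sensitivity, 1)
  expect_lte(rec$false_positives, 1)
})
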