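fake_corr <- function(edges) {
  ## minimal correlation_table with the given significant edges (r = 1)
  out <- data.frame(var1 = edges[, 1], var2 = edges[, 2], r = 1, n = 100,
                    p = 1e-12, p_bh = 1e-10, p_bonf = 1e-10,
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_table", class(out))
  out
}

test_that("BH adjustment matches the hand step-up oracle", {
  set.seed(11)
  x <- matrix(rnorm(30 * 6), 30, dimnames = list(NULL, sprintf("v%d", 1:6)))
  ct <- pairwise_correlations(x)
  expect_equal(ct$p_bh, bh_oracle(ct$p), tolerance = 1e-12)
  expect_equal(ct$p_bonf, pmin(ct$p * nrow(ct), 1), tolerance = 1e-12)
  expect_true(all(ct$p_bh >= ct$p - 1e-15))
})

test_that("frozen BH example: (0.001, 0.01, 0.02, 0.04, 0.05)", {
  expect_equal(bh_oracle(c(0.001, 0.01, 0.02, 0.04, 0.05)),
               c(0.005, 0.025, 0.05 * 2 / 3, 0.05, 0.05))
})

test_that("a collinear pair dominates the adjusted p-values", {
  set.seed(2)
  x <- matrix(rnorm(25 * 5), 25, dimnames = list(NULL, sprintf("v%d", 1:5)))
  x <- cbind(x, v6 = x[, 1])
  ct <- pairwise_correlations(x)
  best <- ct[which.min(ct$p_bh), ]
  expect_setequal(c(best$var1, best$var2), c("v1", "v6"))
})

test_that("correlations are symmetric and pairs below min_n are excluded", {
  set.seed(3)
  x <- matrix(rnorm(20 * 4), 20, dimnames = list(NULL, sprintf("v%d", 1:4)))
  x[1:17, 4] <- NA  # only 3 complete obs against the others
  ct <- pairwise_correlations(x, min_n = 5)
  expect_false("v4" %in% c(ct$var1, ct$var2))
  expect_gt(nrow(attr(ct, "excluded")), 0)
  cm <- cor(x[, 1:3])
  for (k in seq_len(nrow(ct))) {
    expect_equal(ct$r[k], cm[ct$var1[k], ct$var2[k]], tolerance = 1e-12)
  }
})

test_that("authority centrality matches the closed form on a path graph", {
  ## path a-b-c with unit weights: scores proportional to (1, sqrt(2), 1)
  net <- build_network(fake_corr(cbind(c("a", "b"), c("b", "c"))))
  got <- net$nodes$authority[match(c("a", "b", "c"), net$nodes$id)]
  expect_equal(got, c(1 / sqrt(2), 1, 1 / sqrt(2)), tolerance = 1e-9)
})

test_that("the center of a star carries the maximal centrality", {
  edges <- cbind("hub", sprintf("leaf%d", 1:4))
  net <- build_network(fake_corr(edges))
  expect_identical(net$nodes$id[which.max(net$nodes$authority)], "hub")
  expect_equal(max(net$nodes$authority), 1)
})

test_that("authority agrees with an independent eigenvector implementation", {
  skip_if_not_installed("igraph")
  set.seed(8)
  x <- matrix(rnorm(60 * 6), 60, dimnames = list(NULL, sprintf("v%d", 1:6)))
  for (j in 2:6) x[, j] <- x[, j - 1] + rnorm(60, 0, seq(0.3, 0.9, length.out = 5)[j - 1])
  ct <- pairwise_correlations(x)
  net <- build_network(ct, alpha = 0.05)
  expect_gt(nrow(net$edges), 4)
  g <- igraph::graph_from_data_frame(net$edges[c("var1", "var2", "weight")],
                                     directed = FALSE,
                                     vertices = net$nodes$id)
  expect_true(igraph::is_connected(g))  # one component: global comparison valid
  ref <- igraph::hits_scores(g)$authority
  expect_equal(net$nodes$authority, unname(ref[net$nodes$id]),
               tolerance = 1e-6)
})

test_that("the edge set shrinks monotonically as alpha tightens", {
  set.seed(4)
  x <- matrix(rnorm(50 * 10), 50, dimnames = list(NULL, sprintf("v%d", 1:10)))
  x[, 1:4] <- x[, 1] + matrix(rnorm(50 * 4, 0, 0.8), 50)
  ct <- pairwise_correlations(x)
  sizes <- vapply(c(0.2, 0.05, 0.01, 0.001),
                  function(a) nrow(build_network(ct, a)$edges), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  key <- function(net) paste(net$edges$var1, net$edges$var2)
  expect_true(all(key(build_network(ct, 0.01)) %in% key(build_network(ct, 0.05))))
})

test_that("an empty edge set gives an empty network, not an error", {
  ct <- fake_corr(cbind("a", "b"))
  ct$p_bonf <- 0.9
  net <- build_network(ct)
  expect_identical(nrow(net$nodes), 0L)
})

test_that("BP equals the enumerated appearance frequency of each cluster", {
  set.seed(6)
  n <- 30
  f <- rnorm(n)
  x <- cbind(a = f + rnorm(n, 0, 0.3), b = f + rnorm(n, 0, 0.3),
             c = rnorm(n), d = rnorm(n))
  b <- bootstrap_cluster(x, n_boot = 100, scale_factors = c(0.8, 1, 1.2),
                         seed = 4, store_replicates = TRUE)
  s1 <- which(b$scale_factors == 1)
  keys <- vapply(b$clusters, function(cl) paste(sort(cl), collapse = "\r"), "")
  for (k in seq_along(keys)) {
    count <- sum(vapply(b$replicates[[s1]],
                        function(rep) keys[k] %in% rep, logical(1)))
    expect_equal(b$support$bp[k], count / 100)
  }
})

test_that("well-separated blocks get AU support of at least 0.95", {
  set.seed(5)
  n <- 40
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(sapply(1:3, function(i) f1 + rnorm(n, 0, 0.05)),
             sapply(1:3, function(i) f2 + rnorm(n, 0, 0.05)))
  colnames(x) <- sprintf("v%d", 1:6)
  b <- bootstrap_cluster(x, n_boot = 200, seed = 3)
  sizes <- vapply(b$clusters, length, integer(1))
  blocks <- which(sizes == 3)
  expect_identical(length(blocks), 2L)
  expect_true(all(b$support$au[blocks] >= 0.95))
})

test_that("AU exceeds BP for supported clusters with positive curvature", {
  set.seed(5)
  n <- 40
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(sapply(1:4, function(i) f1 + rnorm(n, 0, 0.9)),
             sapply(1:4, function(i) f2 + rnorm(n, 0, 0.9)))
  colnames(x) <- sprintf("v%d", 1:8)
  b <- bootstrap_cluster(x, n_boot = 200, seed = 2)
  mid <- b$support$bp > 0.2 & b$support$bp < 0.95
  expect_gt(sum(mid), 0)
  expect_true(all(b$support$au[mid] >= b$support$bp[mid]))
})

test_that("clustering is invariant to the variable input order", {
  set.seed(12)
  x <- matrix(rnorm(30 * 6), 30, dimnames = list(NULL, sprintf("v%d", 1:6)))
  x[, 2] <- x[, 1] + rnorm(30, 0, 0.2)
  x[, 4] <- x[, 3] + rnorm(30, 0, 0.2)
  b1 <- bootstrap_cluster(x, n_boot = 100, seed = 9)
  b2 <- bootstrap_cluster(x[, c(4, 2, 6, 1, 3, 5)], n_boot = 100, seed = 9)
  key <- function(b) sort(vapply(b$clusters,
                                 function(cl) paste(sort(cl), collapse = "+"), ""))
  expect_identical(key(b1), key(b2))
  expect_equal(sort(b1$hclust$height), sort(b2$hclust$height), tolerance = 1e-12)
})

test_that("degenerate scale grids are rejected", {
  x <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, sprintf("v%d", 1:4)))
  expect_error(bootstrap_cluster(x, n_boot = 100, scale_factors = c(1, 1.2)),
               "below and above 1")
  expect_error(bootstrap_cluster(x, n_boot = 50), ">= 100")
})

test_that("network and dendrogram exports are readable plain text", {
  set.seed(13)
  x <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, sprintf("v%d", 1:5)))
  x[, 2] <- x[, 1] + rnorm(30, 0, 0.2)
  ct <- pairwise_correlations(x)
  net <- build_network(ct, alpha = 0.2, adjust = "raw")
  g_path <- withr::local_tempfile(fileext = ".graphml")
  e_path <- withr::local_tempfile(fileext = ".csv")
  write_network(net, g_path, e_path)
  expect_true(any(grepl("graphml", readLines(g_path))))
  expect_equal(nrow(utils::read.csv(e_path)), nrow(net$edges))

  b <- bootstrap_cluster(x, n_boot = 100, seed = 1)
  n_path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(b, n_path)
  tr <- ape::read.tree(n_path)
  expect_setequal(tr$tip.label, colnames(x))
  expect_true(any(grepl("AU", tr$node.label)))
})
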