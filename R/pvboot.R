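#' Hierarchical clustering with multiscale bootstrap cluster support
#'
#' Clusters the variables (columns) of a data matrix and attaches to every
#' internal cluster a BP (bootstrap probability) value -- the fraction of
#' ordinary bootstrap trees containing the cluster -- and an AU
#' (approximately unbiased) p-value obtained from multiscale bootstrap
#' resampling: bootstrap sample sizes `m = round(r * n)` are varied over
#' `scale_factors` r, the probit-transformed support
#' \eqn{\psi_r = \Phi^{-1}(1 - BP_r)} is regressed on \eqn{(\sqrt r, 1/\sqrt r)}
#' by weighted least squares (binomial weights), and for fitted coefficients
#' (v, c) the AU value is \eqn{1 - \Phi(v - c)}. The scale grid must bracket
#' 1 from both sides, otherwise the signed-distance/curvature decomposition
#' is ill-posed.
#'
#' @param x numeric samples x variables matrix; complete (impute first).
#' @param n_boot bootstrap replicates per scale (>= 100).
#' @param scale_factors relative bootstrap sample sizes; must contain values
#'   below and above 1.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (`"ward.D"` by default, the legacy ward behavior).
#' @param distance `"correlation"` (1 - Pearson r between variables) or
#'   `"euclidean"`.
#' @param seed integer seed for the resampling.
#' @param store_replicates keep the per-replicate cluster sets (memory-heavy;
#'   used for enumeration checks).
#' @return object of class `boot_dendrogram`: `hclust`, `clusters` (list of
#'   leaf-label vectors per internal node), `support` (data.frame with `bp`,
#'   `au` per internal node), `bp_matrix` (clusters x scales), settings, and
#'   optionally `replicates`.
#' @export
bootstrap_cluster <- function(x, n_boot = 1000, scale_factors = seq(0.5, 1.4, by = 0.1),
                              linkage = "ward.D",
                              distance = c("correlation", "euclidean"),
                              seed = 1, store_replicates = FALSE) {
  x <- as.matrix(x)
  distance <- match.arg(distance)
  if (ncol(x) < 3) stop("need at least 3 variables to cluster")
  assert_config(n_boot >= 100, "`n_boot` must be >= 100 per scale")
  assert_config(any(scale_factors < 1) && any(scale_factors > 1),
                "`scale_factors` must contain values below and above 1 (AU fit ill-posed otherwise)")
  n <- nrow(x); p <- ncol(x)

  var_dist <- function(rows) {
    sub <- x[rows, , drop = FALSE]
    if (distance == "correlation") {
      r <- suppressWarnings(stats::cor(sub))
      d <- 1 - r
      d[is.na(d)] <- 2  # constant column under resampling: maximal dissimilarity
      stats::as.dist(d)
    } else {
      stats::dist(t(sub))
    }
  }

  hc <- stats::hclust(var_dist(seq_len(n)), method = linkage)
  clusters <- hclust_clusters(hc)
  keys <- vapply(clusters, function(cl) paste(sort(cl), collapse = "\r"), "")

  set.seed(substream_seed(seed, "pvboot"))
  counts <- matrix(0L, length(clusters), length(scale_factors))
  replicates <- if (store_replicates) {
    lapply(scale_factors, function(...) vector("list", n_boot))
  } else NULL
  for (s in seq_along(scale_factors)) {
    m <- max(3L, round(scale_factors[s] * n))
    for (b in seq_len(n_boot)) {
      rows <- sample.int(n, m, replace = TRUE)
      bh <- stats::hclust(var_dist(rows), method = linkage)
      bkeys <- vapply(hclust_clusters(bh),
                      function(cl) paste(sort(cl), collapse = "\r"), "")
      hit <- keys %in% bkeys
      counts[hit, s] <- counts[hit, s] + 1L
      if (store_replicates) replicates[[s]][[b]] <- bkeys
    }
  }
  bp_matrix <- counts / n_boot
  dimnames(bp_matrix) <- list(NULL, sprintf("r=%g", scale_factors))

  au <- vapply(seq_along(clusters), function(k)
    au_from_multiscale(counts[k, ], n_boot, scale_factors), numeric(1))
  ref_scale <- which.min(abs(scale_factors - 1))
  support <- data.frame(node = seq_along(clusters),
                        bp = bp_matrix[, ref_scale],
                        au = au)

  structure(list(hclust = hc, clusters = clusters, support = support,
                 bp_matrix = bp_matrix, scale_factors = scale_factors,
                 n_boot = n_boot, linkage = linkage, distance = distance,
                 replicates = replicates),
            class = "boot_dendrogram")
}

# Leaf-label sets of every internal node of an hclust tree, in merge order.
hclust_clusters <- function(hc) {
  p <- length(hc$labels %||% seq_len(nrow(hc$merge) + 1L))
  labs <- hc$labels %||% as.character(seq_len(p))
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    take <- function(v) if (v < 0) labs[-v] else sets[[v]]
    sets[[k]] <- c(take(hc$merge[k, 1]), take(hc$merge[k, 2]))
  }
  sets
}

# Multiscale AU from per-scale appearance counts (Shimodaira correction).
au_from_multiscale <- function(cnt, n_boot, scales) {
  if (all(cnt == n_boot)) return(1)
  if (all(cnt == 0)) return(0)
  cnt_eff <- pmin(pmax(cnt, 0.5), n_boot - 0.5)
  bp <- cnt_eff / n_boot
  psi <- stats::qnorm(1 - bp)
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  w <- n_boot * stats::dnorm(psi)^2 / (bp * (1 - bp))
  coefs <- tryCatch(solve(crossprod(X, w * X), crossprod(X, w * psi)),
                    error = function(e) NULL)
  if (is.null(coefs)) return(mean(cnt) / n_boot)
  1 - stats::pnorm(coefs[1] - coefs[2])
}

#' @export
print.boot_dendrogram <- function(x, ...) {
  cat(sprintf("<boot_dendrogram> %d variables, %s linkage on %s distance; %d boots x %d scales\n",
              length(x$hclust$labels), x$linkage, x$distance, x$n_boot,
              length(x$scale_factors)))
  top <- utils::head(x$support[order(-x$support$au), ], 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  node %d: AU %.2f BP %.2f (%d leaves)\n", top$node[i],
                top$au[i], top$bp[i], length(x$clusters[[top$node[i]]])))
  }
  invisible(x)
}

#' Export a supported dendrogram as Newick with AU/BP node comments
#'
#' @param boot a `boot_dendrogram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(boot, path) {
  ph <- ape::as.phylo(boot$hclust)
  nn <- ph$Nnode
  labels <- character(nn)
  clade_sets <- phylo_clades(ph)
  keys <- vapply(boot$clusters, function(cl) paste(sort(cl), collapse = "\r"), "")
  for (i in seq_len(nn)) {
    k <- match(paste(sort(clade_sets[[i]]), collapse = "\r"), keys)
    labels[i] <- if (is.na(k)) "" else
      sprintf("AU%.2f_BP%.2f", boot$support$au[k], boot$support$bp[k])
  }
  ph$node.label <- labels
  ape::write.tree(ph, file = path)
  invisible(path)
}

# Tip-label sets of each internal node of a phylo object.
phylo_clades <- function(ph) {
  ntip <- length(ph$tip.label)
  sets <- vector("list", ph$Nnode)
  get <- function(node) {
    if (node <= ntip) return(ph$tip.label[node])
    idx <- node - ntip
    if (!is.null(sets[[idx]])) return(sets[[idx]])
    kids <- ph$edge[ph$edge[, 1] == node, 2]
    out <- unlist(lapply(kids, get))
    sets[[idx]] <<- out
    out
  }
  get(ntip + 1L)
  ## ensure all filled (handles any unvisited nodes defensively)
  for (i in seq_len(ph$Nnode)) if (is.null(sets[[i]])) get(ntip + i)
  sets
}
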