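#' Box-Cox normalization of a positive phenotype
#'
#' Power transform `y = (x^lambda - 1) / lambda` (natural log at lambda = 0)
#' with lambda chosen by maximizing the profile log-likelihood
#' \deqn{\ell(\lambda) = -\frac{n}{2}\log\hat\sigma^2(\lambda) + (\lambda - 1)\sum_i \log x_i}
#' over `interval` (Brent optimization; the profile is unimodal for the
#' skewed abundance distributions this is meant for).
#'
#' @param x positive values (relative abundances of an ester, typically).
#' @param interval search interval for lambda.
#' @return list of class `boxcox_fit`: `lambda`, `transformed`,
#'   `log_likelihood`, `interval`.
#' @export
boxcox_transform <- function(x, interval = c(-2, 2)) {
  if (any(!is.finite(x))) stop("non-finite value at position ",
                               which(!is.finite(x))[1])
  if (any(x <= 0)) {
    stop("Box-Cox requires positive values; offending sample(s): ",
         paste(utils::head(which(x <= 0), 5), collapse = ", "))
  }
  n <- length(x)
  slx <- sum(log(x))
  ll <- function(lambda) {
    yt <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
    s2 <- mean((yt - mean(yt))^2)
    -n / 2 * log(s2) + (lambda - 1) * slx
  }
  opt <- stats::optimize(ll, interval, maximum = TRUE, tol = 1e-8)
  lambda <- opt$maximum
  yt <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  structure(list(lambda = lambda, transformed = yt,
                 log_likelihood = opt$objective, interval = interval,
                 profile = ll),
            class = "boxcox_fit")
}

#' @export
print.boxcox_fit <- function(x, ...) {
  cat(sprintf("<boxcox_fit> lambda = %.4f (profile logLik %.2f)\n",
              x$lambda, x$log_likelihood))
  invisible(x)
}

#' Apply the Box-Cox transform at a fixed exponent
#'
#' @param x positive values.
#' @param lambda exponent; 0 gives the natural log.
#' @return transformed values `(x^lambda - 1) / lambda`.
#' @export
box_cox_apply <- function(x, lambda) {
  if (any(x <= 0)) stop("Box-Cox requires positive values")
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Single-marker association scan
#'
#' Regresses the phenotype on additive marker dosage (0/1/2), one marker at
#' a time, reporting the slope, the variance explained `R^2` (model SS over
#' total SS, identical to the squared dosage-phenotype correlation), the
#' F-test p-value, and Benjamini-Hochberg adjusted p-values across markers.
#' Monomorphic markers are skipped (logged in the `skipped` attribute);
#' missing dosages are dropped casewise per marker.
#'
#' @param geno a `genotype_matrix` (from [generate_genotypes()] or
#'   [read_genotypes()]).
#' @param phenotype numeric phenotype; defaults to `geno$phenotype`.
#' @return data.frame of class `association_result` ordered by linkage group
#'   and position: `marker_id`, `linkage_group`, `position`, `slope`, `r2`,
#'   `p`, `p_bh`, `n`.
#' @export
single_marker_scan <- function(geno, phenotype = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  y_all <- phenotype %||% geno$phenotype
  if (is.null(y_all)) stop("no phenotype supplied")
  G <- geno$G
  stopifnot(length(y_all) == nrow(G))
  res <- vector("list", ncol(G)); skipped <- character()
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    ok <- !is.na(g) & !is.na(y_all)
    g <- g[ok]; y <- y_all[ok]
    if (length(unique(g)) < 2) { skipped <- c(skipped, colnames(G)[j]); next }
    n <- length(y)
    sxx <- sum((g - mean(g))^2)
    sxy <- sum((g - mean(g)) * (y - mean(y)))
    syy <- sum((y - mean(y))^2)
    slope <- sxy / sxx
    r2 <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
    fstat <- r2 / (1 - r2) * (n - 2)
    p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
    res[[j]] <- data.frame(marker_id = colnames(G)[j], slope = slope, r2 = r2,
                           p = p, n = n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no polymorphic marker to test")
  out$p_bh <- stats::p.adjust(out$p, "BH")
  m <- match(out$marker_id, geno$map$marker_id)
  out$linkage_group <- geno$map$linkage_group[m]
  out$position <- geno$map$position[m]
  out <- out[order(out$linkage_group, out$position),
             c("marker_id", "linkage_group", "position", "slope", "r2",
               "p", "p_bh", "n")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("association_result", class(out))
  out
}

#' Principal component analysis of genotype or chemical matrices
#'
#' Centered PCA (autoscaled when `scale. = TRUE`, the convention for
#' chemical matrices). Any variable containing a missing value is omitted
#' before the decomposition — the standard treatment for SNP matrices with
#' sporadic missing calls.
#'
#' @param x samples x variables numeric matrix.
#' @param scale. autoscale variables first?
#' @return list of class `pca_result`: `scores`, `percent_variance`,
#'   `n_variables_used`, `omitted_variables`.
#' @export
pca_matrix <- function(x, scale. = FALSE) {
  x <- as.matrix(x)
  has_na <- colSums(is.na(x)) > 0
  omitted <- colnames(x)[has_na]
  x <- x[, !has_na, drop = FALSE]
  if (scale.) {
    const <- col_sd(x) == 0
    omitted <- c(omitted, colnames(x)[const])
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 complete variables; cannot run PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, percent_variance = pv,
                 rotation = pc$rotation,
                 n_variables_used = ncol(x), omitted_variables = omitted),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d variables; PC1 %.1f%%, PC2 %.1f%%\n",
              x$n_variables_used, x$percent_variance[1],
              ifelse(length(x$percent_variance) > 1, x$percent_variance[2], 0)))
  invisible(x)
}

#' Genotype-class means with Tukey groupings
#'
#' For a single marker: per-dosage-class phenotype means and compact-letter
#' groupings from Tukey's HSD at `alpha` (classes sharing a letter are not
#' significantly different).
#'
#' @param geno a `genotype_matrix`.
#' @param marker_id marker to summarize.
#' @param phenotype phenotype vector (defaults to `geno$phenotype`).
#' @param alpha familywise level for the HSD.
#' @return data.frame: `dosage`, `n`, `mean`, `se`, `group`.
#' @export
genotype_class_report <- function(geno, marker_id, phenotype = NULL,
                                  alpha = 0.05) {
  y <- phenotype %||% geno$phenotype
  g <- geno$G[, marker_id]
  ok <- !is.na(g) & !is.na(y)
  g <- factor(g[ok], levels = sort(unique(g[ok]))); y <- y[ok]
  fit <- stats::aov(y ~ g)
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  levels_g <- levels(g)
  ## compact letter display: greedily merge classes not separated by the HSD
  sep <- matrix(FALSE, length(levels_g), length(levels_g),
                dimnames = list(levels_g, levels_g))
  for (cmp in rownames(hsd)) {
    ab <- strsplit(cmp, "-", fixed = TRUE)[[1]]
    if (hsd[cmp, "p adj"] < alpha) sep[ab[1], ab[2]] <- sep[ab[2], ab[1]] <- TRUE
  }
  groups <- rep("", length(levels_g)); names(groups) <- levels_g
  letter <- 0L
  for (a in levels_g) {
    if (groups[a] != "") next
    letter <- letter + 1L
    members <- levels_g[!sep[a, ] | levels_g == a]
    members <- members[vapply(members, function(m)
      all(!sep[m, members[members != m]]), TRUE)]
    groups[members] <- paste0(groups[members], letters[letter])
  }
  data.frame(dosage = as.numeric(levels_g),
             n = as.integer(table(g)),
             mean = as.numeric(tapply(y, g, mean)),
             se = as.numeric(tapply(y, g, function(v) stats::sd(v) / sqrt(length(v)))),
             group = unname(groups),
             stringsAsFactors = FALSE)
}
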