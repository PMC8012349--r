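#' Panelist-adjusted sample means for each sensory attribute
#'
#' Consumers differ systematically in how they use rating scales, and each
#' sample is rated only by the consumers of its session. For every attribute
#' a mixed linear model `score ~ 0 + sample + (1 | panelist)` is fitted by
#' REML and the fixed-effect estimates are returned as the adjusted
#' (least-squares) sample means. With a single panelist, or when
#' `method = "raw"`, plain per-sample means are returned (with one rater per
#' sample the two coincide; the raw path is also the cheap option inside
#' large simulation studies, where per-sample means over ~100 raters make the
#' panelist adjustment negligible).
#'
#' Samples rated by a single panelist are flagged and their standard error
#' inflated (it cannot separate panelist offset from residual noise).
#'
#' @param ratings a [panel_ratings()] table.
#' @param method `"mixed"` (REML) or `"raw"` (per-sample means).
#' @return data.frame of class `sensory_means`: one row per sample x
#'   attribute with `mean`, `se`, `n_raters`, `single_rater` flag. Per-attribute
#'   panelist variance components are attached as attribute
#'   `"variance_components"`.
#' @export
fit_panelist_adjusted_means <- function(ratings, method = c("mixed", "raw")) {
  stopifnot(inherits(ratings, "panel_ratings"))
  method <- match.arg(method)
  df <- as.data.frame(ratings)
  out <- list(); vc <- list()
  for (attr_name in intersect(ALL_ATTRIBUTES, unique(df$attribute))) {
    sub <- df[df$attribute == attr_name, ]
    n_raters <- tapply(sub$panelist_id, sub$sample_id,
                       function(x) length(unique(x)))
    raw_mean <- tapply(sub$score, sub$sample_id, mean)
    raw_se <- tapply(sub$score, sub$sample_id,
                     function(x) stats::sd(x) / sqrt(length(x)))
    if (method == "mixed" && length(unique(sub$panelist_id)) >= 2) {
      sub$sample_id <- factor(sub$sample_id)
      sub$panelist_id <- factor(sub$panelist_id)
      fit <- lme4::lmer(score ~ 0 + sample_id + (1 | panelist_id), data = sub,
                        REML = TRUE,
                        control = lme4::lmerControl(calc.derivs = FALSE))
      est <- lme4::fixef(fit)
      names(est) <- sub("^sample_id", "", names(est))
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
      names(se) <- names(est)
      v <- as.data.frame(lme4::VarCorr(fit))
      vc[[attr_name]] <- data.frame(
        attribute = attr_name,
        panelist_var = v$vcov[v$grp == "panelist_id"],
        residual_var = v$vcov[v$grp == "Residual"]
      )
      ids <- names(raw_mean)
      mean_est <- est[ids]; se_est <- se[ids]
    } else {
      ids <- names(raw_mean)
      mean_est <- raw_mean; se_est <- raw_se
      vc[[attr_name]] <- data.frame(attribute = attr_name,
                                    panelist_var = NA_real_,
                                    residual_var = NA_real_)
    }
    single <- n_raters[ids] < 2
    se_est[single] <- ifelse(is.na(se_est[single]) | se_est[single] == 0,
                             Inf, se_est[single] * sqrt(2))
    out[[attr_name]] <- data.frame(sample_id = ids, attribute = attr_name,
                                   mean = as.numeric(mean_est),
                                   se = as.numeric(se_est),
                                   n_raters = as.integer(n_raters[ids]),
                                   single_rater = as.logical(single),
                                   row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "variance_components") <- do.call(rbind, vc)
  class(res) <- c("sensory_means", class(res))
  res
}

#' Reshape sensory means to one row per sample
#'
#' @param means a `sensory_means` table.
#' @return data.frame with `sample_id` and one column per attribute.
#' @export
sensory_means_wide <- function(means) {
  wide <- stats::reshape(as.data.frame(means)[c("sample_id", "attribute", "mean")],
                         idvar = "sample_id", timevar = "attribute",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

# Rank-based partial correlation of x and y given z:
# r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))
partial_cor <- function(r_xy, r_xz, r_yz) {
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Correlation structure among sensory attributes
#'
#' Spearman rank correlations between all attribute pairs, with two-sided
#' p-values, plus -- because perceived sweetness is correlated with every
#' other attribute and confounds hedonic interpretation -- partial
#' correlations of each attribute pair controlling for sweetness, computed on
#' the rank-transformed data so they remain Spearman-consistent.
#'
#' @param means a `sensory_means` table (or a wide data.frame of sample
#'   attribute means).
#' @param control attribute controlled for in the partial correlations.
#' @return data.frame with one row per unordered attribute pair: `rho`, `p`,
#'   and `partial_rho` (NA for pairs involving the control attribute).
#' @export
attribute_correlations <- function(means, control = "sweetness") {
  wide <- if (inherits(means, "sensory_means")) sensory_means_wide(means) else means
  attrs <- setdiff(names(wide), "sample_id")
  x <- as.matrix(wide[attrs])
  if (nrow(x) < 4) stop("need at least 4 samples for attribute correlations")
  const <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  ranks <- apply(x, 2, rank)
  rho <- suppressWarnings(stats::cor(x, method = "spearman",
                                     use = "pairwise.complete.obs"))
  rho[const, ] <- NA; rho[, const] <- NA; diag(rho) <- ifelse(const, NA, 1)
  rr <- suppressWarnings(stats::cor(ranks))
  pairs <- utils::combn(attrs, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    p <- if (is.na(rho[a, b])) NA_real_ else {
      suppressWarnings(stats::cor.test(x[, a], x[, b], method = "spearman",
                                       exact = FALSE)$p.value)
    }
    pr <- if (control %in% attrs && !(control %in% c(a, b)) &&
              !anyNA(c(rr[a, b], rr[a, control], rr[b, control]))) {
      partial_cor(rr[a, b], rr[a, control], rr[b, control])
    } else NA_real_
    data.frame(attr1 = a, attr2 = b, rho = rho[a, b], p = p,
               partial_rho = pr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "rho_matrix") <- rho
  attr(out, "control") <- control
  out
}

#' Linear temperature trends of sensory or chemical responses
#'
#' Regresses a response (e.g. liking, sweetness, total sugars, total
#' volatiles) on the pre-harvest mean soil temperature, per genotype and
#' pooled.
#'
#' @param data data.frame with columns `genotype`, `temperature`, and the
#'   response.
#' @param response name of the response column.
#' @return data.frame with one row per genotype plus a `"pooled"` row:
#'   `slope`, `intercept`, `n`.
#' @export
temperature_trend <- function(data, response) {
  stopifnot(all(c("genotype", "temperature", response) %in% names(data)))
  fit_one <- function(d, label) {
    if (length(unique(d$temperature)) < 2) {
      stop(sprintf("genotype %s: slope undefined with a single temperature value", label))
    }
    co <- stats::coef(stats::lm(d[[response]] ~ d$temperature))
    data.frame(genotype = label, intercept = co[[1]], slope = co[[2]],
               n = nrow(d), stringsAsFactors = FALSE)
  }
  per <- lapply(split(data, data$genotype), function(d)
    fit_one(d, as.character(d$genotype[1])))
  out <- rbind(do.call(rbind, per), fit_one(data, "pooled"))
  rownames(out) <- NULL
  out
}
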