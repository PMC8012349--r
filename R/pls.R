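#' Fit a univariate-response PLS model by NIPALS
#'
#' Classical NIPALS partial least squares for a single response: per
#' component the X-weight vector is the normalized covariance direction
#' `w = X'y / ||X'y||`, scores `t = X w`, y-loading `q = y't / t't`,
#' X-loadings `p = X't / t't`, followed by deflation of both X and y.
#' Predictors are centered internally (they arrive autoscaled from upstream);
#' the response is centered and, by default, scaled to unit variance. The
#' per-component explained response sum of squares is `SS_a = q_a^2 t_a' t_a`,
#' the quantity that weights the VIP formula.
#'
#' @param X numeric predictor matrix (complete; no missing values).
#' @param y numeric response vector.
#' @param ncomp number of latent components.
#' @param scale_y standardize the response before fitting?
#' @return object of class `pls_model`: `weights` (p x A), `scores` (n x A),
#'   `loadings` (p x A), `y_loadings` (A), `ss_comp` (A), `coefficients`
#'   (original-scale regression vector), `fitted`, `r_squared`, `ncomp`,
#'   centering/scaling info.
#' @export
fit_pls_nipals <- function(X, y, ncomp = 3, scale_y = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) stop("PLS input must be complete; impute upstream")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  rk <- qr(scale(X, scale = FALSE))$rank
  if (ncomp > rk) {
    stop(sprintf("ncomp = %d exceeds the rank of centered X (%d)", ncomp, rk))
  }
  if (any(col_sd(X) == 0)) stop("zero-variance predictor column; drop upstream")

  x_center <- colMeans(X)
  y_center <- mean(y)
  y_scale <- if (scale_y) stats::sd(y) else 1
  if (y_scale == 0) stop("response is constant")
  Xc <- sweep(X, 2, x_center)
  yc <- (y - y_center) / y_scale

  p <- ncol(X); n <- nrow(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp); ss <- numeric(ncomp)
  Xd <- Xc; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    w <- w / sqrt(sum(w^2))
    tt <- Xd %*% w
    t2 <- sum(tt^2)
    qa <- sum(yd * tt) / t2
    pa <- crossprod(Xd, tt) / t2
    Xd <- Xd - tt %*% t(pa)
    yd <- yd - qa * tt
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- tt; q[a] <- qa
    ss[a] <- qa^2 * t2
  }
  ## regression vector on the centered scale: B = W (P'W)^-1 q
  B <- W %*% solve(crossprod(P, W), q)
  fitted_c <- as.numeric(Xc %*% B)
  fitted <- fitted_c * y_scale + y_center
  r2 <- 1 - sum((yc - fitted_c)^2) / sum(yc^2)
  dimnames(W) <- list(colnames(X), NULL)
  dimnames(P) <- list(colnames(X), NULL)
  structure(list(weights = W, scores = Tm, loadings = P, y_loadings = q,
                 ss_comp = ss, coefficients = as.numeric(B) * y_scale,
                 fitted = fitted, r_squared = r2, ncomp = ncomp,
                 x_center = x_center, y_center = y_center, y_scale = y_scale,
                 variables = colnames(X)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components over %d predictors; training R2 = %.4f\n",
              x$ncomp, length(x$variables), x$r_squared))
  invisible(x)
}

#' Predict from a fitted NIPALS PLS model
#'
#' @param object a `pls_model`.
#' @param newdata predictor matrix with the training columns.
#' @param ... unused.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$variables, drop = FALSE]
  as.numeric(sweep(newdata, 2, object$x_center) %*%
               (object$coefficients / object$y_scale)) * object$y_scale +
    object$y_center
}

#' Variable importance in projection (VIP)
#'
#' Wold's VIP: with `p` predictors, A components, per-component explained
#' response sum of squares `SS_a` and normalized weights `w_a`,
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a}.}
#' The scores satisfy the identity \eqn{\sum_j VIP_j^2 = p}.
#'
#' @param model a `pls_model`.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  W <- model$weights
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  p <- nrow(W)
  vip2 <- p * as.numeric(wn2 %*% model$ss_comp) / sum(model$ss_comp)
  stats::setNames(sqrt(vip2), model$variables)
}

# Independent reference PLS used in tests: the weight vector of each
# component is the dominant eigenvector of X' y y' X, with the same
# deflation. Exported for use as a cross-check oracle, not a user entry point.
#' Eigen-decomposition reference PLS (cross-check implementation)
#'
#' Same model as [fit_pls_nipals()] computed through an eigen-decomposition
#' of \eqn{X' y y' X} per component. Used to cross-validate the NIPALS path.
#' @inheritParams fit_pls_nipals
#' @return list with `fitted` and `weights`.
#' @export
fit_pls_eigen <- function(X, y, ncomp = 3, scale_y = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  x_center <- colMeans(X)
  y_center <- mean(y)
  y_scale <- if (scale_y) stats::sd(y) else 1
  Xd <- sweep(X, 2, x_center); yd <- (y - y_center) / y_scale
  p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    M <- tcrossprod(crossprod(Xd, yd))  # X'y y'X
    e <- eigen(M, symmetric = TRUE)
    w <- e$vectors[, 1]
    if (sum(w * crossprod(Xd, yd)) < 0) w <- -w  # fix sign to the NIPALS convention
    tt <- Xd %*% w
    t2 <- sum(tt^2)
    qa <- sum(yd * tt) / t2
    pa <- crossprod(Xd, tt) / t2
    Xd <- Xd - tt %*% t(pa)
    yd <- yd - qa * tt
    W[, a] <- w; P[, a] <- pa; q[a] <- qa
  }
  B <- W %*% solve(crossprod(P, W), q)
  fitted <- as.numeric(sweep(X, 2, x_center) %*% B) * y_scale + y_center
  list(fitted = fitted, weights = W)
}
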