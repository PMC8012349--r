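# Shared fixtures and independent oracles used across the suite.

# A small, fast study configuration used wherever the full 148-sample design
# is not the point of the test.
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    n_samples = 24, n_panelists_per_session = 8, samples_per_session = 4,
    n_volatiles = 12, n_core_volatiles = 9, n_latent_pathways = 1,
    n_enhancers = 2, n_markers = 10, n_geno_samples = 60, seed = seed
  ), list(...))
  do.call(sim_config, args)
}

# Hand step-up Benjamini-Hochberg oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Profiled REML log-likelihood for y = X beta + Z u + e with a single
# random-intercept variance ratio lambda = sigma_u^2 / sigma_e^2.
reml_loglik <- function(y, X, Z, lambda) {
  n <- length(y); p <- ncol(X)
  V <- diag(n) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  q <- as.numeric(crossprod(r, Vi %*% r))
  -0.5 * (determinant(V)$modulus + determinant(XtVi %*% X)$modulus +
            (n - p) * log(q))
}

# Build a chem_matrix directly from an abundance matrix and period labels.
make_chem <- function(ab, periods, classes = NULL) {
  ab <- as.matrix(ab)
  if (is.null(colnames(ab))) colnames(ab) <- sprintf("C%02d", seq_len(ncol(ab)))
  chem_matrix(ab,
              data.frame(sample_id = sprintf("S%03d", seq_len(nrow(ab))),
                         period = periods, stringsAsFactors = FALSE),
              data.frame(compound_id = colnames(ab),
                         class = classes %||% rep("ester", ncol(ab)),
                         stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
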