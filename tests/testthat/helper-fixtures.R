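# Fixtures are built programmatically; nothing is read from disk except what
# the tests themselves write to tempfiles.

fixture_cohort <- function(n_subjects = 9, seed = 42, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects, seed = seed, ...))
}

fixture_csv <- function(data, path = tempfile(fileext = ".csv")) {
  write_cohort(data, path)
  path
}

# Rank-1 noiseless records: every measure column equal to the same vector.
fixture_rank1 <- function(n = 20, seed = 3) {
  v <- withr::with_seed(seed, rnorm(n))
  x <- outer(v, rep(1, 8))
  colnames(x) <- default_battery()$measure
  x
}

# Brute-force PCA oracle, independent of the implementation's
# eigen(cov(...)) route: covariance assembled by an explicit double loop,
# eigenstructure via the SVD of the centered data matrix.
oracle_pca <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  mu <- colMeans(x)
  cc <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      cc[i, j] <- sum((x[, i] - mu[i]) * (x[, j] - mu[j])) / (n - 1)
    }
  }
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  list(cov = cc, values = sv$d^2 / (n - 1), vectors = sv$v)
}

# Flip the columns of `m` so each correlates positively with `ref`'s.
align_columns <- function(m, ref) {
  for (j in seq_len(ncol(m))) {
    if (sum(m[, j] * ref[, j]) < 0) m[, j] <- -m[, j]
  }
  m
}

# One-component PCA test EV under the same split/scaling protocol as
# evaluate_cv (scaler fitted on training rows).
pca_cv_test_ev <- function(x, test_sets) {
  vapply(test_sets, function(te) {
    tr <- setdiff(seq_len(nrow(x)), te)
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, sd)
    z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    fit <- fit_pca(z[tr, , drop = FALSE], 1)
    zc <- sweep(z[te, , drop = FALSE], 2, fit$center)
    xhat <- sweep(zc %*% fit$loadings %*% t(fit$loadings), 2, fit$center, "+")
    explained_variance(z[te, , drop = FALSE], xhat)
  }, numeric(1))
}
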