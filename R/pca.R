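#' Principal component analysis of a standardized battery
#'
#' Eigendecomposition of the sample covariance (n-1 denominator) of the
#' records-by-measures matrix. Because the inputs are standardized first,
#' this is correlation-matrix PCA. Components are ordered by eigenvalue;
#' per-component variance fractions are eigenvalue / trace; scores are the
#' centered data projected onto the loadings.
#'
#' Sign convention: when a direction-of-improvement vector is available
#' (from `directions` or `battery`), each loading column is flipped so its
#' inner product with the direction vector is non-negative — the first
#' component then loads positively on higher-is-better measures. Without
#' directions, the largest-magnitude loading entry is made positive.
#'
#' @param data Standardized cohort tibble or records-by-measures matrix
#'   (>= 2 rows).
#' @param n_components Number of components to retain (default 2).
#' @param battery Optional battery (orders columns and supplies directions).
#' @param directions Optional per-measure sign vector overriding the
#'   battery's.
#' @return An object of class `composcore_pca` with `loadings`
#'   (measures x components, orthonormal columns), `variance_fractions`
#'   (all eigenvalue shares), `scores`, `center`, `eigenvalues`.
#' @export
#' @examples
#' z <- generate_two_factor(two_factor_config(n_records = 200, seed = 1))
#' fit <- fit_pca(z, n_components = 2, battery = default_battery())
#' glance(fit)
fit_pca <- function(data, n_components = 2L, battery = NULL, directions = NULL) {
  x <- as_measure_matrix(data, battery)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2) abort("covariance undefined: need at least 2 records")
  if (n_components < 1 || n_components > k) {
    abort(sprintf("n_components must lie in [1, %d]", k))
  }
  if (is.null(directions) && !is.null(battery)) {
    directions <- validate_battery(battery)$direction
  }
  cc <- stats::cov(x)
  ee <- eigen(cc, symmetric = TRUE)
  eigenvalues <- pmax(ee$values, 0)
  fractions <- eigenvalues / sum(eigenvalues)
  loadings <- ee$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    s <- if (!is.null(directions)) {
      sum(loadings[, j] * directions)
    } else {
      loadings[which.max(abs(loadings[, j])), j]
    }
    if (s < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- paste0("PC", seq_len(n_components))
  center <- colMeans(x)
  scores <- sweep(x, 2, center) %*% loadings
  structure(
    list(
      loadings = loadings,
      variance_fractions = fractions,
      eigenvalues = eigenvalues,
      scores = scores,
      center = center,
      n_components = as.integer(n_components),
      n = n
    ),
    class = "composcore_pca"
  )
}

#' @export
print.composcore_pca <- function(x, ...) {
  cat(sprintf(
    "<composcore_pca> %d records, %d component(s) | PC1 %.1f%%%s\n",
    x$n, x$n_components, 100 * x$variance_fractions[1],
    if (length(x$variance_fractions) > 1) {
      sprintf(", PC2 %.1f%%", 100 * x$variance_fractions[2])
    } else ""
  ))
  invisible(x)
}

#' @describeIn fit_pca Loadings in long form (`measure`, `component`,
#'   `loading`).
#' @param x A `composcore_pca`.
#' @param ... Unused.
#' @export
tidy.composcore_pca <- function(x, ...) {
  l <- x$loadings
  tibble(
    measure = rep(rownames(l) %||% as.character(seq_len(nrow(l))), ncol(l)),
    component = rep(colnames(l), each = nrow(l)),
    loading = as.numeric(l)
  )
}

#' @describeIn fit_pca One-row summary with the leading variance fractions.
#' @export
glance.composcore_pca <- function(x, ...) {
  tibble(
    n = x$n,
    n_components = x$n_components,
    pc1_fraction = x$variance_fractions[1],
    pc2_fraction = if (length(x$variance_fractions) > 1) x$variance_fractions[2] else NA_real_
  )
}

#' First-component composite scores
#'
#' @param result A `composcore_pca` from [fit_pca()].
#' @return Numeric vector of PC1 scores, one per record (sample mean 0).
#' @export
pca_composite <- function(result) {
  if (!inherits(result, "composcore_pca")) abort("result must be a composcore_pca")
  drop(result$scores[, 1L])
}

#' First-component loadings with directions of improvement
#'
#' A publication-style loadings table: measure, PC1 load factor, and the
#' measure's direction of improvement, sorted by descending load factor.
#'
#' @param result A `composcore_pca`.
#' @param battery Battery metadata supplying the directions.
#' @return A tibble with columns `measure`, `load_factor`, `direction`.
#' @export
pca_loadings_table <- function(result, battery = default_battery()) {
  if (!inherits(result, "composcore_pca")) abort("result must be a composcore_pca")
  battery <- validate_battery(battery)
  l1 <- result$loadings[, 1L]
  out <- tibble(
    measure = rownames(result$loadings),
    load_factor = as.numeric(l1)
  )
  out <- dplyr::left_join(out, battery[c("measure", "direction")], by = "measure")
  out$direction <- ifelse(out$direction > 0, "Higher", "Lower")
  arrange(out, dplyr::desc(.data$load_factor))
}

#' Nesting stability of the first component
#'
#' Checks that PC1 from a 1-component fit equals PC1 from a 2-component fit
#' (up to sign) — the eigendecomposition nesting property that
#' distinguishes PCA from the autoencoder, whose learned axis can change
#' with the requested dimension. A (near-)tied top eigenvalue pair makes
#' the component direction ill-defined; that degeneracy is reported as a
#' flag rather than silently resolved.
#'
#' @param data Standardized cohort tibble or matrix (>= 3 rows).
#' @param battery Optional battery.
#' @param tol Discrepancy tolerance for declaring stability.
#' @param gap_tol Relative eigen-gap below which the top pair is flagged
#'   degenerate.
#' @return A list with `stable` (logical; `NA` when degenerate),
#'   `degenerate`, `max_discrepancy`, and `relative_gap`.
#' @export
stability_check <- function(data, battery = NULL, tol = 1e-10, gap_tol = 1e-6) {
  x <- as_measure_matrix(data, battery)
  if (nrow(x) < 3) abort("stability check needs at least 3 records")
  fit1 <- fit_pca(x, n_components = 1L)
  fit2 <- fit_pca(x, n_components = 2L)
  a <- fit1$loadings[, 1L]
  b <- fit2$loadings[, 1L]
  if (sum(a * b) < 0) b <- -b
  disc <- max(abs(a - b))
  ev <- fit2$eigenvalues
  gap <- (ev[1] - ev[2]) / max(ev[1], .Machine$double.eps)
  degenerate <- gap < gap_tol
  list(
    stable = if (degenerate) NA else disc < tol,
    degenerate = degenerate,
    max_discrepancy = disc,
    relative_gap = gap
  )
}
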