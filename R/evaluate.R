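#' Explained variance of a reconstruction
#'
#' The model-quality metric: per measure, the residual variance is
#' `s2_k = sum((x_k - x'_k)^2) / (n - 1)`; the explained-variance fraction is
#' `1 - mean_k(s2_k) / mean_k(var_k(x))`. On data standardized with its own
#' statistics the denominator is 1 and the fraction is one minus the mean
#' residual variance. Always `<= 1`, with equality iff the reconstruction is
#' perfect; it can be negative for reconstructions worse than the column
#' means.
#'
#' @param x Records-by-measures matrix (or data frame) of observed values.
#' @param x_reconstructed Reconstruction of the same shape.
#' @return The explained-variance fraction (scalar).
#' @export
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' explained_variance(x, x)  # 1
explained_variance <- function(x, x_reconstructed) {
  x <- as_measure_matrix(x)
  xr <- as_measure_matrix(x_reconstructed)
  if (!all(dim(x) == dim(xr))) abort("x and x_reconstructed must have equal shapes")
  n <- nrow(x)
  if (n < 2) abort("variance undefined: need at least 2 records")
  resid_var <- colSums((x - xr)^2) / (n - 1)
  total_var <- apply(x, 2, var)
  1 - mean(resid_var) / mean(total_var)
}

#' Mean residual variance of a reconstruction
#'
#' `mean_k( sum((x_k - x'_k)^2) / (n - 1) )` — the reconstruction-error
#' companion to [explained_variance()]. Non-negative by construction.
#'
#' @inheritParams explained_variance
#' @return The mean per-measure residual variance (scalar).
#' @export
reconstruction_error <- function(x, x_reconstructed) {
  x <- as_measure_matrix(x)
  xr <- as_measure_matrix(x_reconstructed)
  if (!all(dim(x) == dim(xr))) abort("x and x_reconstructed must have equal shapes")
  n <- nrow(x)
  if (n < 2) abort("variance undefined: need at least 2 records")
  mean(colSums((x - xr)^2) / (n - 1))
}

#' Evaluate an architecture under repeated 90/10 splits
#'
#' Runs `n_runs` train/test evaluations with mutually disjoint test sets:
#' a seeded permutation of the records is drawn and the first
#' `n_runs * ceiling(test_frac * n)` positions are cut into consecutive,
#' non-overlapping test sets. Within each run the scaler is (by default)
#' fitted on the training records only, both partitions are standardized
#' with it, the model is trained on the training records, and the test
#' explained variance and residual variance are reported.
#'
#' @param data Cohort tibble or records-by-measures matrix. Raw or already
#'   standardized values are both acceptable: each run re-standardizes with
#'   statistics of its own training rows (standardization is
#'   affine-invariant, so a prior global scaling does not leak).
#' @param arch An [ae_architecture()].
#' @param battery Optional battery restricting/ordering the measure columns.
#' @param n_runs Number of evaluation runs (default 2).
#' @param test_frac Test fraction per run (default 0.1; test size is
#'   `ceiling(test_frac * n)`).
#' @param scaler_policy `"train"` (leakage-safe, default) fits the scaler on
#'   each run's training rows; `"all"` fits it once on all rows.
#' @param split_by `"record"` (default) splits at the record level so a
#'   subject's two conditions may straddle train/test; `"subject"` keeps
#'   each subject's records together (requires a `subject` column).
#' @param seed Integer seed; run r trains with seed `seed + r`.
#' @inheritParams train_ae
#' @return An object of class `ae_evaluation`: per-run tibble plus mean
#'   test explained variance and mean reconstruction error.
#' @export
evaluate_cv <- function(data, arch = ae_architecture(), battery = NULL,
                        n_runs = 2L, test_frac = 0.1,
                        scaler_policy = c("train", "all"),
                        split_by = c("record", "subject"),
                        learning_rate = 0.01, epochs = 2000L,
                        patience = 200L, min_delta = 1e-5, seed = 1L) {
  scaler_policy <- match.arg(scaler_policy)
  split_by <- match.arg(split_by)
  x <- as_measure_matrix(data, battery)
  n <- nrow(x)
  if (n < 4) abort("need at least 4 records to form a train/test split")

  if (split_by == "subject") {
    if (!is.data.frame(data) || is.null(data$subject)) {
      abort("split_by = \"subject\" requires a data frame with a 'subject' column")
    }
    subjects <- unique(data$subject)
    ns <- length(subjects)
    ms <- ceiling(test_frac * ns)
    if (n_runs * ms > ns - 1) {
      abort("too few subjects for disjoint test sets of this size")
    }
    perm <- withr::with_seed(seed, sample(subjects))
    test_sets <- lapply(seq_len(n_runs), function(r) {
      which(data$subject %in% perm[((r - 1) * ms + 1):(r * ms)])
    })
  } else {
    m <- ceiling(test_frac * n)
    if (n_runs * m > n - 2) {
      abort("too few records for disjoint test sets of this size")
    }
    perm <- withr::with_seed(seed, sample.int(n))
    test_sets <- lapply(seq_len(n_runs), function(r) {
      sort(perm[((r - 1) * m + 1):(r * m)])
    })
  }

  runs <- purrr::map_dfr(seq_len(n_runs), function(r) {
    te <- test_sets[[r]]
    tr <- setdiff(seq_len(n), te)
    fit_rows <- if (scaler_policy == "train") tr else seq_len(n)
    mu <- colMeans(x[fit_rows, , drop = FALSE])
    sdev <- apply(x[fit_rows, , drop = FALSE], 2, sd)
    bad <- which(!(is.finite(sdev) & sdev > 0))
    if (length(bad) > 0) {
      abort(sprintf(
        "degenerate scale: measure '%s' has zero variance in run %d's scaling rows",
        colnames(x)[bad[1]], r
      ))
    }
    z <- sweep(sweep(x, 2, mu, "-"), 2, sdev, "/")
    model <- train_ae(
      z[tr, , drop = FALSE], arch = arch, learning_rate = learning_rate,
      epochs = epochs, patience = patience, min_delta = min_delta,
      seed = seed + r
    )
    z_tr <- z[tr, , drop = FALSE]
    z_te <- z[te, , drop = FALSE]
    tibble(
      run = r,
      n_train = length(tr),
      n_test = length(te),
      ev_train = explained_variance(z_tr, reconstruct(model, z_tr)),
      ev_test = explained_variance(z_te, reconstruct(model, z_te)),
      recon_error_test = reconstruction_error(z_te, reconstruct(model, z_te)),
      epochs_run = model$epochs_run,
      seed = seed + r
    )
  })

  structure(
    list(
      runs = runs,
      mean_ev_test = mean(runs$ev_test),
      mean_ev_train = mean(runs$ev_train),
      mean_recon_error = mean(runs$recon_error_test),
      test_sets = test_sets,
      architecture = arch,
      scaler_policy = scaler_policy,
      split_by = split_by,
      seed = as.integer(seed)
    ),
    class = "ae_evaluation"
  )
}

#' @export
print.ae_evaluation <- function(x, ...) {
  cat(sprintf(
    "<ae_evaluation> %d runs | mean test EV %.4f | mean reconstruction error %.4f\n",
    nrow(x$runs), x$mean_ev_test, x$mean_recon_error
  ))
  print(x$runs)
  invisible(x)
}

#' @describeIn evaluate_cv Per-run results as a tibble.
#' @param x An `ae_evaluation`.
#' @param ... Unused.
#' @export
tidy.ae_evaluation <- function(x, ...) x$runs

#' @describeIn evaluate_cv One-row summary across runs.
#' @export
glance.ae_evaluation <- function(x, ...) {
  tibble(
    n_runs = nrow(x$runs),
    mean_ev_test = x$mean_ev_test,
    mean_ev_train = x$mean_ev_train,
    mean_recon_error = x$mean_recon_error,
    hidden = x$architecture$hidden,
    activation = x$architecture$activation,
    seed = x$seed
  )
}

#' Hyper-parameter grid search over activations and hidden widths
#'
#' Evaluates every (activation, width) pair — by default the 4 x 5 = 20
#' configurations relu/tanh/sigmoid/linear x 10/12/16/24/32 — under
#' [evaluate_cv()] with a shared seed, and returns the configuration
#' maximizing the mean test explained variance. Exact ties go to the first
#' configuration in (activation-list, width-list) order.
#'
#' @inheritParams evaluate_cv
#' @param activations Character vector of hidden activations to search.
#' @param widths Integer vector of hidden widths to search.
#' @param dropout Dropout rate shared by all searched configurations.
#' @return An object of class `ae_grid`: the full results `table`, the
#'   winning `best_architecture`, and its `best_evaluation`.
#' @export
grid_search <- function(data, battery = NULL,
                        activations = c("relu", "tanh", "sigmoid", "linear"),
                        widths = c(10L, 12L, 16L, 24L, 32L),
                        dropout = 0.4, n_runs = 2L, test_frac = 0.1,
                        scaler_policy = c("train", "all"),
                        learning_rate = 0.01, epochs = 2000L,
                        patience = 200L, min_delta = 1e-5, seed = 1L) {
  scaler_policy <- match.arg(scaler_policy)
  grid <- tidyr::expand_grid(activation = activations, hidden = as.integer(widths))
  evals <- purrr::pmap(grid, function(activation, hidden) {
    evaluate_cv(
      data, arch = ae_architecture(hidden = hidden, activation = activation,
                                   dropout = dropout),
      battery = battery, n_runs = n_runs, test_frac = test_frac,
      scaler_policy = scaler_policy, learning_rate = learning_rate,
      epochs = epochs, patience = patience, min_delta = min_delta, seed = seed
    )
  })
  table <- dplyr::bind_cols(
    grid,
    purrr::map_dfr(evals, function(e) {
      tibble(
        mean_ev_test = e$mean_ev_test,
        mean_ev_train = e$mean_ev_train,
        mean_recon_error = e$mean_recon_error
      )
    })
  )
  best_idx <- which.max(table$mean_ev_test)  # first max wins ties
  structure(
    list(
      table = table,
      best_architecture = ae_architecture(
        hidden = table$hidden[best_idx],
        activation = table$activation[best_idx],
        dropout = dropout
      ),
      best_evaluation = evals[[best_idx]],
      seed = as.integer(seed)
    ),
    class = "ae_grid"
  )
}

#' @export
print.ae_grid <- function(x, ...) {
  cat(sprintf("<ae_grid> %d configurations searched\n", nrow(x$table)))
  cat("best: ")
  print(x$best_architecture)
  invisible(x)
}

#' @describeIn grid_search Full search table.
#' @param x An `ae_grid`.
#' @param ... Unused.
#' @export
tidy.ae_grid <- function(x, ...) x$table

#' @describeIn grid_search Winning configuration as one row.
#' @export
glance.ae_grid <- function(x, ...) {
  best <- which.max(x$table$mean_ev_test)
  x$table[best, ]
}
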