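test_that("architecture validates its fields", {
  a <- ae_architecture()
  expect_equal(c(a$input, a$hidden, a$bottleneck), c(8L, 24L, 1L))
  expect_equal(a$activation, "relu")
  expect_equal(a$dropout, 0.4)
  expect_error(ae_architecture(dropout = 1), "dropout")
  expect_error(ae_architecture(hidden = 0), "hidden")
  expect_error(ae_architecture(activation = "gelu"))
})

test_that("training reduces its own objective and records a loss trace", {
  coh <- fixture_cohort(n_subjects = 9, seed = 2)
  z <- standardize(coh, fit_scaler(coh))
  fit <- train_ae(z, epochs = 400, seed = 1)
  expect_lt(fit$loss_final, fit$loss_initial)
  expect_equal(length(fit$loss_trace), fit$epochs_run)
  expect_true(all(is.finite(fit$loss_trace)))
})

test_that("training is deterministic given the seed", {
  coh <- fixture_cohort(n_subjects = 6, seed = 3)
  z <- standardize(coh, fit_scaler(coh))
  f1 <- train_ae(z, epochs = 120, seed = 7)
  f2 <- train_ae(z, epochs = 120, seed = 7)
  expect_identical(f1$parameters, f2$parameters)
  expect_identical(f1$loss_trace, f2$loss_trace)
  f3 <- train_ae(z, epochs = 120, seed = 8)
  expect_false(identical(f1$parameters, f3$parameters))
})

test_that("a linear width-1 bottleneck represents rank-1 data exactly", {
  x <- scale(fixture_rank1(n = 20, seed = 3))
  fit <- train_ae(x, ae_architecture(activation = "linear", dropout = 0),
                  epochs = 2000, seed = 1)
  expect_lt(fit$loss_final, 1e-3)
  # PCA oracle: rank-1 data is perfectly reconstructed by one component
  p <- fit_pca(unclass(x), 1)
  expect_equal(p$variance_fractions[1], 1, tolerance = 1e-9)
  expect_lt(max(abs(reconstruct(fit, x) - x)), 0.03)
})

test_that("encoding is deterministic and respects the battery contract", {
  coh <- fixture_cohort(n_subjects = 6, seed = 5)
  z <- standardize(coh, fit_scaler(coh))
  fit <- train_ae(z, epochs = 150, seed = 2)
  s1 <- encode(fit, z)
  expect_identical(s1, encode(fit, z))
  expect_length(s1, nrow(z))

  # identical rows get identical scores
  zm <- as.matrix(z[, default_battery()$measure])
  dup <- rbind(zm, zm[1, , drop = FALSE])
  sdup <- encode(fit, dup)
  expect_equal(sdup[nrow(dup)], sdup[1])

  expect_error(encode(fit, zm[, 1:5]), "battery mismatch|missing measure")
})

test_that("a trained bottleneck separates two clusters", {
  xc <- rbind(matrix(1, 8, 8), matrix(-1, 8, 8)) +
    matrix(withr::with_seed(4, rnorm(128, sd = 0.05)), 16, 8)
  colnames(xc) <- default_battery()$measure
  fit <- train_ae(xc, ae_architecture(dropout = 0), epochs = 500, seed = 5)
  s <- encode(fit, xc)
  mid <- (max(s) + min(s)) / 2
  side_a <- s[1:8] > mid
  side_b <- s[9:16] > mid
  expect_true(all(side_a) && !any(side_b) || !any(side_a) && all(side_b))
})

test_that("reconstruct matches shapes and composes with encode/decode", {
  coh <- fixture_cohort(n_subjects = 9, seed = 6)
  z <- standardize(coh, fit_scaler(coh))
  fit <- train_ae(z, epochs = 100, seed = 3)
  xhat <- reconstruct(fit, z)
  expect_equal(dim(xhat), c(18L, 8L))
  expect_equal(decode(fit, encode(fit, z)), xhat, tolerance = 1e-12)
})

test_that("divergent training raises a divergence error", {
  coh <- fixture_cohort(n_subjects = 6, seed = 8)
  z <- standardize(coh, fit_scaler(coh))
  expect_error(
    train_ae(z, ae_architecture(activation = "linear", dropout = 0),
             learning_rate = 1e80, epochs = 100, seed = 1),
    "diverged|lower learning_rate"
  )
})

test_that("explained variance follows its definition", {
  x <- matrix(withr::with_seed(1, rnorm(60)), 12, 5)
  expect_equal(explained_variance(x, x), 1)
  xbar <- matrix(colMeans(x), 12, 5, byrow = TRUE)
  expect_equal(explained_variance(x, xbar), 0, tolerance = 1e-12)

  # one column perfect, the other with residual variance 0.5 -> EV 0.75
  x2 <- cbind(a = c(-1, 0, 1), b = c(-1, 0, 1))
  xr <- x2
  xr[1, "b"] <- xr[1, "b"] + 1  # sum(e^2)/(n-1) = 0.5
  expect_equal(explained_variance(x2, xr), 0.75)
  expect_equal(reconstruction_error(x2, xr), 0.25)

  expect_error(explained_variance(x[1, , drop = FALSE], x[1, , drop = FALSE]),
               "at least 2")
  expect_error(explained_variance(x, x[, 1:3]), "equal shapes")
})

test_that("explained variance is bounded above by 1, error below by 0", {
  for (s in 1:20) {
    x <- matrix(withr::with_seed(s, rnorm(40)), 8, 5)
    xr <- matrix(withr::with_seed(100 + s, rnorm(40)), 8, 5)
    expect_lte(explained_variance(x, xr), 1)
    expect_gte(reconstruction_error(x, xr), 0)
  }
})

test_that("cross-validation forms disjoint ceiling-10% test sets", {
  coh <- fixture_cohort(n_subjects = 9, seed = 4)
  cv <- evaluate_cv(coh, arch = ae_architecture(hidden = 10),
                    epochs = 30, seed = 2)
  expect_equal(cv$runs$n_test, c(2L, 2L))
  expect_equal(cv$runs$n_train, c(16L, 16L))
  expect_length(intersect(cv$test_sets[[1]], cv$test_sets[[2]]), 0)
  expect_error(evaluate_cv(coh[1:3, ], epochs = 5), "at least 4")
})

test_that("cross-validation is seed-deterministic", {
  coh <- fixture_cohort(n_subjects = 8, seed = 4)
  cv1 <- evaluate_cv(coh, arch = ae_architecture(hidden = 10), epochs = 40, seed = 5)
  cv2 <- evaluate_cv(coh, arch = ae_architecture(hidden = 10), epochs = 40, seed = 5)
  expect_identical(cv1$runs, cv2$runs)
})

test_that("subject-level splits keep a subject's records together", {
  coh <- fixture_cohort(n_subjects = 12, seed = 4)
  cv <- evaluate_cv(coh, arch = ae_architecture(hidden = 10), epochs = 20,
                    split_by = "subject", seed = 2)
  for (te in cv$test_sets) {
    subj <- unique(coh$subject[te])
    expect_true(all(which(coh$subject %in% subj) %in% te))
  }
})

test_that("near-rank-1 data is almost fully explained out of sample", {
  x <- fixture_rank1(n = 20, seed = 3)
  cv <- evaluate_cv(x, arch = ae_architecture(dropout = 0), epochs = 2000, seed = 2)
  expect_gt(cv$mean_ev_test, 0.95)
})

test_that("grid search enumerates the full activation-by-width grid", {
  coh <- fixture_cohort(n_subjects = 6, seed = 10)
  gs <- grid_search(coh, epochs = 3, patience = Inf, seed = 1)
  expect_equal(nrow(gs$table), 20L)
  expect_equal(nrow(dplyr::distinct(gs$table, activation, hidden)), 20L)
  expect_setequal(unique(gs$table$activation), c("relu", "tanh", "sigmoid", "linear"))
  expect_setequal(unique(gs$table$hidden), c(10L, 12L, 16L, 24L, 32L))
})

test_that("a singleton grid returns its only configuration as winner", {
  coh <- fixture_cohort(n_subjects = 6, seed = 10)
  gs <- grid_search(coh, activations = "tanh", widths = 12, epochs = 10, seed = 1)
  expect_equal(nrow(gs$table), 1L)
  expect_equal(gs$best_architecture$activation, "tanh")
  expect_equal(gs$best_architecture$hidden, 12L)
})

test_that("grid search wins on rank-1 data with near-perfect test EV", {
  x <- fixture_rank1(n = 20, seed = 3)
  gs <- grid_search(x, dropout = 0, widths = c(10L, 24L), epochs = 1500, seed = 4)
  expect_gt(glance(gs)$mean_ev_test, 0.95)
})
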