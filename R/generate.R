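#' Published per-condition marginal moments of the battery
#'
#' Per-measure, per-condition means and standard deviations of the eight raw
#' outcome measures under the mechanical-knee (MK) and
#' microprocessor-controlled-knee (MCK) conditions, used to calibrate the
#' synthetic cohort generator.
#'
#' @return A long tibble with columns `measure`, `condition`, `mean`, `sd`.
#' @export
published_marginals <- function() {
  tibble::tribble(
    ~measure,  ~condition, ~mean,  ~sd,
    "AMP",     "MK",        31.44,   7.04,
    "AMP",     "MCK",       35.67,   5.40,
    "BERG",    "MK",        37.11,   7.5,
    "BERG",    "MCK",       43.56,  13.20,
    "6MWT",    "MK",       137.48,  85.63,
    "6MWT",    "MCK",      145.43, 110.30,
    "PEQ_amb", "MK",        60.63,  18.75,
    "PEQ_amb", "MCK",       81.92,  18.74,
    "MFES",    "MK",         7.78,   1.14,
    "MFES",    "MCK",        9.33,   0.69,
    "FSST",    "MK",        17.37,   5.04,
    "FSST",    "MCK",       16.79,  11.17,
    "10MWT",   "MK",        22.27,   9.72,
    "10MWT",   "MCK",       15.3,    7.24,
    "TUG",     "MK",        27.47,  14.96,
    "TUG",     "MCK",       25.32,  14.14
  )
}

# Balanced +/-1 pattern orthogonal to the direction vector d: the loading of
# the quadratic latent component. c_k = (-1)^(k+1) d_k has sign products that
# alternate, so sum(c * d) = 0 for any +/-1 d of even length.
quad_pattern <- function(directions) {
  k <- length(directions)
  if (k %% 2 != 0) abort("quadratic pattern requires an even number of measures")
  (-1)^(seq_len(k) + 1) * directions
}

#' Configuration of the latent-factor cohort generator
#'
#' The generator draws, for subject i and condition j, a latent health factor
#' `h_ij = sqrt(tau) a_i + sqrt(1 - tau) u_ij + delta 1[j = better]` (`a_i`,
#' `u_ij` independent standard normal), then standardized measures
#' `z_ijk = rho d_k h_ij + gamma c_k (h_ij^2 - 1) + sqrt(1 - rho^2) e_ijk`,
#' where `d` is the direction-of-improvement vector, `c` a balanced sign
#' pattern orthogonal to `d` carrying the optional nonlinear (quadratic)
#' component, and `e_ijk` standard normal noise. Each `z` column is divided by
#' its exact population standard deviation `sqrt(1 + 2 gamma^2 c_k^2)` before
#' the affine map onto the configured per-condition marginals, so the
#' marginals are matched regardless of `rho`/`gamma`.
#'
#' @param n_subjects Number of subjects (each contributes one record per
#'   condition).
#' @param rho Factor loading in `[0, 1)`: share of each standardized
#'   measure's SD carried by the latent health factor.
#' @param tau Within-subject correlation in `[0, 1]` of the latent factor
#'   across the two conditions.
#' @param delta Latent condition shift (latent SD units) added under the
#'   better condition, on top of the marginal means; default 0 so the
#'   marginals fully determine the condition effect.
#' @param gamma Weight (>= 0) of the centered quadratic latent component; 0
#'   gives a purely linear factor model.
#' @param marginals Long tibble of per-measure, per-condition `mean` and
#'   `sd`; defaults to [published_marginals()].
#' @param battery Battery metadata; see [default_battery()].
#' @param conditions Ordered pair of condition labels.
#' @param better Which condition label is the better one (receives `delta`).
#' @param seed Integer seed; the generator uses a single seeded stream.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 9, rho = 0.8, tau = 0.8, delta = 0,
                          gamma = 0, marginals = published_marginals(),
                          battery = default_battery(),
                          conditions = c("MK", "MCK"), better = "MCK",
                          seed = 1L) {
  battery <- validate_battery(battery)
  if (!is_scalar_number(n_subjects) || n_subjects < 1) {
    abort("n_subjects must be a positive integer")
  }
  if (!is_scalar_number(rho) || rho < 0 || rho >= 1) {
    abort("rho must lie in [0, 1)")
  }
  if (!is_scalar_number(tau) || tau < 0 || tau > 1) {
    abort("tau must lie in [0, 1]")
  }
  if (!is_scalar_number(gamma) || gamma < 0) abort("gamma must be >= 0")
  if (!is_scalar_number(delta)) abort("delta must be a finite number")
  if (length(conditions) != 2 || anyDuplicated(conditions) > 0) {
    abort("conditions must be two distinct labels")
  }
  if (!better %in% conditions) abort("'better' must be one of the conditions")
  need <- tidyr::expand_grid(measure = battery$measure, condition = conditions)
  marginals <- dplyr::inner_join(need, as_tibble(marginals),
                                 by = c("measure", "condition"))
  if (nrow(marginals) != nrow(need)) {
    abort("marginals must cover every (measure, condition) pair")
  }
  if (!all(is.finite(marginals$mean)) || !all(is.finite(marginals$sd) & marginals$sd > 0)) {
    abort("marginal means must be finite and sds strictly positive")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), rho = rho, tau = tau,
      delta = delta, gamma = gamma, marginals = marginals,
      battery = battery, conditions = as.character(conditions),
      better = better, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic crossover cohort
#'
#' Draws a cohort from the latent-factor model described in
#' [cohort_config()]. Identical config and seed give an identical dataset.
#'
#' @param config A [cohort_config()] object.
#' @return A validated cohort tibble: `2 * n_subjects` records, one per
#'   (subject, condition).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 9, seed = 42))
#' dplyr::count(cohort, condition)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("config must be created by cohort_config()")
  }
  n <- config$n_subjects
  battery <- config$battery
  k <- nrow(battery)
  d <- battery$direction
  cpat <- quad_pattern(d)
  conds <- config$conditions
  better_idx <- match(config$better, conds)

  withr::with_seed(config$seed, {
    a <- rnorm(n)
    u <- matrix(rnorm(n * 2L), n, 2L)
    e <- array(rnorm(n * 2L * k), dim = c(n, 2L, k))
  })

  h <- sqrt(config$tau) * a + sqrt(1 - config$tau) * u
  h[, better_idx] <- h[, better_idx] + config$delta

  # population SD of each standardized-measure column (delta shifts only the
  # mean; with d_k^2 = 1 the variance is 1 + 2 gamma^2 c_k^2)
  zsd <- sqrt(1 + 2 * config$gamma^2 * cpat^2)

  rows <- vector("list", 2L)
  subj <- sprintf("S%03d", seq_len(n))
  for (j in 1:2) {
    hj <- h[, j]
    z <- config$rho * outer(hj, d) +
      config$gamma * outer(hj^2 - 1, cpat) +
      sqrt(1 - config$rho^2) * e[, j, ]
    z <- sweep(z, 2, zsd, "/")
    marg <- config$marginals[config$marginals$condition == conds[j], ]
    marg <- marg[match(battery$measure, marg$measure), ]
    x <- sweep(sweep(z, 2, marg$sd, "*"), 2, marg$mean, "+")
    colnames(x) <- battery$measure
    rows[[j]] <- dplyr::bind_cols(
      tibble(subject = subj, condition = conds[j]),
      as_tibble(as.data.frame(x, check.names = FALSE))
    )
  }
  out <- bind_rows(rows)
  out <- out[order(match(out$subject, subj), match(out$condition, conds)), ]
  validate_cohort(out, battery = battery, condition_levels = conds)
}

#' Configuration of the planted two-factor linear generator
#'
#' Builds a population covariance whose top-two eigenvalue shares equal the
#' requested targets: `x = sqrt(v1') u1 f1 + sqrt(v2') u2 f2 + sqrt(r/K) e`
#' with `f1, f2, e` independent standard normal and `(v1', v2', r)` solving
#' `v1' + r/K = v1`, `v2' + r/K = v2`, `v1' + v2' + r = 1` (`K = 8`
#' measures). Used to plant a known principal-component spectrum.
#'
#' @param n_records Number of records to draw.
#' @param v1,v2 Target eigenvalue shares of the first and second components
#'   (`v1 + v2 <= 1`; equality gives a noise-free two-factor model).
#' @param u1,u2 Optional orthonormal loading vectors over the measures;
#'   defaults are the direction vector `d / sqrt(8)` and the balanced
#'   orthogonal sign pattern `c / sqrt(8)`.
#' @param battery Battery metadata (supplies measure names and defaults for
#'   `u1`, `u2`).
#' @param seed Integer seed.
#' @return An object of class `two_factor_config` with the solved variance
#'   split (`v1p`, `v2p`, `r`).
#' @export
#' @examples
#' cfg <- two_factor_config(n_records = 100, v1 = 0.673, v2 = 0.098)
#' c(cfg$v1p, cfg$v2p, cfg$r)
two_factor_config <- function(n_records = 1000, v1 = 0.673, v2 = 0.098,
                              u1 = NULL, u2 = NULL,
                              battery = default_battery(), seed = 1L) {
  battery <- validate_battery(battery)
  k <- nrow(battery)
  if (!is_scalar_number(n_records) || n_records < 1) {
    abort("n_records must be a positive integer")
  }
  if (!is_scalar_number(v1) || !is_scalar_number(v2) || v1 < 0 || v2 < 0 ||
      v1 + v2 > 1) {
    abort("targets must satisfy v1, v2 >= 0 and v1 + v2 <= 1")
  }
  d <- battery$direction
  u1 <- u1 %||% (d / sqrt(k))
  u2 <- u2 %||% (quad_pattern(d) / sqrt(k))
  if (length(u1) != k || length(u2) != k) abort("u1 and u2 must have one entry per measure")
  if (abs(sum(u1^2) - 1) > 1e-8 || abs(sum(u2^2) - 1) > 1e-8 ||
      abs(sum(u1 * u2)) > 1e-8) {
    abort("u1 and u2 must be orthonormal")
  }
  # v1' + r/K = v1, v2' + r/K = v2, v1' + v2' + r = 1  =>  r = (1 - v1 - v2) / (1 - 2/K)
  r <- (1 - v1 - v2) / (1 - 2 / k)
  v1p <- v1 - r / k
  v2p <- v2 - r / k
  if (min(v1p, v2p, r) < -1e-12) {
    abort("infeasible spectrum targets: solved variance split has a negative component")
  }
  v1p <- max(v1p, 0); v2p <- max(v2p, 0); r <- max(r, 0)
  structure(
    list(
      n_records = as.integer(n_records), v1 = v1, v2 = v2,
      v1p = v1p, v2p = v2p, r = r, u1 = u1, u2 = u2,
      measures = battery$measure, seed = as.integer(seed)
    ),
    class = "two_factor_config"
  )
}

#' Draw records from the planted two-factor linear model
#'
#' @param config A [two_factor_config()] object.
#' @return A tibble of `n_records` rows with one column per measure
#'   (population mean 0; covariance given by [two_factor_covariance()]).
#' @export
generate_two_factor <- function(config) {
  if (!inherits(config, "two_factor_config")) {
    abort("config must be created by two_factor_config()")
  }
  n <- config$n_records
  k <- length(config$u1)
  withr::with_seed(config$seed, {
    f1 <- rnorm(n)
    f2 <- rnorm(n)
    e <- matrix(rnorm(n * k), n, k)
  })
  x <- sqrt(config$v1p) * outer(f1, config$u1) +
    sqrt(config$v2p) * outer(f2, config$u2) +
    sqrt(config$r / k) * e
  colnames(x) <- config$measures
  as_tibble(as.data.frame(x, check.names = FALSE))
}

#' Population covariance and exact eigen-shares of the two-factor model
#'
#' @param config A [two_factor_config()] object.
#' @return A list with the measures-by-measures covariance `sigma`, its
#'   `eigenvalues`, and eigenvalue `shares` (fractions of the trace).
#' @export
two_factor_covariance <- function(config) {
  if (!inherits(config, "two_factor_config")) {
    abort("config must be created by two_factor_config()")
  }
  k <- length(config$u1)
  sigma <- config$v1p * tcrossprod(config$u1) +
    config$v2p * tcrossprod(config$u2) +
    (config$r / k) * diag(k)
  dimnames(sigma) <- list(config$measures, config$measures)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  list(sigma = sigma, eigenvalues = ev, shares = ev / sum(ev))
}

#' Named generator presets
#'
#' * `"published-linear"` — crossover cohort calibrated to the published
#'   per-condition marginals; purely linear latent factor
#'   (`rho = 0.8`, `tau = 0.8`, `gamma = 0`).
#' * `"published-nonlinear"` — same, with a quadratic latent component
#'   (`gamma = 0.5`) that a one-component linear method cannot capture.
#' * `"two-factor-673"` — planted two-component spectrum with eigenvalue
#'   shares 67.3% and 9.8%.
#'
#' @param preset Preset name.
#' @param n Number of subjects (cohort presets) or records (two-factor
#'   preset); `NULL` keeps each preset's default.
#' @param seed Integer seed.
#' @return A `cohort_config` or `two_factor_config`.
#' @export
preset_config <- function(preset = c("published-linear", "published-nonlinear",
                                     "two-factor-673"),
                          n = NULL, seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "published-linear" = cohort_config(
      n_subjects = n %||% 9, rho = 0.8, tau = 0.8, gamma = 0, seed = seed
    ),
    "published-nonlinear" = cohort_config(
      n_subjects = n %||% 100, rho = 0.8, tau = 0.8, gamma = 0.5, seed = seed
    ),
    "two-factor-673" = two_factor_config(
      n_records = n %||% 1000, v1 = 0.673, v2 = 0.098, seed = seed
    )
  )
}

#' Build a cohort generator configuration from a YAML file
#'
#' Reads a YAML mapping whose keys mirror the arguments of [cohort_config()]
#' (`n_subjects`, `rho`, `tau`, `delta`, `gamma`, `conditions`, `better`,
#' `seed`, and optionally a `marginals` list of
#' `{measure, condition, mean, sd}` entries).
#'
#' @param path Path to a YAML file.
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
cohort_config_from_yaml <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$marginals)) {
    y$marginals <- purrr::map_dfr(y$marginals, as_tibble)
  }
  if (!is.null(y$conditions)) y$conditions <- as.character(y$conditions)
  args <- utils::modifyList(y, list(...))
  do.call(cohort_config, args)
}
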