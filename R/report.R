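#' Run the full composite-scoring pipeline
#'
#' End-to-end orchestration: load or simulate a cohort, standardize, score
#' it with the autoencoder (with leakage-safe 90/10 evaluation and optional
#' grid search) and/or PCA, sign-align each composite, test the condition
#' effect with the two-level repeated-measures ANOVA, and assemble
#' summaries, loadings and arrow-plot data. Deterministic given the seed.
#'
#' @param data A cohort tibble or the path to a cohort CSV; `NULL` to
#'   simulate instead.
#' @param preset A generator preset name (see [preset_config()]) used when
#'   `data` is `NULL`.
#' @param config A [cohort_config()] used when `data` is `NULL` (takes
#'   precedence over `preset`).
#' @param battery Battery metadata.
#' @param methods Subset of `c("ae", "pca")`.
#' @param grid Run the hyper-parameter [grid_search()] and use the winning
#'   architecture for the final autoencoder (default `FALSE`).
#' @param arch Autoencoder architecture when `grid = FALSE`.
#' @param seed Integer seed for simulation, splits and training.
#' @param epochs,learning_rate,patience Training settings.
#' @param scaler_policy Scaling policy for the 90/10 evaluation runs
#'   (`"train"`, leakage-safe, or `"all"`).
#' @param out_dir Optional directory; when given, [write_report()] is
#'   called on the result.
#' @return An object of class `composcore_report`.
#' @export
#' @examples
#' rep <- run_pipeline(preset = "published-linear", seed = 1, epochs = 200)
#' rep$methods$pca$anova
run_pipeline <- function(data = NULL, preset = NULL, config = NULL,
                         battery = default_battery(),
                         methods = c("ae", "pca"), grid = FALSE,
                         arch = ae_architecture(), seed = 1L,
                         epochs = 2000L, learning_rate = 0.01,
                         patience = 200L,
                         scaler_policy = c("train", "all"),
                         out_dir = NULL) {
  scaler_policy <- match.arg(scaler_policy)
  methods <- match.arg(methods, c("ae", "pca"), several.ok = TRUE)
  battery <- validate_battery(battery)

  if (is.character(data) && length(data) == 1L) {
    data <- load_cohort(data, battery)
  } else if (is.null(data)) {
    if (!is.null(config)) {
      if (!inherits(config, "cohort_config")) {
        abort("config must be created by cohort_config()")
      }
      data <- generate_cohort(config)
    } else if (!is.null(preset)) {
      cfg <- preset_config(preset, seed = seed)
      if (!inherits(cfg, "cohort_config")) {
        abort(sprintf("preset '%s' does not generate a crossover cohort", preset))
      }
      config <- cfg
      data <- generate_cohort(cfg)
    } else {
      abort("usage: supply a cohort (data frame or CSV path), a config, or a preset")
    }
  }
  data <- validate_cohort(data, battery)
  scaler <- fit_scaler(data, battery)
  z <- standardize(data, scaler, battery)

  results <- list()
  if ("ae" %in% methods) {
    gs <- NULL
    if (isTRUE(grid)) {
      gs <- grid_search(
        z, battery = battery, scaler_policy = scaler_policy,
        learning_rate = learning_rate, epochs = epochs, patience = patience,
        seed = seed
      )
      arch <- gs$best_architecture
    }
    cv <- evaluate_cv(
      z, arch = arch, battery = battery, scaler_policy = scaler_policy,
      learning_rate = learning_rate, epochs = epochs, patience = patience,
      seed = seed
    )
    model <- train_ae(
      z, arch = arch, battery = battery, learning_rate = learning_rate,
      epochs = epochs, patience = patience, seed = seed
    )
    raw <- encode(model, z, battery)
    sc <- align_sign(raw, z, battery, method = "ae",
                     explained_variance = cv$mean_ev_test)
    results$ae <- list(
      model = model, evaluation = cv, grid = gs, scores = sc,
      anova = rm_anova(sc), arrows = arrow_plot_data(sc)
    )
  }
  if ("pca" %in% methods) {
    pca <- fit_pca(z, n_components = 2L, battery = battery)
    raw <- pca_composite(pca)
    sc <- align_sign(raw, z, battery, method = "pca",
                     explained_variance = pca$variance_fractions[1])
    results$pca <- list(
      model = pca, scores = sc, anova = rm_anova(sc),
      arrows = arrow_plot_data(sc),
      loadings = pca_loadings_table(pca, battery),
      stability = stability_check(z, battery)
    )
  }

  summaries <- purrr::imap(results, function(res, m) {
    summarize_composite(res$scores, battery = battery)
  })
  summary <- bind_rows(
    bind_rows(summaries),
    summarize_composite(
      results[[1]]$scores, data = data, battery = battery
    )[-(1:2), ]
  )

  report <- structure(
    list(
      cohort = data,
      battery = battery,
      scaler = scaler,
      standardized = z,
      methods = results,
      summary = summary,
      measure_tests = measure_tests(data, battery),
      config = config,
      options = list(
        methods = methods, grid = isTRUE(grid), seed = as.integer(seed),
        epochs = as.integer(epochs), learning_rate = learning_rate,
        scaler_policy = scaler_policy
      )
    ),
    class = "composcore_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.composcore_report <- function(x, ...) {
  cat(sprintf(
    "<composcore_report> %d records, %d subjects, conditions %s vs %s\n",
    nrow(x$cohort), length(unique(x$cohort$subject)),
    levels(x$cohort$condition)[1], levels(x$cohort$condition)[2]
  ))
  for (m in names(x$methods)) {
    res <- x$methods[[m]]
    an <- res$anova
    ev <- attr(res$scores, "explained_variance")
    cat(sprintf(
      "  %-3s EV %.3f | sign %+d | F(%d, %d) = %.3f, p = %.3g\n",
      m, ev, sign_factor(res$scores), an$df[1], an$df[2], an$statistic,
      an$p_value
    ))
  }
  invisible(x)
}

# Plain-list view of a report for JSON serialization (no timestamps, so a
# given seed yields byte-identical output).
report_as_list <- function(report) {
  meth <- purrr::imap(report$methods, function(res, m) {
    an <- res$anova
    out <- list(
      method = m,
      sign_factor = sign_factor(res$scores),
      explained_variance = attr(res$scores, "explained_variance"),
      anova = list(
        F = an$statistic, df1 = an$df[1], df2 = an$df[2],
        p_value = an$p_value, mean_difference = an$mean_difference,
        n_pairs = an$n_pairs
      )
    )
    if (m == "ae") {
      out$architecture <- unclass(res$model$architecture)
      out$training <- list(
        learning_rate = res$model$learning_rate,
        epochs_run = res$model$epochs_run,
        loss_initial = res$model$loss_initial,
        loss_final = res$model$loss_final,
        seed = res$model$seed
      )
      out$evaluation <- as.list(glance(res$evaluation))
      if (!is.null(res$grid)) out$grid <- res$grid$table
    }
    if (m == "pca") {
      out$variance_fractions <- res$model$variance_fractions
      out$stability <- res$stability
    }
    out
  })
  list(
    n_records = nrow(report$cohort),
    n_subjects = length(unique(report$cohort$subject)),
    conditions = levels(report$cohort$condition),
    options = report$options,
    methods = meth,
    measure_tests = report$measure_tests
  )
}

#' Write a pipeline report bundle to disk
#'
#' Writes `report.json` (metrics, test results, seeds, configuration),
#' `scores.csv`, `summary.csv`, `arrows.csv` and — when PCA was run —
#' `loadings.csv` into `dir`. Output is byte-identical for identical input
#' and seed.
#'
#' @param report A `composcore_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "composcore_report")) {
    abort("report must be a composcore_report")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    report_as_list(report), file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  scores <- purrr::imap_dfr(report$methods, function(res, m) {
    mutate(as_tibble(res$scores), method = m, .before = 1)
  })
  readr::write_csv(scores, file.path(dir, "scores.csv"), progress = FALSE)
  readr::write_csv(report$summary, file.path(dir, "summary.csv"), progress = FALSE)
  arrows <- purrr::imap_dfr(report$methods, function(res, m) {
    mutate(res$arrows, method = m, .before = 1)
  })
  readr::write_csv(arrows, file.path(dir, "arrows.csv"), progress = FALSE)
  if (!is.null(report$methods$pca)) {
    readr::write_csv(report$methods$pca$loadings, file.path(dir, "loadings.csv"),
                     progress = FALSE)
  }
  invisible(dir)
}
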