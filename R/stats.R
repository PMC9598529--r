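#' Sign-align a composite to the direction of improvement
#'
#' A bottleneck or PC1 score is only defined up to sign. This fixes it
#' against a direction-adjusted health proxy: for each record,
#' `p_i = mean_k(d_k z_ik)` (the mean standardized score after flipping
#' lower-is-better measures), and the composite keeps or flips its sign so
#' that it correlates non-negatively with `p`. The aligned composite then
#' increases with improvement in any measure: higher = healthier.
#'
#' @param raw Numeric vector of raw composite scores, one per record of
#'   `data`.
#' @param data The standardized records (tibble or matrix) the scores were
#'   computed from; `subject` / `condition` columns are carried through when
#'   present.
#' @param battery Battery metadata supplying the direction vector.
#' @param method Optional label (`"ae"`, `"pca"`, ...) recorded on the
#'   result.
#' @param explained_variance Optional explained-variance fraction recorded
#'   on the result.
#' @return A `composite_result` tibble with columns (`subject`,
#'   `condition`,) `raw`, `aligned`, and attributes `sign_factor`, `method`,
#'   `explained_variance`.
#' @export
align_sign <- function(raw, data, battery = default_battery(), method = NULL,
                       explained_variance = NULL) {
  battery <- validate_battery(battery)
  z <- as_measure_matrix(data, battery)
  if (length(raw) != nrow(z)) {
    abort("need exactly one raw score per record of data")
  }
  if (!is.numeric(raw) || anyNA(raw)) abort("raw scores must be numeric and complete")
  if (sd(raw) == 0) {
    abort("alignment undefined: raw composite scores have zero variance")
  }
  proxy <- drop(z %*% battery$direction) / nrow(battery)
  sf <- if (cor(raw, proxy) >= 0) 1 else -1
  out <- tibble(raw = as.numeric(raw), aligned = sf * as.numeric(raw))
  if (is.data.frame(data)) {
    ids <- intersect(c("subject", "condition"), names(data))
    if (length(ids) > 0) out <- dplyr::bind_cols(as_tibble(data)[ids], out)
  }
  attr(out, "sign_factor") <- sf
  attr(out, "method") <- method
  attr(out, "explained_variance") <- explained_variance
  class(out) <- c("composite_result", class(out))
  out
}

#' Sign factor of an aligned composite
#'
#' @param x A `composite_result` from [align_sign()].
#' @return `+1` or `-1`.
#' @export
sign_factor <- function(x) {
  sf <- attr(x, "sign_factor")
  if (is.null(sf)) abort("x carries no sign_factor attribute")
  sf
}

# Complete (subject, condition-pair) score table, erroring on incomplete
# pairs. Returns one row per subject with score under each level.
complete_pairs <- function(scores, value) {
  if (!is.data.frame(scores)) abort("scores must be a data frame")
  need <- c("subject", "condition", value)
  miss <- setdiff(need, names(scores))
  if (length(miss) > 0) {
    abort(paste0("scores lack column(s): ", paste(miss, collapse = ", ")))
  }
  lev <- condition_levels_of(scores)
  if (length(lev) != 2) abort("scores must have exactly two condition levels")
  wide <- tidyr::pivot_wider(
    scores[need],
    names_from = "condition", values_from = dplyr::all_of(value)
  )
  incomplete <- wide$subject[!stats::complete.cases(wide[lev])]
  if (length(incomplete) > 0) {
    abort(sprintf(
      "incomplete pair: subject '%s' lacks a record for one condition",
      incomplete[1]
    ))
  }
  list(wide = wide, levels = lev)
}

#' Two-level repeated-measures ANOVA of the condition effect
#'
#' With one within-subject factor at two levels, the repeated-measures
#' ANOVA reduces exactly to the two-sided paired t-test: `F = t^2` with
#' `df = (1, n_pairs - 1)` and an identical p-value. The test statistic is
#' computed in closed form from the paired differences
#' (second condition level minus the first).
#'
#' @param scores A data frame with `subject`, `condition` and a score
#'   column — typically a `composite_result` from [align_sign()].
#' @param value Name of the score column (default `"aligned"`).
#' @return An object of class `rm_anova` with `statistic` (F), `t`, `df`,
#'   `p_value`, `mean_difference`, `n_pairs`, and the condition `levels`.
#' @export
#' @examples
#' scores <- tibble::tibble(
#'   subject = rep(c("a", "b", "c"), each = 2),
#'   condition = factor(rep(c("MK", "MCK"), 3), levels = c("MK", "MCK")),
#'   aligned = c(0, 1, 1, 3, 2, 5)
#' )
#' rm_anova(scores)
rm_anova <- function(scores, value = "aligned") {
  cp <- complete_pairs(scores, value)
  lev <- cp$levels
  diffs <- cp$wide[[lev[2]]] - cp$wide[[lev[1]]]
  np <- length(diffs)
  if (np < 2) abort("insufficient data: need at least 2 complete pairs")
  sdd <- sd(diffs)
  if (sdd == 0) {
    abort("degenerate: paired differences have zero variance, F is undefined")
  }
  tstat <- mean(diffs) / (sdd / sqrt(np))
  fstat <- tstat^2
  p <- 2 * pt(-abs(tstat), df = np - 1)
  structure(
    list(
      statistic = fstat,
      t = tstat,
      df = c(1L, np - 1L),
      p_value = p,
      mean_difference = mean(diffs),
      n_pairs = np,
      levels = lev,
      value = value
    ),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA (%s vs %s, paired-t reduction)\n  F(%d, %d) = %.4f, p = %.3g\n  mean difference (%s - %s) = %.4f over %d pairs\n",
    x$levels[2], x$levels[1], x$df[1], x$df[2], x$statistic, x$p_value,
    x$levels[2], x$levels[1], x$mean_difference, x$n_pairs
  ))
  invisible(x)
}

#' @describeIn rm_anova One-row tibble of the test.
#' @param x An `rm_anova`.
#' @param ... Unused.
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble(
    term = "condition",
    statistic = x$statistic,
    t = x$t,
    df1 = x$df[1],
    df2 = x$df[2],
    p_value = x$p_value,
    mean_difference = x$mean_difference,
    n_pairs = x$n_pairs
  )
}

#' @describeIn rm_anova Same as `tidy()` (single-term model).
#' @export
glance.rm_anova <- function(x, ...) tidy(x)

#' Per-measure paired condition tests
#'
#' The per-measure analogue of the composite test: a two-sided paired
#' t-test per raw measure (second condition level minus the first), with a
#' 0.05 significance threshold. No multiple-testing correction is applied
#' across the eight tests; the `significant` column is to be read with that
#' in mind.
#'
#' @param data A cohort tibble.
#' @param battery Battery metadata.
#' @return A tibble with one row per measure: `mean_difference`,
#'   `statistic` (t), `df`, `p_value`, `significant`, and `improved`
#'   (whether the mean change runs in the measure's direction of
#'   improvement).
#' @export
measure_tests <- function(data, battery = default_battery()) {
  battery <- validate_battery(battery)
  data <- validate_cohort(data, battery)
  purrr::map2_dfr(battery$measure, battery$direction, function(m, d) {
    sc <- data[c("subject", "condition", m)]
    cp <- complete_pairs(sc, m)
    diffs <- cp$wide[[cp$levels[2]]] - cp$wide[[cp$levels[1]]]
    tt <- stats::t.test(diffs)
    tibble(
      measure = m,
      mean_difference = mean(diffs),
      statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value,
      significant = tt$p.value < 0.05,
      improved = mean(diffs) * d > 0
    )
  })
}

#' Per-condition summaries of composite and raw measures
#'
#' Publication-style summary: for the composite (and, when a cohort is
#' supplied, for every raw measure) the per-condition n, mean, sample SD,
#' and standard error `SD / sqrt(n)`. With a single record per condition
#' the SD and SE are reported as missing. Invariant to record order.
#'
#' @param scores A `composite_result` (or any data frame with `subject`,
#'   `condition` and a score column).
#' @param data Optional cohort tibble for per-measure raw summaries.
#' @param battery Battery metadata (used with `data`).
#' @param value Name of the composite column (default `"aligned"`).
#' @return A tibble with columns `variable`, `condition`, `n`, `mean`,
#'   `sd`, `se`; the composite row first, then measures in battery order.
#' @export
summarize_composite <- function(scores, data = NULL,
                                battery = default_battery(),
                                value = "aligned") {
  one <- function(df, col, label) {
    df |>
      group_by(.data$condition) |>
      summarise(
        n = dplyr::n(),
        mean = mean(.data[[col]]),
        sd = if (dplyr::n() > 1) sd(.data[[col]]) else NA_real_,
        .groups = "drop"
      ) |>
      mutate(variable = label, se = .data$sd / sqrt(.data$n)) |>
      dplyr::select("variable", "condition", "n", "mean", "sd", "se")
  }
  label <- attr(scores, "method") %||% "composite"
  out <- one(as_tibble(scores), value, paste0("composite_", label))
  if (!is.null(data)) {
    battery <- validate_battery(battery)
    data <- validate_cohort(data, battery)
    out <- bind_rows(
      out,
      purrr::map_dfr(battery$measure, function(m) one(data, m, m))
    )
  }
  out
}

#' Figure-ready per-subject arrow data
#'
#' One arrow per subject in composite-score space, oriented from the `from`
#' condition to the `to` condition (defaults: first condition level to
#' second). Group mean markers are attached as the `"group_means"`
#' attribute. The mean arrow displacement equals the difference of the
#' group means.
#'
#' @inheritParams rm_anova
#' @param from,to Condition labels giving the arrow orientation.
#' @return A tibble with one row per subject: `subject`, `from`, `to`,
#'   `score_from`, `score_to`, `delta`; attribute `"group_means"` holds a
#'   per-condition tibble of mean scores.
#' @export
arrow_plot_data <- function(scores, value = "aligned", from = NULL, to = NULL) {
  cp <- complete_pairs(scores, value)
  lev <- cp$levels
  from <- from %||% lev[1]
  to <- to %||% lev[2]
  if (!all(c(from, to) %in% lev) || from == to) {
    abort("'from' and 'to' must be the two condition levels")
  }
  score_from <- cp$wide[[from]]
  score_to <- cp$wide[[to]]
  out <- tibble(
    subject = cp$wide$subject,
    from = .env$from,
    to = .env$to,
    score_from = .env$score_from,
    score_to = .env$score_to,
    delta = score_to - score_from
  )
  gm <- as_tibble(scores) |>
    group_by(.data$condition) |>
    summarise(mean_score = mean(.data[[value]]), .groups = "drop")
  attr(out, "group_means") <- gm
  out
}
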