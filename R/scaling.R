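#' Fit a standard scaler on (a subset of) a cohort
#'
#' Computes the per-measure mean and sample standard deviation (n-1
#' denominator) over the selected records. Keeping the scaler a separate
#' object lets leakage-safe policies (fit on training records only) be
#' expressed downstream.
#'
#' @param data A cohort tibble or records-by-measures matrix.
#' @param battery Battery metadata; see [default_battery()].
#' @param subset Optional logical or integer row index of the records to fit
#'   on; defaults to all records.
#' @return A tibble with columns `measure`, `mean`, `sd`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 20, seed = 1))
#' fit_scaler(cohort)
fit_scaler <- function(data, battery = default_battery(), subset = NULL) {
  battery <- validate_battery(battery)
  m <- as_measure_matrix(data, battery)
  rows <- if (is.null(subset)) seq_len(nrow(m)) else {
    if (is.logical(subset)) which(subset) else as.integer(subset)
  }
  if (length(rows) == 0) abort("scaler subset is empty")
  if (length(rows) < 2) {
    abort("degenerate scale: standard deviation is undefined on a single record")
  }
  m <- m[rows, , drop = FALSE]
  mu <- colMeans(m)
  sdev <- apply(m, 2, sd)
  bad <- which(!(is.finite(sdev) & sdev > 0))
  if (length(bad) > 0) {
    abort(sprintf(
      "degenerate scale: measure '%s' has zero variance in the fitted subset",
      colnames(m)[bad[1]]
    ))
  }
  tibble(measure = colnames(m), mean = unname(mu), sd = unname(sdev))
}

#' Standardize a cohort with a fitted scaler
#'
#' Applies `z = (x - mean) / sd` per measure. The inverse transform
#' ([unstandardize()]) recovers the raw values to machine precision.
#'
#' @param data A cohort tibble or records-by-measures matrix.
#' @param scaler A scaler tibble from [fit_scaler()].
#' @param battery Battery metadata; defaults to the scaler's measure order.
#' @return A tibble of the same shape as `data` with standardized measure
#'   columns (identifier columns, when present, are carried through). The
#'   scaler is attached as attribute `"scaler"`.
#' @export
standardize <- function(data, scaler, battery = NULL) {
  measures <- scaler$measure
  if (is.null(battery)) {
    battery <- tibble(measure = measures, units = NA_character_, direction = 1)
  } else {
    battery <- validate_battery(battery)
    miss <- setdiff(battery$measure, measures)
    if (length(miss) > 0) {
      abort(paste0("scaler does not cover measure(s): ", paste(miss, collapse = ", ")))
    }
    measures <- battery$measure
    scaler <- scaler[match(measures, scaler$measure), , drop = FALSE]
  }
  m <- as_measure_matrix(data, tibble(measure = measures, direction = 1))
  z <- sweep(sweep(m, 2, scaler$mean, "-"), 2, scaler$sd, "/")
  out <- as_tibble(as.data.frame(z, check.names = FALSE))
  if (is.data.frame(data)) {
    ids <- intersect(c("subject", "condition"), names(data))
    if (length(ids) > 0) out <- dplyr::bind_cols(data[ids], out)
  }
  attr(out, "scaler") <- scaler
  out
}

#' Invert a standardization
#'
#' @param data A standardized tibble or matrix.
#' @param scaler The scaler used to standardize (defaults to the `"scaler"`
#'   attribute left by [standardize()]).
#' @return A tibble of raw-scale values.
#' @export
unstandardize <- function(data, scaler = attr(data, "scaler")) {
  if (is.null(scaler)) abort("no scaler supplied and none attached to data")
  m <- as_measure_matrix(data, tibble(measure = scaler$measure, direction = 1))
  x <- sweep(sweep(m, 2, scaler$sd, "*"), 2, scaler$mean, "+")
  out <- as_tibble(as.data.frame(x, check.names = FALSE))
  if (is.data.frame(data)) {
    ids <- intersect(c("subject", "condition"), names(data))
    if (length(ids) > 0) out <- dplyr::bind_cols(data[ids], out)
  }
  out
}
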