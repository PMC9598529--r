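#' Load a cohort table from CSV
#'
#' Reads a long-format cohort file — one row per (subject, condition) record —
#' with a `subject` column, a `condition` column holding exactly two levels,
#' and one numeric column per battery measure. Row order is preserved and the
#' result is validated (no missing values, no duplicated records).
#'
#' @param path Path to a CSV file (UTF-8, period decimal separator).
#' @param battery Battery metadata; see [default_battery()].
#' @param condition_levels Optional character vector of length 2 fixing the
#'   order of the condition levels; defaults to order of first appearance.
#' @return A validated cohort tibble with `subject` (character), `condition`
#'   (factor with two levels) and the measure columns in battery order.
#' @export
load_cohort <- function(path, battery = default_battery(), condition_levels = NULL) {
  battery <- validate_battery(battery)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  need <- c("subject", "condition", battery$measure)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("cohort file lacks column(s): ", paste(miss, collapse = ", ")))
  }
  raw <- raw[need]
  for (m in battery$measure) {
    vals <- suppressWarnings(as.numeric(raw[[m]]))
    bad <- which(!is.finite(vals))
    if (length(bad) > 0) {
      abort(sprintf(
        "missing or non-numeric value for measure '%s' in row %d", m, bad[1]
      ))
    }
    raw[[m]] <- vals
  }
  validate_cohort(raw, battery = battery, condition_levels = condition_levels)
}

#' Validate a cohort table
#'
#' Checks the structural invariants of a cohort: all battery measures present
#' and finite, exactly two condition levels, and at most one record per
#' (subject, condition) pair.
#'
#' @inheritParams load_cohort
#' @param data A data frame with `subject`, `condition` and measure columns.
#' @return The cohort as a tibble, with `condition` converted to a two-level
#'   factor.
#' @export
validate_cohort <- function(data, battery = default_battery(), condition_levels = NULL) {
  battery <- validate_battery(battery)
  if (!is.data.frame(data)) abort("cohort must be a data frame")
  need <- c("subject", "condition", battery$measure)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("cohort lacks column(s): ", paste(miss, collapse = ", ")))
  }
  data <- as_tibble(data)[need]
  data$subject <- as.character(data$subject)

  lev <- condition_levels %||%
    (if (is.factor(data$condition)) levels(droplevels(data$condition))
     else unique(as.character(data$condition)))
  obs <- unique(as.character(data$condition))
  if (length(obs) != 2) {
    abort(sprintf(
      "cohort must have exactly two condition levels, found %d (%s)",
      length(obs), paste(obs, collapse = ", ")
    ))
  }
  if (!setequal(obs, lev)) {
    abort("condition_levels do not match the levels present in the data")
  }
  data$condition <- factor(as.character(data$condition), levels = lev)

  key <- paste(data$subject, data$condition, sep = "\r")
  if (anyDuplicated(key) > 0) {
    dup <- data[duplicated(key), , drop = FALSE]
    abort(sprintf(
      "duplicated record for subject '%s', condition '%s'",
      dup$subject[1], as.character(dup$condition[1])
    ))
  }
  for (m in battery$measure) {
    v <- data[[m]]
    if (!is.numeric(v)) abort(sprintf("measure '%s' is not numeric", m))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      abort(sprintf("missing value for measure '%s' in row %d", m, bad[1]))
    }
  }
  data
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort()]: numeric content round-trips exactly (full
#' double precision).
#'
#' @param data A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  out <- data
  out$condition <- as.character(out$condition)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
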