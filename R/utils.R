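# Internal helpers shared across modules.

# Coerce a cohort tibble / data frame / bare matrix to the records-by-measures
# numeric matrix used by the numerical code. When a battery is supplied its
# measure order is enforced; otherwise all numeric columns are taken in order.
as_measure_matrix <- function(x, battery = NULL) {
  measures <- if (!is.null(battery)) battery$measure else NULL
  if (is.matrix(x)) {
    m <- x
    if (!is.null(measures)) {
      if (!is.null(colnames(m))) {
        miss <- setdiff(measures, colnames(m))
        if (length(miss) > 0) {
          abort(paste0("missing measure column(s): ", paste(miss, collapse = ", ")))
        }
        m <- m[, measures, drop = FALSE]
      } else if (ncol(m) != length(measures)) {
        abort(sprintf("expected %d measure columns, got %d", length(measures), ncol(m)))
      }
    }
  } else if (is.data.frame(x)) {
    if (is.null(measures)) {
      keep <- vapply(x, is.numeric, logical(1))
      m <- as.matrix(x[keep])
    } else {
      miss <- setdiff(measures, names(x))
      if (length(miss) > 0) {
        abort(paste0("missing measure column(s): ", paste(miss, collapse = ", ")))
      }
      m <- as.matrix(x[measures])
    }
  } else {
    abort("expected a data frame or a numeric matrix of measures")
  }
  storage.mode(m) <- "double"
  m
}

# Condition labels of a cohort in their level order (factor levels when the
# condition column is a factor, order of first appearance otherwise).
condition_levels_of <- function(data) {
  cond <- data$condition
  if (is.null(cond)) abort("data has no 'condition' column")
  if (is.factor(cond)) levels(cond) else unique(as.character(cond))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
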