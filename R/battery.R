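#' The default eight-measure outcome battery
#'
#' Metadata for the clinical outcome battery scored by the package: measure
#' name, units, and direction of improvement (`+1` when a higher raw score
#' means better function, `-1` when a lower one does). The direction vector
#' drives sign alignment of composites and the improvement axis of the
#' synthetic cohort generator.
#'
#' The battery comprises the Amputee Mobility Predictor (AMP), Berg Balance
#' Scale (BERG), 6-minute walk test (6MWT), the ambulation module of the
#' Prosthesis Evaluation Questionnaire (PEQ_amb), the Modified Falls Efficacy
#' Scale (MFES) — all higher-is-better — and the Four Square Step Test (FSST),
#' 10-metre walk test (10MWT) and Timed Up and Go (TUG), which are timed and
#' therefore lower-is-better.
#'
#' @return A tibble with columns `measure`, `units`, `direction`.
#' @export
#' @examples
#' default_battery()
default_battery <- function() {
  tibble::tribble(
    ~measure,  ~units,           ~direction,
    "AMP",     "points (0-47)",   1,
    "BERG",    "points (0-56)",   1,
    "6MWT",    "m",               1,
    "PEQ_amb", "score (0-100)",   1,
    "MFES",    "score (0-10)",    1,
    "FSST",    "s",              -1,
    "10MWT",   "s",              -1,
    "TUG",     "s",              -1
  )
}

#' Validate battery metadata
#'
#' @param battery A data frame with columns `measure`, `direction` and
#'   optionally `units`.
#' @return The battery as a tibble, invisibly validated.
#' @export
validate_battery <- function(battery) {
  if (!is.data.frame(battery)) abort("battery must be a data frame")
  miss <- setdiff(c("measure", "direction"), names(battery))
  if (length(miss) > 0) {
    abort(paste0("battery lacks column(s): ", paste(miss, collapse = ", ")))
  }
  battery <- as_tibble(battery)
  if (!"units" %in% names(battery)) battery$units <- NA_character_
  if (anyDuplicated(battery$measure) > 0) {
    abort("battery measure names must be unique")
  }
  if (!all(battery$direction %in% c(-1, 1))) {
    abort("battery directions must be exactly +1 or -1")
  }
  battery
}

#' Read battery metadata from a YAML file
#'
#' Expects either a top-level list of entries or a `battery:` key, each entry
#' carrying `measure`, `units`, `direction`.
#'
#' @param path Path to a YAML file.
#' @return A validated battery tibble.
#' @export
read_battery <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- y$battery %||% y
  battery <- purrr::map_dfr(entries, function(e) {
    tibble(
      measure = as.character(e$measure),
      units = as.character(e$units %||% NA_character_),
      direction = as.numeric(e$direction)
    )
  })
  validate_battery(battery)
}

# Direction vector d in battery order.
direction_vector <- function(battery) {
  battery <- validate_battery(battery)
  stats::setNames(as.numeric(battery$direction), battery$measure)
}
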