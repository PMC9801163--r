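#' Read a coded survey table from CSV
#'
#' Reads a respondent-level table of integer-coded items plus descriptive
#' columns (`country`, `gender`, `age_group`), a positive calibration
#' `weight` per respondent and an optional stable `row_id`. Every item
#' value is validated against its admissible codes; codes declared as
#' missing are converted to `NA`. Row order is preserved.
#'
#' @param path Path to a CSV file (UTF-8, header row).
#' @param codings Item codings, as returned by [covid_item_codings()] or
#'   [read_item_codings()].
#' @return A tibble with `row_id`, one integer column per item, the
#'   descriptive columns present in the file, and `weight`.
#' @export
read_survey_csv <- function(path, codings = covid_item_codings()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c(codings$name, "weight")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Survey file is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"row_id" %in% names(raw)) raw$row_id <- seq_len(nrow(raw))
  validate_survey(raw, codings)
}

# Validate item codes and weights; convert missing codes to NA.
validate_survey <- function(data, codings) {
  for (i in seq_len(nrow(codings))) {
    nm <- codings$name[[i]]
    codes <- codings$codes[[i]]
    miss <- codings$missing_codes[[i]]
    v <- data[[nm]]
    if (!is.numeric(v)) {
      abort(paste0("Column `", nm, "` must be numeric (integer codes)."))
    }
    v[v %in% miss] <- NA
    bad <- which(!is.na(v) & !(v %in% codes))
    if (length(bad) > 0) {
      abort(paste0(
        "Unknown code in variable `", nm, "`: value ", v[bad[1L]],
        " at row ", bad[1L], " (admissible: ",
        paste(codes, collapse = ", "), ")."
      ))
    }
    data[[nm]] <- as.integer(v)
  }
  if (any(!is.finite(data$weight)) || any(data$weight <= 0)) {
    abort("Column `weight` must be positive and finite.")
  }
  descr <- intersect(c("country", "gender", "age_group"), names(data))
  dplyr::relocate(
    tibble::as_tibble(data),
    "row_id", dplyr::all_of(codings$name), dplyr::all_of(descr), "weight"
  )
}

#' Write a survey table to CSV
#'
#' @param data A survey tibble (as read by [read_survey_csv()] or produced
#'   by [simulate_survey()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Apply a polarity recode to one variable
#'
#' Maps raw instrument codes onto polarity-aligned analysis codes via the
#' coding's `recode` map (old code -> new code). Variables without a
#' recode map are returned unchanged; `NA` passes through.
#'
#' @param values Integer vector of raw codes.
#' @param coding One row of an item-codings tibble (or a list with a
#'   `recode` entry).
#' @return Integer vector of the same length.
#' @export
#' @examples
#' coding <- list(name = "x", recode = c(`0` = 1L, `1` = 0L))
#' recode_variable(c(0L, 1L, 1L), coding)
recode_variable <- function(values, coding) {
  if (is.data.frame(coding)) coding <- as.list(coding[1L, ])
  map <- coding$recode
  if (is.list(map)) map <- map[[1L]]
  if (is.null(map)) {
    return(values)
  }
  old <- as.integer(names(map))
  idx <- match(values, old)
  unmapped <- which(!is.na(values) & is.na(idx))
  if (length(unmapped) > 0) {
    abort(paste0(
      "Value ", values[unmapped[1L]], " of `", coding$name %||% "variable",
      "` has no entry in the recode map."
    ))
  }
  out <- unname(as.integer(map)[idx])
  out[is.na(values)] <- NA_integer_
  out
}

#' Keep respondents complete on the analysis items
#'
#' Listwise deletion over `required_vars`: rows with any missing value
#' among them are dropped, and the kept/dropped counts are reported. The
#' operation is idempotent and preserves the alignment of weights and
#' descriptives (whole rows are dropped).
#'
#' @param data A survey tibble.
#' @param required_vars Item columns that must be non-missing; defaults to
#'   every item named in `codings`.
#' @param codings Item codings used for the default `required_vars`.
#' @return The filtered tibble.
#' @export
filter_complete_cases <- function(data, required_vars = NULL,
                                  codings = covid_item_codings()) {
  required_vars <- required_vars %||% intersect(codings$name, names(data))
  missing_cols <- setdiff(required_vars, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`required_vars` not present in data: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  keep <- stats::complete.cases(as.data.frame(data)[, required_vars, drop = FALSE])
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    abort("No complete cases remain after filtering.")
  }
  message(
    "Complete-case filter: kept ", nrow(out), " of ", nrow(data),
    " rows (dropped ", nrow(data) - nrow(out), ")."
  )
  out
}
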