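#' Raw block sum for one composite indicator
#'
#' Sums the polarity-aligned codes of the items belonging to one thematic
#' block, per respondent. No rescaling is applied.
#'
#' @param items A survey tibble (or data frame) complete on the block's
#'   items, or a single named row.
#' @param spec One row of an indicator-specification tibble
#'   (see [indicator_specs()]).
#' @return Integer vector of raw block sums, one per row of `items`.
#' @export
#' @examples
#' spec <- indicator_specs()[1, ]
#' indicator_raw_sum(data.frame(health_before = 1L, health_change = 0L), spec)
indicator_raw_sum <- function(items, spec) {
  vars <- spec$variables[[1L]]
  if (!is.data.frame(items)) items <- tibble::as_tibble(as.list(items))
  missing_cols <- setdiff(vars, names(items))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing item column(s): ", paste(missing_cols, collapse = ", ")))
  }
  block <- as.matrix(as.data.frame(items)[, vars, drop = FALSE])
  if (anyNA(block)) abort("Block items contain missing values; filter complete cases first.")
  as.integer(rowSums(block))
}

#' Rescale a raw block sum to the 0-10 indicator scale
#'
#' Affine map of the theoretical raw range `[raw_min, raw_max]` onto
#' `[0, 10]`: `10 * (raw - raw_min) / (raw_max - raw_min)`. The
#' theoretical range comes from the admissible item codes, so a raw value
#' outside it signals a coding/spec mismatch and is an error.
#'
#' @param raw Numeric raw block sums.
#' @param raw_min,raw_max Theoretical minimum and maximum block sum.
#' @return Numeric values in `[0, 10]`.
#' @export
#' @examples
#' rescale_0_10(4, 1, 7)
rescale_0_10 <- function(raw, raw_min, raw_max) {
  if (raw_max <= raw_min) abort("`raw_max` must exceed `raw_min` (degenerate block).")
  if (any(raw < raw_min | raw > raw_max, na.rm = TRUE)) {
    abort(paste0(
      "Raw sum outside the theoretical range [", raw_min, ", ", raw_max,
      "]; item codings and indicator spec disagree."
    ))
  }
  10 * (raw - raw_min) / (raw_max - raw_min)
}

#' Build the composite-indicator matrix from a coded survey
#'
#' Column `j` is the block-`j` raw sum rescaled to 0-10 over its
#' theoretical range; higher values mean a worse situation. Weights and
#' descriptive columns are carried through unchanged.
#'
#' @param data A survey tibble, complete-case on every item used by `specs`.
#' @param specs Indicator specifications, see [indicator_specs()].
#' @return An `indicator_tbl`: a tibble with `row_id`, one 0-10 column per
#'   indicator, the descriptive columns present in `data`, and `weight`.
#'   The indicator names are stored in the `indicator_names` attribute;
#'   [indicator_values()] extracts the numeric matrix.
#' @export
#' @examples
#' sim <- simulate_survey(synthetic_config(n_respondents = 50, k_true = 3, seed = 1))
#' X <- build_indicator_matrix(sim$survey)
#' indicator_values(X)[1:3, 1:3]
build_indicator_matrix <- function(data, specs = indicator_specs()) {
  cols <- purrr::pmap(specs, function(name, variables, raw_min, raw_max) {
    raw <- indicator_raw_sum(data, tibble::tibble(
      name = name, variables = list(variables),
      raw_min = raw_min, raw_max = raw_max
    ))
    rescale_0_10(raw, raw_min, raw_max)
  })
  names(cols) <- specs$name
  out <- tibble::tibble(
    row_id = data$row_id %||% seq_len(nrow(data)),
    !!!cols
  )
  for (d in intersect(c("country", "gender", "age_group"), names(data))) {
    out[[d]] <- data[[d]]
  }
  if ("weight" %in% names(data)) out$weight <- data$weight
  new_indicator_tbl(out, specs$name)
}

new_indicator_tbl <- function(data, indicator_names) {
  structure(data,
    class = c("indicator_tbl", class(tibble::tibble())),
    indicator_names = indicator_names
  )
}

#' Extract the numeric indicator matrix
#'
#' @param x An `indicator_tbl` (or a plain numeric matrix, returned as is).
#' @return An `n x m` numeric matrix with indicator columns.
#' @export
indicator_values <- function(x) as_indicator_matrix(x)

#' Convert a bare indicator matrix to an indicator tibble
#'
#' Wraps an `n x m` matrix of 0-10 indicator values (e.g. the noiseless
#' target matrix of a synthetic design) as an `indicator_tbl` with unit
#' weights, so it can flow through the allocation and profiling helpers.
#'
#' @param X Numeric matrix; column names become indicator names
#'   (`ind_1..ind_m` if absent).
#' @param weights Optional positive weights, recycled to `nrow(X)`.
#' @return An `indicator_tbl`.
#' @export
as_indicator_tbl <- function(X, weights = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("ind_", seq_len(ncol(X)))
  out <- tibble::as_tibble(X)
  out <- tibble::add_column(out, row_id = seq_len(nrow(X)), .before = 1L)
  out$weight <- aligned_weights(NULL, weights, nrow(X))
  new_indicator_tbl(out, colnames(X))
}

#' Weighted indicator distributions by a descriptive variable
#'
#' For each group level and indicator: the weighted mean, weighted
#' quartiles (left-continuous inverse weighted ECDF, see
#' [weighted_quantile()]) and the weighted share of respondents exactly at
#' 0 (the best possible situation).
#'
#' @param x An `indicator_tbl`.
#' @param group_var One of the descriptive columns present in `x`
#'   (`"gender"`, `"age_group"`, `"country"`).
#' @return A tibble with one row per group level and indicator.
#' @export
indicator_distribution_by <- function(x, group_var) {
  if (!group_var %in% names(x)) {
    abort(paste0("Group variable `", group_var, "` not present in the data."))
  }
  nms <- attr(x, "indicator_names")
  w <- aligned_weights(x, NULL, nrow(x))
  long <- tibble::as_tibble(as.data.frame(x)[, c(group_var, nms)])
  long$.w <- w
  long |>
    tidyr::pivot_longer(dplyr::all_of(nms),
      names_to = "indicator", values_to = "value"
    ) |>
    dplyr::group_by(.data[[group_var]], .data$indicator) |>
    dplyr::summarise(
      weighted_mean = sum(.data$.w * .data$value) / sum(.data$.w),
      q25 = weighted_quantile(.data$value, .data$.w, 0.25),
      median = weighted_quantile(.data$value, .data$.w, 0.5),
      q75 = weighted_quantile(.data$value, .data$.w, 0.75),
      share_at_zero = sum(.data$.w[.data$value <= 1e-9]) / sum(.data$.w),
      .groups = "drop"
    ) |>
    dplyr::mutate(indicator = factor(.data$indicator, levels = nms)) |>
    dplyr::arrange(.data$indicator, .data[[group_var]])
}
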