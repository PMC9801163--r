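#' Sample covariance of the indicator columns
#'
#' The unweighted sample covariance (denominator `n - 1`) of the data
#' matrix, used to whiten distances in [mahalanobis_allocate()].
#'
#' @param X Data (`indicator_tbl` or matrix), `n >= 2`.
#' @return An `m x m` covariance matrix.
#' @export
covariance_matrix <- function(X) {
  Xm <- as_indicator_matrix(X)
  if (nrow(Xm) < 2L) abort("Covariance needs at least two rows.")
  cov(Xm)
}

# Inverse of a covariance matrix; pseudo-inverse when the condition
# number exceeds 1e12 (e.g. a constant indicator column).
inverse_covariance <- function(S) {
  S <- as.matrix(S)
  d <- svd(S, nu = 0, nv = 0)$d
  if (min(d) <= 0 || max(d) / min(d) > 1e12) MASS::ginv(S) else solve(S)
}

#' Allocate every respondent to the nearest archetypoid (Mahalanobis)
#'
#' Assigns each row `x_i` to the archetypoid `z_l` minimising the squared
#' Mahalanobis distance `(x_i - z_l)' S^{-1} (x_i - z_l)`, with `S` the
#' covariance matrix of the data (pseudo-inverted when singular). Ties
#' break toward the lowest archetypoid index; an archetypoid row is
#' always assigned to its own profile at distance 0.
#'
#' @param X Data (`indicator_tbl` or matrix).
#' @param Z `k x m` archetypoid matrix, or an `archetypoid_model`.
#' @param S Covariance matrix; defaults to [covariance_matrix()] of `X`.
#' @return A `profile_assignment` tibble with columns `row_id`, `profile`
#'   and `d2` (squared distance to the assigned archetypoid). The full
#'   `n x k` distance matrix is in attribute `"distances"` and the rule in
#'   attribute `"method"`.
#' @export
mahalanobis_allocate <- function(X, Z, S = covariance_matrix(X)) {
  Xm <- as_indicator_matrix(X)
  if (inherits(Z, "archetypoid_model")) Z <- Z$Z
  Z <- as.matrix(Z)
  if (ncol(Z) != ncol(Xm)) abort("`X` and `Z` must have the same columns.")
  Sinv <- inverse_covariance(S)
  k <- nrow(Z)
  D2 <- matrix(0, nrow(Xm), k)
  for (l in seq_len(k)) {
    delta <- sweep(Xm, 2, Z[l, ])
    D2[, l] <- pmax(rowSums((delta %*% Sinv) * delta), 0)
  }
  labels <- max.col(-D2, ties.method = "first")
  new_profile_assignment(X, labels,
    d2 = D2[cbind(seq_len(nrow(Xm)), labels)],
    distances = D2, method = "mahalanobis"
  )
}

#' Allocate by maximum mixture weight
#'
#' Assigns each respondent to the profile with the largest alpha
#' (mixture) weight; ties break toward the lowest profile index.
#'
#' @param A An `n x k` alpha matrix with rows on the simplex, or a fitted
#'   `archetypoid_model`/`archetype_model` (its `A` is used).
#' @param X Optional data whose `row_id` column labels the output.
#' @return A `profile_assignment` tibble (see [mahalanobis_allocate()]);
#'   the alpha matrix is kept in attribute `"alphas"`.
#' @export
alpha_allocate <- function(A, X = NULL) {
  if (inherits(A, c("archetypoid_model", "archetype_model"))) A <- A$A
  A <- as.matrix(A)
  labels <- max.col(A, ties.method = "first")
  out <- new_profile_assignment(X, labels,
    d2 = rep(NA_real_, length(labels)),
    distances = NULL, method = "alpha_max"
  )
  attr(out, "alphas") <- A
  out
}

new_profile_assignment <- function(X, labels, d2, distances, method) {
  row_id <- if (is.data.frame(X) && "row_id" %in% names(X)) {
    X$row_id
  } else {
    seq_along(labels)
  }
  structure(
    tibble::tibble(row_id = row_id, profile = as.integer(labels), d2 = d2),
    class = c("profile_assignment", class(tibble::tibble())),
    distances = distances, method = method
  )
}

# Coerce labels input: a profile_assignment tibble or a plain vector.
assignment_labels <- function(labels) {
  if (inherits(labels, "profile_assignment")) {
    return(labels$profile)
  }
  as.integer(labels)
}

#' Survey-weighted profile frequencies
#'
#' `share_j = sum of weights in profile j / total weight`. Profiles with
#' no members are reported with zero share rather than dropped.
#'
#' @param labels A `profile_assignment` or an integer label vector.
#' @param weights Positive calibration weights (default: equal).
#' @param k Number of profiles; defaults to `max(labels)`.
#' @return A tibble with `profile`, `n` (unweighted count), `share_unweighted`,
#'   `weighted_n` and `share`.
#' @export
#' @examples
#' weighted_profile_frequencies(c(1, 1, 2), weights = c(1, 1, 2))
weighted_profile_frequencies <- function(labels, weights = NULL, k = NULL) {
  lab <- assignment_labels(labels)
  w <- aligned_weights(NULL, weights, length(lab))
  k <- as.integer(k %||% max(lab))
  tibble::tibble(profile = seq_len(k)) |>
    dplyr::left_join(
      tibble::tibble(profile = lab, w = w) |>
        dplyr::group_by(.data$profile) |>
        dplyr::summarise(n = dplyr::n(), weighted_n = sum(.data$w), .groups = "drop"),
      by = "profile"
    ) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      weighted_n = dplyr::coalesce(.data$weighted_n, 0),
      share_unweighted = .data$n / sum(.data$n),
      share = .data$weighted_n / sum(.data$weighted_n)
    ) |>
    dplyr::select("profile", "n", "share_unweighted", "weighted_n", "share")
}

#' Extrapolate profile shares to a population total
#'
#' `count_j = share_j * total_population`; the counts conserve the total.
#'
#' @param shares A frequency tibble from [weighted_profile_frequencies()]
#'   (its `share` column is used) or a numeric vector of shares summing to 1.
#' @param total_population Total population represented by the survey
#'   (e.g. 448e6 inhabitants for the 27 surveyed countries).
#' @return A tibble with `profile`, `share` and `population`.
#' @export
population_extrapolation <- function(shares, total_population) {
  stopifnot(total_population > 0)
  if (is.data.frame(shares)) {
    profile <- shares$profile
    s <- shares$share
  } else {
    profile <- seq_along(shares)
    s <- as.numeric(shares)
  }
  if (abs(sum(s) - 1) > 1e-6) abort("`shares` must sum to 1.")
  tibble::tibble(profile = profile, share = s, population = s * total_population)
}

#' Weighted profile-by-group cross-tabulation
#'
#' Weighted share of each profile within each group level (rows of the
#' `share_in_group` normalisation sum to 1 per level) and the transpose
#' normalisation (`share_in_profile`: group composition within each
#' profile). Empty cells are reported with zero weight.
#'
#' @param labels A `profile_assignment` or integer label vector.
#' @param group_values Vector of group levels aligned with `labels`.
#' @param weights Positive weights (default: equal).
#' @param k Number of profiles; defaults to `max(labels)`.
#' @return A tibble with `group`, `profile`, `weighted_n`,
#'   `share_in_group`, `share_in_profile`.
#' @export
profile_crosstab <- function(labels, group_values, weights = NULL, k = NULL) {
  lab <- assignment_labels(labels)
  if (length(group_values) != length(lab)) {
    abort("`group_values` must align with `labels`.")
  }
  w <- aligned_weights(NULL, weights, length(lab))
  k <- as.integer(k %||% max(lab))
  tibble::tibble(group = group_values, profile = lab, w = w) |>
    dplyr::group_by(.data$group, .data$profile) |>
    dplyr::summarise(weighted_n = sum(.data$w), .groups = "drop") |>
    tidyr::complete(
      group = unique(group_values), profile = seq_len(k),
      fill = list(weighted_n = 0)
    ) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(share_in_group = .data$weighted_n / sum(.data$weighted_n)) |>
    dplyr::group_by(.data$profile) |>
    dplyr::mutate(
      share_in_profile = ifelse(sum(.data$weighted_n) > 0,
        .data$weighted_n / sum(.data$weighted_n), 0
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group, .data$profile)
}

#' Per-cluster weighted indicator summaries
#'
#' For each profile and indicator: unweighted and weighted counts, the
#' weighted mean and the weighted quartiles (left-continuous inverse
#' weighted ECDF). Used to confirm that the members of each profile
#' maintain the characteristics of their archetypoid.
#'
#' @param X Data (`indicator_tbl` or matrix).
#' @param labels A `profile_assignment` or integer label vector.
#' @param weights Positive weights (default: the `weight` column of `X`,
#'   else equal).
#' @return A tibble with one row per profile and indicator.
#' @export
cluster_summary_stats <- function(X, labels, weights = NULL) {
  Xm <- as_indicator_matrix(X)
  lab <- assignment_labels(labels)
  if (length(lab) != nrow(Xm)) abort("`labels` must align with the rows of `X`.")
  w <- aligned_weights(X, weights, nrow(Xm))
  nms <- colnames(Xm) %||% paste0("ind_", seq_len(ncol(Xm)))
  colnames(Xm) <- nms
  long <- tibble::as_tibble(Xm)
  long$.profile <- lab
  long$.w <- w
  long |>
    tidyr::pivot_longer(dplyr::all_of(nms),
      names_to = "indicator", values_to = "value"
    ) |>
    dplyr::group_by(profile = .data$.profile, .data$indicator) |>
    dplyr::summarise(
      n = dplyr::n(),
      weighted_n = sum(.data$.w),
      mean = sum(.data$.w * .data$value) / sum(.data$.w),
      q25 = weighted_quantile(.data$value, .data$.w, 0.25),
      median = weighted_quantile(.data$value, .data$.w, 0.5),
      q75 = weighted_quantile(.data$value, .data$.w, 0.75),
      .groups = "drop"
    ) |>
    dplyr::mutate(indicator = factor(.data$indicator, levels = nms)) |>
    dplyr::arrange(.data$profile, .data$indicator)
}

#' Full profile report for an allocated survey
#'
#' Convenience wrapper producing the stage-3 analytics in one call:
#' weighted and unweighted profile frequencies, an optional population
#' extrapolation, profile-by-descriptive cross-tabs for every descriptive
#' column present, and per-cluster indicator summaries.
#'
#' @param X An `indicator_tbl` (weights and descriptives are taken from it).
#' @param assignment A `profile_assignment`.
#' @param total_population Optional population total for extrapolation.
#' @return A `profile_summary` list of tibbles: `frequencies`,
#'   `population` (or `NULL`), `crosstabs` (named list), `cluster_stats`.
#' @export
profile_summary <- function(X, assignment, total_population = NULL) {
  stopifnot(inherits(assignment, "profile_assignment"))
  w <- aligned_weights(X, NULL, nrow(X))
  freq <- weighted_profile_frequencies(assignment, w)
  pop <- if (!is.null(total_population)) {
    population_extrapolation(freq, total_population)
  }
  descr <- intersect(c("gender", "age_group", "country"), names(X))
  crosstabs <- lapply(
    setNames(descr, descr),
    function(d) profile_crosstab(assignment, X[[d]], w)
  )
  structure(
    list(
      frequencies = freq, population = pop, crosstabs = crosstabs,
      cluster_stats = cluster_summary_stats(X, assignment, w)
    ),
    class = "profile_summary"
  )
}

#' @export
print.profile_summary <- function(x, ...) {
  cat("Profile summary\n\nWeighted frequencies:\n")
  print(x$frequencies)
  if (!is.null(x$population)) {
    cat("\nPopulation extrapolation:\n")
    print(x$population)
  }
  cat(
    "\nCross-tabs:", paste(names(x$crosstabs), collapse = ", "),
    "\nCluster stats:", nrow(x$cluster_stats), "profile x indicator rows\n"
  )
  invisible(x)
}

#' Join a published per-country stringency column
#'
#' Attaches an externally published government-response stringency value
#' (a 0-100 composite of restriction measures) to a per-country table.
#' The index is ingested as given — never computed here.
#'
#' @param data A tibble with a `country` column (e.g. a country cross-tab).
#' @param stringency A tibble with columns `country` and one numeric
#'   stringency column (e.g. `max_index`).
#' @return `data` with the stringency column(s) joined on `country`.
#' @export
join_stringency <- function(data, stringency) {
  if (!"country" %in% names(data) || !"country" %in% names(stringency)) {
    abort("Both inputs need a `country` column.")
  }
  dplyr::left_join(data, stringency, by = "country")
}
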