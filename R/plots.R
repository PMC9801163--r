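#' Scree plot of reconstruction RSS against k
#'
#' @param object A `scree_tbl` from [scree_rss()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scree_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$rss)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(
      x = "Number of archetypes k", y = "RSS",
      title = "Reconstruction RSS scree",
      subtitle = paste0("method: ", attr(object, "method") %||% "archetypes")
    ) +
    ggplot2::theme_minimal()
}

#' Indicator profile of each archetypoid
#'
#' One line per archetypoid across the indicators, on the common 0-10
#' scale (higher = worse situation).
#'
#' @param object An `archetypoid_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.archetypoid_model <- function(object, ...) {
  td <- tidy(object)
  td$indicator <- factor(td$indicator, levels = unique(td$indicator))
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$indicator, y = .data$value,
    group = factor(.data$profile), colour = factor(.data$profile)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = NULL, y = "Indicator value (0-10, higher = worse)",
      colour = "Archetypoid", title = "Archetypoid indicator profiles"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}

#' Bar chart of weighted profile frequencies
#'
#' @param frequencies Output of [weighted_profile_frequencies()].
#' @return A ggplot.
#' @export
plot_profile_frequencies <- function(frequencies) {
  ggplot2::ggplot(frequencies, ggplot2::aes(
    x = factor(.data$profile), y = .data$share
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) paste0(round(100 * v, 1), "%")) +
    ggplot2::labs(
      x = "Profile", y = "Weighted share",
      title = "Frequency distribution of the profiles"
    ) +
    ggplot2::theme_minimal()
}

#' Stacked bars of profile composition by group
#'
#' @param crosstab Output of [profile_crosstab()].
#' @param share Which normalisation to plot: `"share_in_group"` (default)
#'   or `"share_in_profile"`.
#' @return A ggplot.
#' @export
plot_profile_crosstab <- function(crosstab, share = "share_in_group") {
  stopifnot(share %in% c("share_in_group", "share_in_profile"))
  ggplot2::ggplot(crosstab, ggplot2::aes(
    x = .data$group, y = .data[[share]], fill = factor(.data$profile)
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = NULL, y = "Weighted share", fill = "Profile",
      title = "Distribution of profiles by group"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}
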