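# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
eval_with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

#' Weighted quantiles by the left-continuous inverse weighted ECDF
#'
#' `Q(p)` is the smallest observed value `x` whose cumulative normalised
#' weight reaches `p`. With equal weights this coincides with
#' [stats::quantile()] type 1. This is the quantile rule used throughout
#' the package's weighted descriptive summaries.
#'
#' @param x Numeric values.
#' @param w Positive weights, same length as `x` (default: equal weights).
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles (unnamed), one per `prob`.
#' @export
#' @examples
#' weighted_quantile(c(1, 2, 3, 10), probs = c(0.25, 0.5, 0.75))
weighted_quantile <- function(x, w = NULL, probs = c(0.25, 0.5, 0.75)) {
  w <- w %||% rep(1, length(x))
  stopifnot(length(x) == length(w), all(w > 0), all(probs >= 0 & probs <= 1))
  if (length(x) == 0L) {
    return(rep(NA_real_, length(probs)))
  }
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) {
    if (p <= 0) return(x[1L])
    x[which(cw >= p - 1e-12)[1L]]
  }, numeric(1))
}

# Extract the numeric indicator matrix from an indicator tibble or a matrix.
as_indicator_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (inherits(x, "indicator_tbl") || is.data.frame(x)) {
    nms <- attr(x, "indicator_names")
    if (is.null(nms)) {
      nms <- setdiff(names(x), c("row_id", "weight", "country", "gender", "age_group"))
      nms <- nms[vapply(x[nms], is.numeric, logical(1))]
    }
    return(as.matrix(as.data.frame(x)[, nms, drop = FALSE]))
  }
  abort("`x` must be a numeric matrix or an indicator tibble.")
}

# Weights aligned with X, defaulting to 1.
aligned_weights <- function(x, weights, n) {
  w <- weights
  if (is.null(w) && is.data.frame(x) && "weight" %in% names(x)) w <- x$weight
  w <- w %||% rep(1, n)
  if (length(w) != n) abort("`weights` must have one entry per row.")
  if (any(!is.finite(w)) || any(w <= 0)) abort("`weights` must be positive and finite.")
  w
}
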