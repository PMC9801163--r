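#' Simplex-constrained least squares
#'
#' Finds the convex-combination weights `w` (non-negative, summing to 1)
#' of the basis rows that best reconstruct the target row in squared
#' Euclidean norm. Solved by active-set non-negative least squares on a
#' system augmented with a sum-to-one row (scaled by `200 * max|target|`),
#' followed by exact renormalisation.
#'
#' @param target Numeric vector of length `m`.
#' @param basis `k x m` matrix whose rows span the candidate mixtures.
#' @return Numeric weight vector of length `k`, with the achieved squared
#'   residual in attribute `"rss"`.
#' @export
#' @examples
#' solve_simplex_ls(c(1, 1), rbind(c(0, 0), c(2, 2)))
solve_simplex_ls <- function(target, basis) {
  basis <- as.matrix(basis)
  if (nrow(basis) < 1L) abort("`basis` must have at least one row.")
  if (length(target) != ncol(basis)) {
    abort("`target` length must match the number of basis columns.")
  }
  res <- cpp_alphas(matrix(as.numeric(target), nrow = 1L), basis)
  w <- drop(res$A)
  attr(w, "rss") <- res$resid[1L]
  w
}

#' Optimal mixture weights of every row against fixed archetypes
#'
#' Row `i` of the result is [solve_simplex_ls()] of `x_i` against the rows
#' of `Z`; rows are independent. This is also the allocation device behind
#' the alpha-max rule.
#'
#' @param X Data: an `indicator_tbl` or an `n x m` matrix.
#' @param Z `k x m` matrix of archetypes or archetypoids.
#' @return An `n x k` matrix `A` with rows on the simplex.
#' @export
compute_alphas <- function(X, Z) {
  X <- as_indicator_matrix(X)
  Z <- as.matrix(Z)
  if (nrow(Z) < 1L) abort("`Z` must have at least one row.")
  if (ncol(Z) != ncol(X)) abort("`X` and `Z` must have the same number of columns.")
  cpp_alphas(X, Z)$A
}

#' Residual sum of squares of a convex reconstruction
#'
#' `sum_i || x_i - sum_j alpha_ij z_j ||^2`: the total squared Euclidean
#' error of reconstructing every row as its mixture of the archetypes.
#' Unweighted — calibration weights enter descriptive summaries only,
#' never the fitting objective.
#'
#' @param X Data matrix (or `indicator_tbl`).
#' @param Z `k x m` archetype matrix.
#' @param A `n x k` mixture-weight matrix.
#' @return Non-negative scalar.
#' @export
rss <- function(X, Z, A) {
  X <- as_indicator_matrix(X)
  sum((X - A %*% as.matrix(Z))^2)
}

#' Fit continuous archetypes by alternating simplex least squares
#'
#' Cutler-Breiman-style archetypal analysis: alternately solve the
#' per-row mixture weights `A` given archetypes `Z`, update `Z`
#' unconstrained given `A`, and project each archetype back into the
#' convex hull of the data through a simplex-constrained `beta` row
#' (`Z = B X`). A candidate iteration is accepted only if it lowers the
#' RSS, so the recorded RSS path is non-increasing; iteration stops when
#' the relative improvement falls below `tol`. The best of `n_restarts`
#' random initialisations (k distinct data rows) is returned.
#'
#' @param X Data: an `indicator_tbl` or `n x m` matrix.
#' @param k Number of archetypes, `1 <= k <= n`.
#' @param tol Relative RSS improvement threshold.
#' @param max_iter Maximum alternating iterations per restart.
#' @param n_restarts Number of random initialisations.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param init Optional `k x m` starting archetype matrix (warm start);
#'   when supplied, restarts are skipped.
#' @return An `archetype_model`: list with `Z` (`k x m`), `A` (`n x k`),
#'   `B` (`k x n`), `rss`, `rss_path`, `k`, `n_iter`, `converged`.
#' @export
#' @examples
#' X <- rbind(c(0, 0), c(10, 0), c(5, 0), c(2, 0))
#' fit_archetypes(X, k = 2, seed = 1)$Z
fit_archetypes <- function(X, k, tol = 1e-6, max_iter = 200, n_restarts = 5,
                           seed = 1, init = NULL) {
  X <- as_indicator_matrix(X)
  n <- nrow(X)
  if (!all(is.finite(X))) abort("`X` must be finite.")
  if (k < 1 || k > n) abort("`k` must satisfy 1 <= k <= nrow(X).")
  if (max_iter < 1) abort("`max_iter` must be at least 1.")

  # degenerate data: every row identical
  if (all(abs(sweep(X, 2, X[1L, ])) < 1e-12)) {
    Z <- X[rep(1L, k), , drop = FALSE]
    A <- matrix(1 / k, n, k)
    B <- matrix(0, k, n)
    B[, 1L] <- 1
    return(new_archetype_model(Z, A, B,
      rss = 0, rss_path = 0, k = k,
      n_iter = 0L, converged = TRUE, X = X
    ))
  }

  runs <- if (!is.null(init)) {
    init <- as.matrix(init)
    stopifnot(nrow(init) == k, ncol(init) == ncol(X))
    list(cpp_fit_archetypes_run(X, init, tol, max_iter))
  } else {
    starts <- eval_with_seed(seed, {
      lapply(seq_len(n_restarts), function(r) sample.int(n, k))
    })
    lapply(starts, function(idx) {
      cpp_fit_archetypes_run(X, X[idx, , drop = FALSE], tol, max_iter)
    })
  }
  best <- runs[[which.min(vapply(runs, function(r) r$rss, numeric(1)))]]
  new_archetype_model(best$Z, best$A, best$B,
    rss = best$rss,
    rss_path = best$rss_path, k = k, n_iter = best$n_iter,
    converged = best$converged, X = X
  )
}

new_archetype_model <- function(Z, A, B, rss, rss_path, k, n_iter, converged, X) {
  colnames(Z) <- colnames(X)
  structure(
    list(
      Z = Z, A = A, B = B, rss = rss, rss_path = as.numeric(rss_path),
      k = as.integer(k), n_iter = as.integer(n_iter),
      converged = isTRUE(converged)
    ),
    class = "archetype_model"
  )
}

#' @export
print.archetype_model <- function(x, ...) {
  cat(
    "Continuous archetype model: k =", x$k, "| RSS =", format(x$rss, digits = 6),
    "|", x$n_iter, "iterations", if (x$converged) "(converged)" else "(max_iter)", "\n"
  )
  invisible(x)
}

#' @rdname fit_archetypes
#' @param x An `archetype_model`.
#' @param ... Unused.
#' @export
tidy.archetype_model <- function(x, ...) {
  Z <- x$Z
  nms <- colnames(Z) %||% paste0("ind_", seq_len(ncol(Z)))
  tibble::tibble(
    archetype = rep(seq_len(nrow(Z)), times = ncol(Z)),
    indicator = rep(nms, each = nrow(Z)),
    value = as.numeric(Z)
  )
}

#' @rdname fit_archetypes
#' @export
glance.archetype_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, rss = x$rss, n_iter = x$n_iter, converged = x$converged
  )
}
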