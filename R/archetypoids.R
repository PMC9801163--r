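#' Number of random subsamples for the subsampled archetypoid search
#'
#' `N = floor(1 + (n - m) / (m - k))`, where `n` is the number of rows,
#' `m` the subsample size and `k` the number of archetypoids. At the
#' configuration used for the full COVID-era survey analysis
#' (`n = 33219`, `m = 10`, `k = 6`) this gives `N = 8303`.
#'
#' @param n Number of data rows.
#' @param subsample_size Subsample size `m` (default 10). Note this `m` is
#'   the subsample size, not the number of indicators.
#' @param k Number of archetypoids; must be smaller than `subsample_size`.
#' @return Integer `N >= 1`.
#' @export
#' @examples
#' num_subsamples(33219, 10, 6)
num_subsamples <- function(n, subsample_size = 10, k) {
  if (subsample_size <= k) {
    abort("`subsample_size` must exceed `k` (the N formula divides by m - k).")
  }
  if (n < subsample_size) abort("`n` must be at least `subsample_size`.")
  as.integer(floor(1 + (n - subsample_size) / (subsample_size - k)))
}

#' Subsampling scheme for [adalara_fit()]
#'
#' @param subsample_size Rows per subsample (default 10).
#' @param n_subsamples Number of subsamples `N`; when `NULL`, computed
#'   from [num_subsamples()] at fit time.
#' @param seed Integer seed governing subsample draws and subsample fits.
#' @return A `subsample_scheme` list.
#' @export
subsample_scheme <- function(subsample_size = 10, n_subsamples = NULL, seed = 1) {
  stopifnot(subsample_size >= 2, is.null(n_subsamples) || n_subsamples >= 1)
  structure(
    list(
      subsample_size = as.integer(subsample_size),
      n_subsamples = if (!is.null(n_subsamples)) as.integer(n_subsamples),
      seed = as.integer(seed)
    ),
    class = "subsample_scheme"
  )
}

#' BUILD phase: initial archetypoid candidates
#'
#' With a fitted continuous archetype model, each archetype is replaced by
#' the nearest data row in Euclidean distance (ties to the lowest index);
#' when two archetypes claim the same row, the later one takes its
#' next-nearest unused row. Without a model, a greedy fallback adds rows
#' one at a time, each minimising the resulting reconstruction RSS.
#'
#' @param X Data (`indicator_tbl` or matrix).
#' @param k Number of archetypoids.
#' @param archetype_model Optional [fit_archetypes()] result at the same `k`.
#' @return Integer vector of `k` distinct row indices.
#' @export
build_phase <- function(X, k, archetype_model = NULL) {
  X <- as_indicator_matrix(X)
  n <- nrow(X)
  if (k < 1 || k > n) abort("`k` must satisfy 1 <= k <= nrow(X).")

  if (!is.null(archetype_model)) {
    stopifnot(inherits(archetype_model, "archetype_model"), archetype_model$k == k)
    idx <- integer(0)
    for (j in seq_len(k)) {
      d2 <- colSums((t(X) - archetype_model$Z[j, ])^2)
      ord <- order(d2, seq_len(n)) # ties -> lowest row index
      idx <- c(idx, ord[!(ord %in% idx)][1L])
    }
    return(idx)
  }

  # greedy fallback: add the row that minimises the subset RSS
  idx <- integer(0)
  for (j in seq_len(k)) {
    cand <- setdiff(seq_len(n), idx)
    sets <- cbind(
      matrix(rep(idx, each = length(cand)), nrow = length(cand)),
      cand
    )
    scores <- cpp_score_subsets(X, sets - 1L)
    idx <- c(idx, cand[which.min(scores)])
  }
  idx
}

#' SWAP phase: best-improvement archetypoid exchanges
#'
#' Repeatedly evaluates every (selected, unselected) exchange and applies
#' the single best strictly-RSS-reducing swap, until no swap improves the
#' RSS by more than `1e-9` relative or 100 sweeps elapse. Ties break
#' toward the lowest candidate row index.
#'
#' @param X Data (`indicator_tbl` or matrix).
#' @param indices Starting set of distinct row indices.
#' @return An `archetypoid_model`; its `trace` tibble logs each applied
#'   swap (sweep, row out, row in, RSS after).
#' @export
swap_phase <- function(X, indices) {
  Xm <- as_indicator_matrix(X)
  indices <- as.integer(indices)
  if (anyDuplicated(indices) || any(indices < 1L | indices > nrow(Xm))) {
    abort("`indices` must be distinct row indices of `X`.")
  }
  res <- cpp_swap_phase(Xm, indices - 1L, 1e-9, 100L)
  idx <- as.integer(res$idx) + 1L
  new_archetypoid_model(
    Xm, idx,
    trace = tibble::tibble(
      sweep = as.integer(res$sweep),
      out = as.integer(res$out) + 1L,
      `in` = as.integer(res[["in"]]) + 1L,
      rss = as.numeric(res$rss_after)
    )
  )
}

new_archetypoid_model <- function(X, indices, trace = NULL, archetypes = NULL) {
  al <- cpp_alphas(X, X[indices, , drop = FALSE])
  structure(
    list(
      indices = indices,
      Z = X[indices, , drop = FALSE],
      A = al$A,
      rss = sum(al$resid),
      k = length(indices),
      trace = trace %||% tibble::tibble(
        sweep = integer(), out = integer(), `in` = integer(), rss = numeric()
      ),
      archetypes = archetypes
    ),
    class = "archetypoid_model"
  )
}

#' Fit archetypoids by continuous initialisation plus BUILD/SWAP
#'
#' The PAM-style archetypoid search: fit continuous archetypes
#' ([fit_archetypes()]), take the nearest observed row to each archetype
#' ([build_phase()]), then locally improve the set by best-improvement
#' exchanges ([swap_phase()]). The archetypoid set is constrained to
#' observed rows (one-hot `beta`), so its RSS is never below the
#' continuous-archetype RSS at the same `k`; the returned model keeps the
#' associated continuous model (refined from the archetypoid solution when
#' that improves it) in `$archetypes`.
#'
#' In addition to the BUILD start, the SWAP search is repeated from
#' `swap_restarts` random index sets (seeded) and the best local optimum
#' is kept: the exchange neighbourhood has genuine local optima on small
#' datasets, and multiple starts make the search reliably reach the
#' exhaustive optimum there.
#'
#' @inheritParams fit_archetypes
#' @param swap_restarts Additional random SWAP starts beyond the BUILD
#'   start.
#' @return An `archetypoid_model`: `indices` (rows of `X` selected as
#'   archetypoids), `Z`, `A`, `rss`, `k`, `trace`, `archetypes`.
#' @export
#' @examples
#' X <- rbind(c(0, 0), c(10, 0), c(5, 1), c(1, 0.5))
#' fit_archetypoids(X, k = 2, seed = 1)$indices
fit_archetypoids <- function(X, k, seed = 1, tol = 1e-6, max_iter = 200,
                             n_restarts = 5, polish = TRUE,
                             swap_restarts = 4) {
  Xm <- as_indicator_matrix(X)
  am <- fit_archetypes(Xm, k,
    tol = tol, max_iter = max_iter,
    n_restarts = n_restarts, seed = seed
  )
  idx0 <- build_phase(Xm, k, am)
  model <- swap_phase(Xm, idx0)
  if (swap_restarts > 0) {
    starts <- eval_with_seed(seed + 1000003L, {
      lapply(seq_len(swap_restarts), function(i) sample.int(nrow(Xm), k))
    })
    for (st in starts) {
      alt <- swap_phase(Xm, st)
      if (alt$rss < model$rss) model <- alt
    }
  }
  if (polish) {
    # continuous refinement from the archetypoid solution: guarantees the
    # constrained fit never undercuts the stored continuous fit
    ref <- cpp_fit_archetypes_run(Xm, model$Z, tol, max_iter)
    if (ref$rss < am$rss) {
      am <- new_archetype_model(ref$Z, ref$A, ref$B,
        rss = ref$rss,
        rss_path = ref$rss_path, k = k, n_iter = ref$n_iter,
        converged = ref$converged, X = Xm
      )
    }
  }
  model$archetypes <- am
  model
}

#' Subsampled archetypoid search for large samples
#'
#' CLARA-style subsampling around the PAM-based archetypoid search: the
#' first of `N` seeded subsamples holds `subsample_size` rows drawn from
#' a random permutation of the data; every later subsample carries the
#' incumbent `k` archetypoids plus the next `subsample_size - k` fresh
#' rows of the permutation, so the `N` of [num_subsamples()] is exactly
#' the number of subsamples needed to sweep the whole dataset once.
#' Archetypoids are fitted on each subsample ([fit_archetypoids()]),
#' mapped back to full-data row indices, and every candidate set is
#' scored by its full-data RSS (optimal alphas over all `n` rows); the
#' best-scoring set becomes the incumbent and is returned at the end.
#'
#' @param X Data (`indicator_tbl` or matrix).
#' @param k Number of archetypoids.
#' @param scheme A [subsample_scheme()].
#' @param n_restarts Restarts for each subsample's continuous
#'   initialisation (subsamples are tiny, so few restarts suffice).
#' After the sweep, the incumbent is polished by a restricted full-data
#' SWAP: exchange candidates are limited to the rows worst reconstructed
#' by the incumbent set (`polish_pool` of them), which is where a missed
#' extreme profile necessarily shows up, keeping the polish linear in `n`.
#'
#' @return An `archetypoid_model` for the full data, with the number of
#'   subsamples in attribute `"n_subsamples"` and every candidate set's
#'   full-data RSS in attribute `"candidate_rss"`.
#' @param polish_pool Number of worst-reconstructed rows eligible for the
#'   final restricted SWAP polish (0 disables it).
#' @export
adalara_fit <- function(X, k, scheme = subsample_scheme(), n_restarts = 2,
                        polish_pool = 40) {
  Xm <- as_indicator_matrix(X)
  n <- nrow(Xm)
  m_s <- scheme$subsample_size
  if (m_s <= k) abort("`subsample_size` must exceed `k`.")
  if (n < m_s) abort("`X` must have at least `subsample_size` rows.")
  N <- scheme$n_subsamples %||% num_subsamples(n, m_s, k)

  perm <- eval_with_seed(scheme$seed, sample.int(n))
  fresh_per <- m_s - k
  scores <- numeric(N)
  incumbent <- NULL
  incumbent_rss <- Inf
  for (i in seq_len(N)) {
    rows <- if (i == 1L) {
      perm[seq_len(m_s)]
    } else {
      lo <- m_s + (i - 2L) * fresh_per + 1L
      fresh <- perm[seq.int(lo, length.out = fresh_per)]
      fresh <- fresh[!is.na(fresh)] # permutation exhausted on the last sweep
      unique(c(incumbent, fresh))
    }
    rows <- sort(rows)
    if (length(rows) <= k) {
      scores[i] <- incumbent_rss
      next
    }
    fit <- fit_archetypoids(Xm[rows, , drop = FALSE], k,
      seed = scheme$seed + i, max_iter = 100,
      n_restarts = n_restarts, polish = FALSE, swap_restarts = 0
    )
    candidate <- rows[fit$indices]
    if (!is.null(incumbent) && setequal(candidate, incumbent)) {
      # unchanged set: full-data score already known
      scores[i] <- incumbent_rss
      next
    }
    cand_rss <- cpp_subset_rss(Xm, candidate - 1L)
    scores[i] <- cand_rss
    if (cand_rss < incumbent_rss) {
      incumbent <- candidate
      incumbent_rss <- cand_rss
    }
  }

  if (polish_pool > 0) {
    # continuous refinement of the incumbent: the alternating archetype fit
    # drifts each archetype toward the underlying extreme profile, and the
    # nearest observed rows to the refined archetypes form a new candidate
    am <- fit_archetypes(Xm, k, init = Xm[incumbent, , drop = FALSE], max_iter = 150)
    cand <- build_phase(Xm, k, am)
    cand_rss <- cpp_subset_rss(Xm, cand - 1L)
    if (cand_rss < incumbent_rss) {
      incumbent <- cand
      incumbent_rss <- cand_rss
    }
  }

  # restricted SWAP polish: entries limited to worst-reconstructed rows
  if (polish_pool > 0) {
    for (sweep in seq_len(5L)) {
      al <- cpp_alphas(Xm, Xm[incumbent, , drop = FALSE])
      resid <- al$resid
      pool <- order(resid, decreasing = TRUE)
      pool <- setdiff(pool, incumbent)[seq_len(min(polish_pool, n - k))]
      sets <- do.call(rbind, lapply(seq_len(k), function(j) {
        s <- matrix(rep(incumbent, each = length(pool)), nrow = length(pool))
        s[, j] <- pool
        s
      }))
      sc <- cpp_score_subsets(Xm, sets - 1L)
      best <- which.min(sc)
      if ((incumbent_rss - sc[best]) <= 1e-9 * incumbent_rss) break
      incumbent <- sets[best, ]
      incumbent_rss <- sc[best]
    }
  }

  model <- new_archetypoid_model(Xm, as.integer(incumbent))
  attr(model, "n_subsamples") <- N
  attr(model, "candidate_rss") <- scores
  model
}

#' RSS scree over the number of archetypes
#'
#' Computes the reconstruction RSS for `k = k_min, ..., k_max` with a
#' warm-started sweep: the solution at `k` is augmented with the
#' worst-reconstructed row to initialise `k + 1`, which makes the curve
#' non-increasing by construction. The elbow of this curve is the usual
#' guide for choosing `k`; the choice itself is left to the user.
#' `method = "archetypes"` (default) sweeps the continuous fit — the
#' curve produced when screening large surveys; `method = "archetypoids"`
#' sweeps the constrained fit via warm-started SWAP and is intended for
#' moderate `n` (each sweep is quadratic in `n`).
#'
#' @inheritParams fit_archetypes
#' @param k_min,k_max Range of `k` to sweep.
#' @param method `"archetypes"` or `"archetypoids"`.
#' @return A `scree_tbl` tibble with columns `k` and `rss`.
#' @export
scree_rss <- function(X, k_min = 1, k_max, seed = 1,
                      method = c("archetypes", "archetypoids"),
                      tol = 1e-6, max_iter = 200, n_restarts = 5) {
  method <- match.arg(method)
  Xm <- as_indicator_matrix(X)
  n <- nrow(Xm)
  if (k_min < 1 || k_max > n || k_min > k_max) {
    abort("Require 1 <= k_min <= k_max <= nrow(X).")
  }
  ks <- seq.int(k_min, k_max)
  out <- numeric(length(ks))

  if (method == "archetypes") {
    model <- fit_archetypes(Xm, k_min,
      tol = tol, max_iter = max_iter,
      n_restarts = n_restarts, seed = seed
    )
    out[1L] <- model$rss
    for (i in seq_along(ks)[-1L]) {
      resid <- rowSums((Xm - model$A %*% model$Z)^2)
      warm <- rbind(model$Z, Xm[which.max(resid), ])
      warm_fit <- fit_archetypes(Xm, ks[i],
        tol = tol, max_iter = max_iter,
        seed = seed + i, init = warm
      )
      fresh_fit <- fit_archetypes(Xm, ks[i],
        tol = tol, max_iter = max_iter,
        n_restarts = n_restarts, seed = seed + i
      )
      model <- if (fresh_fit$rss < warm_fit$rss) fresh_fit else warm_fit
      out[i] <- model$rss
    }
  } else {
    model <- fit_archetypoids(Xm, k_min, seed = seed, tol = tol, max_iter = max_iter)
    out[1L] <- model$rss
    for (i in seq_along(ks)[-1L]) {
      resid <- rowSums((Xm - model$A %*% model$Z)^2)
      add <- order(resid, decreasing = TRUE)
      add <- add[!(add %in% model$indices)][1L]
      model <- swap_phase(Xm, c(model$indices, add))
      out[i] <- model$rss
    }
  }

  structure(
    tibble::tibble(k = as.integer(ks), rss = out),
    class = c("scree_tbl", class(tibble::tibble())),
    method = method
  )
}

#' @export
print.archetypoid_model <- function(x, ...) {
  cat(
    "Archetypoid model: k =", x$k, "| rows:", paste(x$indices, collapse = ", "),
    "| RSS =", format(x$rss, digits = 6), "\n"
  )
  invisible(x)
}

#' Tidy an archetypoid model
#'
#' @param x An `archetypoid_model`.
#' @param ... Unused.
#' @return One row per archetypoid and indicator (`profile`, `row`,
#'   `indicator`, `value`).
#' @export
tidy.archetypoid_model <- function(x, ...) {
  Z <- x$Z
  nms <- colnames(Z) %||% paste0("ind_", seq_len(ncol(Z)))
  tibble::tibble(
    profile = rep(seq_len(nrow(Z)), times = ncol(Z)),
    row = rep(x$indices, times = ncol(Z)),
    indicator = rep(nms, each = nrow(Z)),
    value = as.numeric(Z)
  )
}

#' @rdname tidy.archetypoid_model
#' @export
glance.archetypoid_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, rss = x$rss, n_swaps = nrow(x$trace),
    archetype_rss = if (!is.null(x$archetypes)) x$archetypes$rss else NA_real_
  )
}

#' Archetypoid table, one row per profile
#'
#' A wide display table shaped like the published archetypoid matrix: one
#' row per archetypoid, one column per indicator, plus the data row each
#' archetypoid corresponds to. Values are rounded for display only.
#'
#' @param model An `archetypoid_model`.
#' @param digits Decimal places for display (default 1).
#' @return A tibble.
#' @export
archetypoid_table <- function(model, digits = 1) {
  stopifnot(inherits(model, "archetypoid_model"))
  Z <- round(model$Z, digits)
  out <- tibble::as_tibble(Z, .name_repair = "minimal")
  tibble::add_column(out,
    profile = seq_len(model$k), row = model$indices,
    .before = 1L
  )
}
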