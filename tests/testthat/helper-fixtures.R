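# Shared fixtures, built in code at test time.

# A tiny survey tibble with known item codes (2 respondents: all-best and
# all-worst codes on every block).
best_worst_survey <- function() {
  codings <- covid_item_codings()
  best <- lapply(codings$codes, min)
  worst <- lapply(codings$codes, max)
  items <- purrr::map2(best, worst, ~ c(.x, .y))
  names(items) <- codings$name
  tibble::tibble(
    row_id = 1:2, !!!items,
    country = c("Spain", "Sweden"), gender = c("female", "male"),
    age_group = c("50-65", "80+"), weight = c(1, 1)
  )
}

# Exhaustive archetypoid optimum: minimal subset RSS over all C(n, k) sets.
enumerate_archetypoids <- function(X, k) {
  sets <- t(utils::combn(nrow(X), k))
  scores <- vapply(seq_len(nrow(sets)), function(i) {
    Z <- X[sets[i, ], , drop = FALSE]
    rss(X, Z, compute_alphas(X, Z))
  }, numeric(1))
  list(
    indices = sets[which.min(scores), ], rss = min(scores),
    all_rss = scores, sets = sets
  )
}

# Grid search over the simplex (step h) for the best mixture of basis rows.
grid_simplex_ls <- function(target, basis, h = 1e-3) {
  k <- nrow(basis)
  stopifnot(k %in% c(2L, 3L))
  g <- seq(0, 1, by = h)
  W <- if (k == 2L) {
    cbind(g, 1 - g)
  } else {
    W2 <- expand.grid(w1 = g, w2 = g)
    W2 <- W2[W2$w1 + W2$w2 <= 1 + 1e-12, ]
    cbind(W2$w1, W2$w2, pmax(0, 1 - W2$w1 - W2$w2))
  }
  recon <- W %*% basis
  obj <- rowSums((recon - matrix(target, nrow(W), length(target), byrow = TRUE))^2)
  i <- which.min(obj)
  list(weights = W[i, ], rss = obj[i])
}

# Small planted-vertex indicator matrix with exact vertices in rows 1..k.
planted_fixture <- function(n = 60, k = 3, m = 2, seed = 42, noise_sd = 0) {
  sim_cfg <- synthetic_config(
    n_respondents = n, k_true = k, n_indicators = m,
    noise_sd = noise_sd, seed = seed, weight_cv = 0
  )
  v <- make_vertices(k, m, seed = seed)
  lat <- sample_mixtures(sim_cfg, v)
  list(
    X = mixture_to_indicators(lat, noise_sd, seed = seed + 10L),
    latent = lat, config = sim_cfg
  )
}
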