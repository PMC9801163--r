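test_that("the subsample-count formula reproduces the study configuration and edge cases", {
  expect_identical(num_subsamples(33219, 10, 6), 8303L)
  expect_identical(num_subsamples(10, 10, 6), 1L)
  expect_identical(num_subsamples(100, 10, 6), 23L)
  expect_error(num_subsamples(100, 6, 6), "must exceed")
  expect_error(num_subsamples(5, 10, 2), "at least")
})

test_that("BUILD selects exact archetype rows and deduplicates shared nearest rows", {
  X <- rbind(c(0, 0), c(10, 0), c(0, 10), c(3, 3), c(6, 2))
  am <- fit_archetypes(X, 3, seed = 1, max_iter = 500)
  idx <- build_phase(X, 3, am)
  expect_setequal(idx, c(1L, 2L, 3L))

  # two archetypes nearest to the same row: the second takes its next-nearest
  fake <- structure(
    list(Z = rbind(c(0, 0.1), c(0.1, 0)), k = 2L),
    class = "archetype_model"
  )
  idx2 <- build_phase(X, 2, fake)
  expect_equal(idx2[1], 1L)
  expect_true(idx2[2] != 1L)
  expect_equal(length(unique(idx2)), 2L)
})

test_that("greedy BUILD fallback minimises subset RSS at each step", {
  X <- cbind(c(0, 1, 10))
  idx <- build_phase(X, 1)
  # brute force over the 3 candidates: row 2 (value 1) minimises the RSS
  expect_equal(idx, 2L)
})

test_that("SWAP leaves a verified global optimum untouched and logs a strict descent", {
  withr::local_seed(23)
  X <- matrix(runif(16, 0, 10), 8)
  enum <- enumerate_archetypoids(X, 2)
  m <- swap_phase(X, enum$indices)
  expect_equal(nrow(m$trace), 0L)
  expect_setequal(m$indices, enum$indices)
  expect_equal(m$rss, enum$rss, tolerance = 1e-8)

  # from a poor start the applied swaps strictly decrease the RSS
  worst_start <- enum$sets[which.max(enum$all_rss), ]
  m2 <- swap_phase(X, worst_start)
  if (nrow(m2$trace) > 1) expect_true(all(diff(m2$trace$rss) < 0))
  expect_equal(m2$rss, enum$rss, tolerance = 1e-6)
})

test_that("triangle vertices beat interior points for k = 3 from any start", {
  X <- rbind(
    c(0, 0), c(10, 0), c(5, 9), # vertices
    c(5, 3), c(4, 2), c(6, 4) # interior
  )
  for (start in list(c(4L, 5L, 6L), c(1L, 4L, 6L), c(2L, 3L, 5L))) {
    m <- swap_phase(X, start)
    expect_setequal(m$indices, c(1L, 2L, 3L))
  }
  expect_lt(swap_phase(X, c(1L, 2L, 3L))$rss, 1e-12)
})

test_that("k = n selects every row with zero RSS and no swaps", {
  X <- matrix(runif(8, 0, 10), 4)
  m <- swap_phase(X, 1:4)
  expect_equal(sort(m$indices), 1:4)
  expect_equal(m$rss, 0, tolerance = 1e-10)
  expect_equal(nrow(m$trace), 0L)
})

test_that("fit_archetypoids recovers planted vertices and reports a consistent RSS", {
  fx <- planted_fixture(n = 60, k = 3, m = 2, seed = 42, noise_sd = 0)
  m <- fit_archetypoids(fx$X, 3, seed = 1)
  expect_setequal(m$indices, fx$latent$planted_rows)
  expect_lt(m$rss, 1e-10)

  # internal consistency of the reported RSS
  X <- matrix(runif(40, 0, 10), 20)
  m3 <- fit_archetypoids(X, 2, seed = 4)
  expect_equal(m3$rss, rss(X, m3$Z, compute_alphas(X, m3$Z)), tolerance = 1e-8)
  expect_equal(m3$Z, X[m3$indices, , drop = FALSE], ignore_attr = TRUE)
})

test_that("k = 1 archetypoid on (0, 1, 10) is the row minimising total squared distance", {
  m <- fit_archetypoids(cbind(c(0, 1, 10)), 1, seed = 1)
  expect_equal(m$indices, 2L)
})

test_that("archetypoid search attains the enumeration optimum on random small fixtures", {
  withr::local_seed(29)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    m_dim <- sample(1:3, 1)
    k <- sample(1:3, 1)
    X <- matrix(runif(n * m_dim, 0, 10), n)
    fit <- fit_archetypoids(X, k, seed = rep)
    enum <- enumerate_archetypoids(X, k)
    expect_lte(fit$rss, enum$rss * (1 + 1e-6) + 1e-9)
  }
})

test_that("archetypoid RSS never undercuts the continuous archetype RSS at equal k", {
  withr::local_seed(31)
  for (rep in 1:5) {
    X <- matrix(runif(30 * 3, 0, 10), 30)
    k <- sample(1:4, 1)
    fit <- fit_archetypoids(X, k, seed = rep)
    expect_gte(fit$rss, fit$archetypes$rss - 1e-8)
  }
})

test_that("adalara with a single full-size subsample reduces to the direct fit", {
  withr::local_seed(37)
  X <- matrix(runif(10 * 2, 0, 10), 10)
  # the single subsample holds the whole dataset, so the subsampled route
  # collapses to one direct BUILD/SWAP fit with the derived seed
  direct <- fit_archetypoids(X, 3,
    seed = 43, n_restarts = 2, max_iter = 100,
    polish = FALSE, swap_restarts = 0
  )
  sub <- adalara_fit(X, 3, subsample_scheme(10, seed = 42), polish_pool = 0)
  expect_equal(attr(sub, "n_subsamples"), 1L)
  expect_setequal(sub$indices, direct$indices)
  expect_equal(sub$rss, direct$rss, tolerance = 1e-10)
})

test_that("adalara's returned set scores no worse than any evaluated candidate", {
  fx <- planted_fixture(n = 150, k = 3, m = 3, seed = 51, noise_sd = 0.2)
  m <- adalara_fit(fx$X, 3, subsample_scheme(6, seed = 7))
  expect_lte(m$rss, min(attr(m, "candidate_rss")) + 1e-8)
  expect_equal(m$rss, rss(fx$X, m$Z, compute_alphas(fx$X, m$Z)), tolerance = 1e-8)
})

test_that("adalara is deterministic given the scheme seed", {
  fx <- planted_fixture(n = 80, k = 3, m = 2, seed = 61, noise_sd = 0.1)
  m1 <- adalara_fit(fx$X, 3, subsample_scheme(8, seed = 5))
  m2 <- adalara_fit(fx$X, 3, subsample_scheme(8, seed = 5))
  expect_identical(m1$indices, m2$indices)
  expect_equal(m1$rss, m2$rss)
})

test_that("the warm-started scree is non-increasing and collapses at k = n", {
  withr::local_seed(41)
  X <- matrix(runif(12 * 2, 0, 10), 12)
  sc <- scree_rss(X, 1, 12, seed = 1, method = "archetypoids")
  expect_true(all(diff(sc$rss) <= 1e-9))
  expect_lt(sc$rss[12], 1e-9)

  sa <- scree_rss(X, 1, 5, seed = 1, method = "archetypes")
  expect_true(all(diff(sa$rss) <= 1e-9))
})

test_that("the scree shows a pronounced elbow at the true number of planted vertices", {
  fx <- planted_fixture(n = 300, k = 4, m = 5, seed = 71, noise_sd = 0.1)
  sc <- scree_rss(fx$X, 1, 6, seed = 2)
  r <- sc$rss
  expect_lt(r[4] / r[3], 0.5) # sharp drop reaching the true k
  expect_gt(r[5] / r[4], 0.8) # comparatively flat beyond it
  expect_gt((r[5] / r[4]) / (r[4] / r[3]), 10) # the elbow dominates
})

test_that("archetypoid models tidy into profile tables", {
  X <- matrix(runif(20, 0, 10), 10)
  colnames(X) <- c("a", "b")
  m <- fit_archetypoids(X, 2, seed = 1)
  td <- tidy(m)
  expect_named(td, c("profile", "row", "indicator", "value"))
  expect_equal(nrow(td), 4L)
  tab <- archetypoid_table(m)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("profile", "row", "a", "b"))
  gl <- glance(m)
  expect_equal(gl$k, 2L)
})
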