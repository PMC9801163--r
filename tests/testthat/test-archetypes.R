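test_that("simplex least squares solves membership, symmetry and boundary cases", {
  basis <- rbind(c(0, 0, 1), c(1, 1, 1))
  w <- solve_simplex_ls(c(0, 0, 1), basis)
  expect_equal(unname(as.numeric(w)), c(1, 0), tolerance = 1e-8)

  mid <- colMeans(basis)
  w <- solve_simplex_ls(mid, basis)
  expect_equal(unname(as.numeric(w)), c(0.5, 0.5), tolerance = 1e-8)

  # 1-D basis {0, 1}, target 2: projection onto the segment -> (0, 1), rss 1
  w <- solve_simplex_ls(2, rbind(0, 1))
  expect_equal(unname(as.numeric(w)), c(0, 1), tolerance = 1e-10)
  expect_equal(attr(w, "rss"), 1, tolerance = 1e-10)
  g <- grid_simplex_ls(2, rbind(0, 1), h = 1e-4)
  expect_equal(unname(as.numeric(w)), unname(g$weights), tolerance = 1e-3)

  expect_error(solve_simplex_ls(1, matrix(numeric(0), 0, 1)), "at least one row")
})

test_that("simplex LS matches an independent NNLS oracle on random instances", {
  skip_if_not_installed("pracma")
  withr::local_seed(7)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    m <- sample(2:6, 1)
    basis <- matrix(runif(k * m, 0, 10), k)
    target <- runif(m, 0, 10)
    w <- solve_simplex_ls(target, basis)
    # oracle: pracma Lawson-Hanson on the same augmented system
    s <- 200 * max(1, max(abs(target)))
    aug <- rbind(t(basis), s)
    x <- pracma::lsqnonneg(aug, c(target, s))$x
    w_ref <- x / sum(x)
    r_ref <- sum((target - as.numeric(w_ref %*% basis))^2)
    expect_equal(attr(w, "rss"), r_ref, tolerance = 1e-6)
  }
})

test_that("alpha rows against fixed archetypes match the grid-search oracle", {
  withr::local_seed(3)
  Z <- matrix(runif(9, 0, 10), 3)
  X <- matrix(runif(60, 0, 10), 20)
  A <- compute_alphas(X, Z)
  expect_equal(rowSums(A), rep(1, 20), tolerance = 1e-8)
  expect_gte(min(A), -1e-9)
  for (i in 1:20) {
    g <- grid_simplex_ls(X[i, ], Z, h = 1e-3)
    # grid resolution bounds the agreement per weight
    expect_lt(max(abs(unname(A[i, ]) - unname(g$weights))), 1.5e-3)
  }
})

test_that("alpha computation handles one-hot and single-archetype cases", {
  Z <- rbind(c(1, 2), c(8, 9), c(3, 0))
  A <- compute_alphas(Z, Z)
  expect_equal(A, diag(3), tolerance = 1e-8)

  A1 <- compute_alphas(matrix(runif(10), 5), matrix(runif(2), 1))
  expect_equal(as.numeric(A1), rep(1, 5))
})

test_that("rss is the summed squared reconstruction error", {
  # every row an archetype, optimal alphas -> 0
  Z <- rbind(c(0, 0), c(4, 4))
  expect_equal(rss(Z, Z, compute_alphas(Z, Z)), 0, tolerance = 1e-12)
  # single archetype at 0, X = (0, 4): residual 16
  expect_equal(rss(matrix(c(0, 4)), matrix(0), matrix(1, 2, 1)), 16)
  # interior point representable by the two archetypes
  X <- matrix(c(0, 1, 2))
  Z <- matrix(c(0, 2))
  expect_equal(rss(X, Z, compute_alphas(X, Z)), 0, tolerance = 1e-12)
})

test_that("a single archetype converges to the row mean", {
  withr::local_seed(5)
  X <- matrix(runif(40, 0, 10), 20)
  m <- fit_archetypes(X, 1, seed = 1)
  expect_equal(as.numeric(m$Z), colMeans(X), tolerance = 1e-4)
  expect_equal(m$rss, sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-6)
})

test_that("noiseless 1-D endpoint mixtures recover the planted endpoints", {
  withr::local_seed(2)
  X <- cbind(runif(200) * 10)
  X[1] <- 0
  X[2] <- 10
  m <- fit_archetypes(X, 2, seed = 1, max_iter = 600, tol = 1e-14)
  expect_equal(sort(as.numeric(m$Z)), c(0, 10), tolerance = 1e-3)
  expect_lt(m$rss, 1e-6)
})

test_that("the RSS path is monotone non-increasing and constraints hold", {
  withr::local_seed(9)
  X <- matrix(runif(150, 0, 10), 50)
  m <- fit_archetypes(X, 3, seed = 4)
  expect_true(all(diff(m$rss_path) <= 1e-12))
  expect_equal(rowSums(m$A), rep(1, 50), tolerance = 1e-8)
  expect_equal(rowSums(m$B), rep(1, 3), tolerance = 1e-8)
  expect_gte(min(m$A), -1e-9)
  expect_gte(min(m$B), -1e-9)
  # Z = B X within tolerance
  expect_equal(m$Z, m$B %*% X, tolerance = 1e-8, ignore_attr = TRUE)
  # reported rss equals recomputation
  expect_equal(m$rss, rss(X, m$Z, m$A), tolerance = 1e-8)
})

test_that("every archetype lies in the convex hull of the data", {
  withr::local_seed(13)
  X <- matrix(runif(30, 0, 10), 10)
  m <- fit_archetypes(X, 2, seed = 2)
  for (j in 1:2) {
    w <- solve_simplex_ls(m$Z[j, ], X)
    expect_lte(attr(w, "rss"), 1e-6)
  }
})

test_that("1-D fits match a dense grid-search oracle over hull positions", {
  withr::local_seed(17)
  for (rep in 1:6) {
    n <- sample(6:12, 1)
    X <- cbind(runif(n, 0, 10))
    # oracle for k = 2: grid over pairs of archetype positions in the hull
    g <- seq(min(X), max(X), length.out = 121)
    pairs <- expand.grid(z1 = g, z2 = g)
    pairs <- pairs[pairs$z1 <= pairs$z2, ]
    oracle <- min(vapply(seq_len(nrow(pairs)), function(i) {
      lo <- pairs$z1[i]
      hi <- pairs$z2[i]
      sum(pmin((X - lo)^2, (X - hi)^2, ifelse(X >= lo & X <= hi, 0, Inf)))
    }, numeric(1)))
    m <- fit_archetypes(X, 2, seed = rep, max_iter = 2000, tol = 1e-14)
    # the alternating fit approaches the hull extremes asymptotically, so
    # agreement with the oracle is to absolute, not machine, precision
    expect_lte(abs(m$rss - oracle), 1e-3)
  }
})

test_that("degenerate all-identical data returns a zero-RSS model", {
  X <- matrix(5, 8, 3)
  m <- fit_archetypes(X, 2, seed = 1)
  expect_equal(m$rss, 0)
  expect_true(m$converged)
  expect_equal(m$Z, matrix(5, 2, 3), ignore_attr = TRUE)
})

test_that("fit errors on invalid inputs", {
  X <- matrix(runif(10), 5)
  expect_error(fit_archetypes(X, 6), "k")
  expect_error(fit_archetypes(matrix(c(1, NA, 3, 4), 2), 1), "finite")
})

test_that("tidy and glance return the expected shapes", {
  m <- fit_archetypes(matrix(runif(20, 0, 10), 10), 2, seed = 1)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4L)
  expect_named(td, c("archetype", "indicator", "value"))
  gl <- glance(m)
  expect_equal(gl$k, 2L)
  expect_equal(gl$rss, m$rss)
})
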