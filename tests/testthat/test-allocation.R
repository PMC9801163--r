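test_that("the sample covariance matches hand computation and tolerates singularity", {
  X <- rbind(c(0, 0), c(2, 0), c(0, 2))
  S <- covariance_matrix(X)
  expect_equal(S, rbind(c(4 / 3, -2 / 3), c(-2 / 3, 4 / 3)), ignore_attr = TRUE)

  withr::local_seed(1)
  big <- cbind(rnorm(5000), rnorm(5000))
  expect_equal(covariance_matrix(big), diag(2), tolerance = 0.1, ignore_attr = TRUE)

  # constant column: singular S handled through the pseudo-inverse
  Xs <- cbind(c(1, 2, 3, 4), rep(5, 4))
  Z <- Xs[c(1, 4), , drop = FALSE]
  expect_no_error(asg <- mahalanobis_allocate(Xs, Z))
  expect_equal(asg$profile, c(1L, 1L, 2L, 2L))
})

test_that("Mahalanobis allocation reproduces hand-computed distances and labels", {
  # archetypoid rows are assigned to themselves at distance zero
  withr::local_seed(3)
  X <- matrix(runif(40, 0, 10), 20)
  m <- fit_archetypoids(X, 3, seed = 1)
  asg <- mahalanobis_allocate(X, m)
  expect_equal(asg$profile[m$indices], 1:3)
  expect_equal(asg$d2[m$indices], rep(0, 3), tolerance = 1e-10)

  # 1-D, unit variance, archetypoids at 0 and 10: x = 3 is closer to 0
  asg1 <- mahalanobis_allocate(matrix(3), rbind(0, 10), S = matrix(1))
  expect_equal(asg1$profile, 1L)

  # 2-D anisotropic hand computation: S = diag(4, 1)
  asg2 <- mahalanobis_allocate(
    matrix(c(3, 0), 1), rbind(c(0, 0), c(4, 2)),
    S = diag(c(4, 1))
  )
  D2 <- attr(asg2, "distances")
  expect_equal(as.numeric(D2), c(2.25, 4.25))
  expect_equal(asg2$profile, 1L)
})

test_that("allocation agrees exactly with a naive double-loop oracle on 1000 rows", {
  fx <- planted_fixture(n = 1000, k = 4, m = 5, seed = 81, noise_sd = 0.5)
  Z <- fx$X[fx$latent$planted_rows, , drop = FALSE]
  S <- covariance_matrix(fx$X)
  asg <- mahalanobis_allocate(fx$X, Z, S)

  naive <- integer(1000)
  for (i in 1:1000) {
    d <- numeric(4)
    for (l in 1:4) d[l] <- stats::mahalanobis(fx$X[i, ], Z[l, ], S)
    naive[i] <- which.min(d)
  }
  expect_identical(asg$profile, naive)
})

test_that("identity covariance reduces Mahalanobis to Euclidean nearest-archetypoid", {
  fx <- planted_fixture(n = 400, k = 3, m = 4, seed = 91, noise_sd = 0.4)
  Z <- fx$X[fx$latent$planted_rows, , drop = FALSE]
  asg <- mahalanobis_allocate(fx$X, Z, S = diag(4))
  eucl <- apply(fx$X, 1, function(x) which.min(colSums((t(Z) - x)^2)))
  expect_identical(asg$profile, as.integer(eucl))
})

test_that("alpha-max allocation follows the largest mixture weight with low-index ties", {
  A <- rbind(
    c(0, 1, 0),
    c(0.5, 0.5, 0),
    c(0.2, 0.3, 0.5)
  )
  asg <- alpha_allocate(A)
  expect_equal(asg$profile, c(2L, 1L, 3L))
  expect_equal(attr(asg, "method"), "alpha_max")

  # k = 1: everyone in profile 1
  expect_equal(alpha_allocate(matrix(1, 5, 1))$profile, rep(1L, 5))
})

test_that("weighted frequencies, extrapolation and empty profiles behave as stated", {
  f <- weighted_profile_frequencies(c(1, 1, 2))
  expect_equal(f$share, c(2 / 3, 1 / 3))

  f2 <- weighted_profile_frequencies(c(1, 1, 2), weights = c(1, 1, 2))
  expect_equal(f2$share, c(0.5, 0.5))

  # empty profile reported with zero share, not dropped
  f3 <- weighted_profile_frequencies(c(1, 3, 3), k = 4)
  expect_equal(f3$profile, 1:4)
  expect_equal(f3$share, c(1 / 3, 0, 2 / 3, 0))
  expect_equal(sum(f3$share), 1)

  pop <- population_extrapolation(c(0.5, 0.5), 100)
  expect_equal(pop$population, c(50, 50))
  pop2 <- population_extrapolation(1, 448e6)
  expect_equal(pop2$population, 448e6)
  expect_equal(sum(pop$population), 100, tolerance = 1e-6)
  expect_error(population_extrapolation(c(0.6, 0.6), 10), "sum to 1")
})

test_that("cross-tabs normalise within group and within profile and ignore row order", {
  lab <- c(1L, 1L, 2L, 2L, 1L)
  grp <- c("a", "a", "a", "b", "b")
  w <- c(1, 1, 2, 1, 1)
  ct <- profile_crosstab(lab, grp, w)
  a1 <- ct[ct$group == "a" & ct$profile == 1, ]
  expect_equal(a1$share_in_group, 2 / 4)
  expect_equal(a1$share_in_profile, 2 / 3)
  shares_by_group <- tapply(ct$share_in_group, ct$group, sum)
  expect_equal(unname(as.numeric(shares_by_group)), c(1, 1))

  # single group level reduces to the frequency table
  ct1 <- profile_crosstab(lab, rep("all", 5), w)
  expect_equal(ct1$share_in_group, weighted_profile_frequencies(lab, w)$share)

  # permutation invariance
  p <- c(4, 2, 5, 1, 3)
  ct2 <- profile_crosstab(lab[p], grp[p], w[p])
  expect_equal(ct2, ct)
})

test_that("the generator's association tilt is recovered in the cross-tab", {
  cfg <- synthetic_config(
    n_respondents = 3000, k_true = 2, seed = 101,
    concentration = 0.05, assoc = 3, weight_cv = 0.3
  )
  sim <- simulate_survey(cfg)
  dom <- max.col(sim$latent$mixing, ties.method = "first")
  ct <- profile_crosstab(dom, sim$survey$gender, sim$survey$weight)
  tilt1 <- ct$share_in_group[ct$group == default_genders()[1] & ct$profile == 1]
  tilt2 <- ct$share_in_group[ct$group == default_genders()[2] & ct$profile == 1]
  expect_gt(tilt1, tilt2) # profile 1 leans toward the first gender level
})

test_that("cluster summaries equal archetypoid values for singleton profiles and hand-computed quartiles", {
  X <- matrix(c(
    0, 0,
    1, 2,
    2, 4,
    3, 6,
    9, 8
  ), ncol = 2, byrow = TRUE)
  # profile 2 contains only row 5 (its archetypoid)
  lab <- c(1L, 1L, 1L, 1L, 2L)
  st <- cluster_summary_stats(X, lab)
  p2 <- st[st$profile == 2, ]
  expect_equal(p2$mean, c(9, 8))
  expect_equal(p2$median, c(9, 8))

  # equal weights: weighted median equals the type-1 sample median
  p1 <- st[st$profile == 1 & st$indicator == "ind_1", ]
  expect_equal(p1$median, unname(quantile(c(0, 1, 2, 3), 0.5, type = 1)))

  # 5-row fixture with weights (1,1,1,1,4): cumulative shares
  # 0.125, 0.25, 0.375, 0.5, 1 -> Q(.25)=x2, Q(.5)=x4, Q(.75)=x5
  st_w <- cluster_summary_stats(X, rep(1L, 5), weights = c(1, 1, 1, 1, 4))
  w1 <- st_w[st_w$indicator == "ind_1", ]
  expect_equal(w1$q25, 1)
  expect_equal(w1$median, 3)
  expect_equal(w1$q75, 9)
})

test_that("profile means sit closer to their own archetypoid than to any other", {
  fx <- planted_fixture(n = 500, k = 3, m = 4, seed = 111, noise_sd = 0.5)
  Z <- fx$X[fx$latent$planted_rows, , drop = FALSE]
  S <- covariance_matrix(fx$X)
  asg <- mahalanobis_allocate(fx$X, Z, S)
  Sinv <- solve(S)
  for (j in 1:3) {
    mu <- colMeans(fx$X[asg$profile == j, , drop = FALSE])
    d <- vapply(1:3, function(l) {
      delta <- mu - Z[l, ]
      as.numeric(delta %*% Sinv %*% delta)
    }, numeric(1))
    expect_equal(which.min(d), j)
  }
})

test_that("profile_summary assembles coherent stage-3 analytics", {
  sim <- simulate_survey(synthetic_config(n_respondents = 200, k_true = 3, seed = 121))
  X <- build_indicator_matrix(sim$survey)
  m <- fit_archetypoids(X, 3, seed = 1, n_restarts = 2, swap_restarts = 0)
  asg <- mahalanobis_allocate(X, m)
  ps <- profile_summary(X, asg, total_population = 448e6)
  expect_equal(sum(ps$frequencies$share), 1, tolerance = 1e-9)
  expect_equal(sum(ps$population$population), 448e6, tolerance = 1)
  expect_named(ps$crosstabs, c("gender", "age_group", "country"))
  expect_equal(nrow(ps$cluster_stats), 3L * 9L)
})

test_that("a published stringency column joins by country without being computed", {
  tab <- tibble::tibble(country = c("Spain", "Italy"), share = c(0.4, 0.6))
  idx <- tibble::tibble(country = c("Italy", "Spain"), max_index = c(93.7, 85.1))
  out <- join_stringency(tab, idx)
  expect_equal(out$max_index, c(85.1, 93.7))
})
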