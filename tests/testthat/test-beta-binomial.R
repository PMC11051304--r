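test_that("mean/dispersion parameterization and its inverse agree", {
  expect_equal(beta_moments(1, 1), c(mu = 0.5, phi = 1 / 3))
  expect_equal(beta_moments(3, 1), c(mu = 0.75, phi = 0.2))
  expect_equal(beta_moments(1, 4), c(mu = 0.2, phi = 1 / 6))
  expect_equal(beta_params_from_moments(0.5, 1 / 3), c(alpha = 1, beta = 1))
  expect_equal(beta_params_from_moments(0.75, 0.2), c(alpha = 3, beta = 1))
  expect_error(beta_moments(0, 1), "positive")
  expect_error(beta_params_from_moments(0, 0.5), "inside")
  set.seed(3)
  for (i in 1:50) {
    mu <- runif(1, 0.01, 0.99)
    phi <- runif(1, 0.001, 0.95)
    ab <- beta_params_from_moments(mu, phi)
    expect_equal(unname(beta_moments(ab[1], ab[2])), c(mu, phi),
                 tolerance = 1e-12)
  }
})

test_that("group mean is the pooled read ratio", {
  expect_equal(estimate_group_mean(c(3, 7), c(10, 10)), 0.5)
  expect_equal(estimate_group_mean(c(0, 0), c(10, 10)), 0)
  expect_equal(estimate_group_mean(5, 20), 0.25)
  expect_error(estimate_group_mean(integer(0), integer(0)), "zero total")
})

test_that("dispersion estimate matches the grid-search oracle", {
  # spec-style worked case
  meth <- c(2, 8, 5, 5, 3, 7)
  tot <- rep(10, 6)
  mu <- estimate_group_mean(meth, tot)
  expect_equal(mu, 0.5)
  phi_hat <- estimate_dispersion(meth, tot, mu)
  expect_equal(phi_hat, grid_dispersion_oracle(meth, tot, mu),
               tolerance = 1e-3)
  # random small instances
  set.seed(21)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    N <- sample(5:60, k, replace = TRUE)
    x <- rbinom(k, N, runif(1, 0.05, 0.95))
    if (sum(x) == 0 || sum(x) == sum(N)) next
    mu <- estimate_group_mean(x, N)
    expect_equal(estimate_dispersion(x, N, mu),
                 grid_dispersion_oracle(x, N, mu), tolerance = 1e-3)
  }
})

test_that("uninformative cases shrink to the prior mode", {
  pr <- dispersion_prior()
  mode <- exp(-3.39 - 1.08^2)
  expect_equal(prior_mode(pr), mode)
  # a single replicate carries no between-replicate information
  expect_equal(estimate_dispersion(5, 20, 0.25, pr), mode)
  # degenerate pooled mean
  expect_equal(estimate_dispersion(c(0, 0), c(10, 10), 0, pr), mode)
  # identical proportions at huge coverage: under-dispersion evidence
  phi_hat <- estimate_dispersion(c(500, 500), c(1000, 1000), 0.5, pr)
  expect_lt(phi_hat, mode)
})

test_that("the group-mean variance formula evaluates exactly", {
  expect_equal(estimate_group_variance(c(10, 10), 0.5, 0), 0.0125)
  expect_equal(estimate_group_variance(c(10, 10), 0.5, 1), 0.125)
  expect_equal(estimate_group_variance(20, 0.25, 0.1), 0.0271875)
  # monotone non-decreasing in phi
  set.seed(5)
  for (i in 1:30) {
    N <- sample(5:50, sample(2:6, 1), replace = TRUE)
    u <- runif(1, 0.05, 0.95)
    phis <- sort(runif(5))
    v <- vapply(phis, function(p) estimate_group_variance(N, u, p),
                numeric(1))
    expect_true(all(diff(v) >= 0))
  }
})

test_that("fit_all estimates both groups and flags unobservable sites", {
  total <- matrix(20L, 2, 4)
  meth <- matrix(c(10L, 2L, 12L, 3L, 9L, 2L, 11L, 4L), 2, 4)
  ds <- make_ds(c(100L, 150L), meth, total)
  est <- fit_all(ds)
  expect_equal(nrow(est), 2L)
  expect_true(all(est$analyzable))
  expect_equal(est$mu_case[1], (10 + 12) / 40)
  # site missing in all cases -> excluded from ranking
  total2 <- total
  total2[2, 1:2] <- NA
  meth2 <- meth
  meth2[2, 1:2] <- NA
  est2 <- fit_all(make_ds(c(100L, 150L), meth2, total2))
  expect_false(est2$analyzable[2])
  expect_equal(nrow(score_all(est2)), 1L)
})

test_that("swapping group labels swaps the estimates exactly", {
  set.seed(9)
  total <- matrix(rpois(12, 20) + 1L, 2, 6)
  meth <- matrix(rbinom(12, as.vector(total), 0.4), 2, 6)
  ds <- make_ds(c(10L, 20L), meth, total, n_case = 3)
  swapped <- meth_dataset(ds$sites, ds$meth, ds$total,
                          stats::setNames(
                            ifelse(ds$group == "case", "control", "case"),
                            names(ds$group)))
  a <- fit_all(ds)
  b <- fit_all(swapped)
  expect_equal(a$mu_case, b$mu_control)
  expect_equal(a$phi_case, b$phi_control)
  expect_equal(a$var_case, b$var_control)
})

test_that("simulated counts recover mu and rank phi with prior shrinkage", {
  set.seed(31)
  for (mu in c(0.2, 0.5, 0.8)) {
    meds <- vapply(c(0.01, 0.05, 0.15), function(phi) {
      n <- 120
      mh <- ph <- numeric(n)
      for (i in seq_len(n)) {
        N <- rpois(6, 120) + 20L
        x <- rbetabinom(6, N, mu, phi)
        mh[i] <- estimate_group_mean(x, N)
        ph[i] <- estimate_dispersion(x, N, mh[i])
      }
      expect_lt(abs(median(mh) - mu), 0.03)
      # empirical Bayes pulls estimates toward the prior mode, so true
      # dispersions above the mode are underestimated, never inflated
      if (phi >= 0.05) expect_lt(median(ph), phi)
      median(ph)
    }, numeric(1))
    # dispersion ordering is preserved despite the shrinkage
    expect_true(all(diff(meds) > 0))
  }
})
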