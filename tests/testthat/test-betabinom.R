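test_that("pmf matches exact closed-form values", {
  # uniform over 0..e when both shapes are 1
  expect_equal(dbetabinom(0, 1, 1, 1), 0.5)
  expect_equal(dbetabinom(2, 5, 1, 1), 1 / 6)
  # C(3,1)*Be(3,5)/Be(2,3) = 12/35 by direct gamma arithmetic
  expect_equal(dbetabinom(1, 3, 2, 3), 12 / 35)
  # e = 0 carries no information
  expect_equal(dbetabinom(0, 0, 2, 3), 1)
  expect_error(dbetabinom(3, 2, 1, 1), "0 <= m <= e")
  expect_error(dbetabinom(1, 2, -1, 1), "positive")
})

test_that("pmf normalizes and is symmetric under (m, alpha) <-> (e - m, beta)", {
  set.seed(1)
  for (i in 1:20) {
    a <- exp(runif(1, log(0.05), log(50)))
    b <- exp(runif(1, log(0.05), log(50)))
    e <- sample(1:100, 1)
    expect_equal(sum(dbetabinom(0:e, e, a, b)), 1, tolerance = 1e-10)
    m <- sample(0:e, 1)
    expect_equal(dbetabinom(m, e, a, b), dbetabinom(e - m, e, b, a))
  }
})

test_that("log-likelihood sums log pmf terms and stays finite", {
  expect_equal(betabinom_loglik(c(1, 1), c(2, 2), 1, 1), 2 * log(1 / 3))
  expect_equal(betabinom_loglik(c(1, 2), c(3, 5), 2, 3),
               log(dbetabinom(1, 3, 2, 3)) + log(dbetabinom(2, 5, 2, 3)))
  # totality: extreme shapes still give a finite comparable value
  expect_true(is.finite(betabinom_loglik(c(1, 5), c(10, 10), 1e-4, 1e4)))
  expect_error(betabinom_loglik(integer(0), integer(0), 1, 1), "empty")
  expect_error(betabinom_loglik(0, 3, 1, 1), "1 <= m <= e")
})

test_that("observed-window conditioning divides by the observable mass", {
  a <- 2; b <- 3; m <- c(1, 2); e <- c(3, 5)
  plain <- betabinom_loglik(m, e, a, b)
  cond <- betabinom_loglik(m, e, a, b, conditioning = "observed")
  win <- vapply(seq_along(m), function(i) {
    1 - dbetabinom(0, e[i], a, b) - dbetabinom(e[i], e[i], a, b)
  }, 0)
  expect_equal(cond, plain - sum(log(win)))
  expect_error(betabinom_loglik(3, 3, a, b, conditioning = "observed"),
               "m < e")
})

test_that("all-positive patients are excluded but counted", {
  out <- exclude_all_positive(c(2, 1), c(2, 3))
  expect_equal(out$m, 1)
  expect_equal(out$e, 3)
  expect_equal(out$n_excluded, 1L)
  empty <- exclude_all_positive(integer(0), integer(0))
  expect_equal(empty$n_excluded, 0L)
  set.seed(4)
  e <- sample(1:10, 100, replace = TRUE)
  m <- pmin(e, rpois(100, 2) + 1)
  out <- exclude_all_positive(m, e)
  expect_equal(length(out$m), 100 - sum(m == e))
  expect_equal(out$n_excluded, sum(m == e))
})

test_that("MLE recovers generating shapes from observed pN+ pairs", {
  pairs <- sim_pnp_pairs(500, 2, 8,
                         function(n) sample(5:30, n, replace = TRUE),
                         seed = 21)
  fit <- fit_betabinom(pairs$m, pairs$e)
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha - 2) / 2, 0.25)
  expect_lt(abs(fit$beta - 8) / 8, 0.25)
  expect_equal(fit$n_used + fit$n_excluded_all_positive, 500)
})

test_that("MLE attains the brute-force grid maximum", {
  for (seed in c(2, 13)) {
    pairs <- sim_pnp_pairs(200, 1.5, 6,
                           function(n) sample(3:25, n, replace = TRUE),
                           seed = seed)
    fit <- fit_betabinom(pairs$m, pairs$e)
    grid <- grid_argmax_loglik(pairs$m, pairs$e, n_grid = 60)
    expect_gte(fit$log_likelihood, grid$max_ll)
  }
})

test_that("degenerate fitting sets raise a fit error", {
  expect_error(fit_betabinom(c(2, 3), c(2, 3)), "too few usable pairs")
  expect_error(fit_betabinom(1, 5), "too few usable pairs")
  expect_error(fit_betabinom(c(0, 1), c(3, 3)), "1 <= m <= e")
})

test_that("mean-fraction bias shrinks as the fitting set grows", {
  err <- vapply(c(200, 2000), function(n) {
    pairs <- sim_pnp_pairs(n, 2, 8,
                           function(k) sample(5:30, k, replace = TRUE),
                           seed = 101)
    fit <- fit_betabinom(pairs$m, pairs$e)
    abs(fit$alpha / (fit$alpha + fit$beta) - 0.2)
  }, 0)
  expect_lt(err[2], 0.02)
  expect_lt(err[2], err[1] + 0.01)  # no blow-up with size
})

test_that("per-stage cohort fitting uses only pN+ patients of each stratum", {
  sim <- simulate_cohort(synthetic_config(n_patients = 600, seed = 8))
  fits <- fit_cohort(sim$cohort)
  expect_named(fits, as.character(1:4))
  for (t in 1:4) {
    rows <- sim$cohort[sim$cohort$t_stage == t, ]
    npos <- sum(rows$nodes_positive >= 1)
    fit <- fits[[as.character(t)]]
    expect_equal(fit$n_used + fit$n_excluded_all_positive, npos)
    expect_true(fit$converged)
  }
})
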