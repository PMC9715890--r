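test_that("false-negative probability matches closed forms and decreases in e", {
  expect_equal(prob_false_negative(0, 3, 7), 1)
  expect_equal(prob_false_negative(4, 1, 1), 0.2)   # 1/(e+1) when uniform
  expect_equal(prob_false_negative(2, 2, 3), 0.4)   # Be(2,5)/Be(2,3)
  expect_equal(prob_false_negative(5, 2, 3), dbetabinom(0, 5, 2, 3))
  expect_error(prob_false_negative(-1, 1, 1), "non-negative")
  p <- prob_false_negative(0:200, 0.8, 4.5)
  expect_true(all(diff(p) < 0))
})

test_that("false-negative count estimate scales by odds and caps at the pN0 tally", {
  expect_equal(estimate_false_negatives(0.5, 10, 100), 10)
  expect_equal(estimate_false_negatives(0.9, 10, 50), 50)
  expect_equal(estimate_false_negatives(0, 7, 3), 0)
  expect_equal(estimate_false_negatives(1, 7, 3), 3)  # limit of the cap
  expect_error(estimate_false_negatives(1.2, 1, 1), "p_fn")
})

test_that("adjusted rate implements the reclassification identity", {
  # no false negatives: adjusted equals raw
  ar <- adjusted_rate(0, 10, 100)
  expect_equal(ar$adjusted_rate, ar$raw_rate)
  # single e, fn = 10, tp = 10, n = 100
  ar <- adjusted_rate(10, 10, 100)
  expect_equal(ar$raw_rate, 10 / 110)
  expect_equal(ar$adjusted_rate, 20 / 110)
  expect_equal(ar$increase, 10 / 110, tolerance = 1e-12)
  # every pN0 reclassified
  ar <- adjusted_rate(c(5, 7), c(1, 2), c(5, 7))
  expect_equal(ar$adjusted_rate, 1)
  expect_error(adjusted_rate(6, 1, 5), "fn exceeds")
  expect_error(adjusted_rate(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("staging score follows the posterior formula and its limits", {
  # e = 0: prior only
  expect_equal(nodal_staging_score(0, 0.3, 2, 5), 0.7)
  # direct substitution with P(FN | 1) = 0.5 under uniform shapes
  expect_equal(nodal_staging_score(1, 0.243, 1, 1),
               0.757 / (0.757 + 0.243 * 0.5))
  # large e: score approaches 1
  expect_gt(nodal_staging_score(5000, 0.9, 2, 5), 0.999)
  expect_error(nodal_staging_score(3, 0, 1, 1), "rate")
  expect_error(nodal_staging_score(3, 1, 1, 1), "rate")
  nss <- nodal_staging_score(0:200, 0.5, 0.8, 4.5)
  expect_true(all(diff(nss) > 0))
})

test_that("adequate extent search honors the strict threshold and edge cases", {
  # uniform shapes, rate 1/2: score is (e+1)/(e+2), first > 0.9 at e = 9
  expect_equal(adequate_lne(0.5, 1, 1, threshold = 0.9), 9L)
  expect_equal(adequate_lne(0.5, 1, 1, threshold = 0.9, strict = FALSE), 8L)
  # prior already suffices
  expect_warning(e0 <- adequate_lne(0.05, 1, 1, threshold = 0.9), "prior")
  expect_equal(e0, 0L)
  # unattainable within e_max
  out <- adequate_lne(0.99, 0.01, 10, threshold = 0.999, e_max = 5)
  expect_true(is.na(out))
  expect_true(attr(out, "nss_at_e_max") < 0.999)
  # raising the threshold can only require more nodes (or push the
  # answer past the search limit)
  set.seed(6)
  for (i in 1:10) {
    r <- runif(1, 0.2, 0.8); a <- runif(1, 0.3, 3); b <- runif(1, 1, 10)
    e90 <- adequate_lne(r, a, b, threshold = 0.90, e_max = 1000)
    e95 <- adequate_lne(r, a, b, threshold = 0.95, e_max = 1000)
    if (is.na(e90)) {
      expect_true(is.na(e95))
    } else if (!is.na(e95)) {
      expect_gte(e95, e90)
    }
  }
})

test_that("score table passes its structural invariants on a fitted cohort", {
  sim <- simulate_cohort(synthetic_config(n_patients = 400, seed = 12))
  fits <- fit_cohort(sim$cohort)
  tab <- build_nss_table(sim$cohort, fits, e_max = 60)
  rates <- attr(tab, "rates")
  for (t in 1:4) {
    rows <- tab[tab$t_stage == t, ]
    expect_true(all(diff(rows$p_fn) < 0))
    expect_true(all(diff(rows$nss) > 0))
    expect_true(all(rows$fn_est <= rows$n + 1e-12))
    fit <- fits[[as.character(t)]]
    expect_equal(rows$p_fn,
                 prob_false_negative(rows$e, fit$alpha, fit$beta))
    # score at e = 0 equals 1 - adjusted rate
    ar <- rates[[as.character(t)]]
    expect_equal(nodal_staging_score(0, ar$adjusted_rate,
                                     fit$alpha, fit$beta),
                 1 - ar$adjusted_rate)
    expect_gte(ar$adjusted_rate, ar$raw_rate)
    # tallies in the table cover the whole stratum
    expect_equal(sum(rows$tp) + sum(rows$n),
                 sum(sim$cohort$t_stage == t))
  }
  # deeper invasion, higher adjusted prevalence, lower score at fixed e
  adj <- vapply(rates, function(r) r$adjusted_rate, 0)
  e_fix <- 15
  nss_at <- vapply(1:4, function(t) {
    tab$nss[tab$t_stage == t & tab$e == e_fix]
  }, 0)
  expect_equal(order(nss_at), order(-adj))
  expect_error(build_nss_table(sim$cohort, fits[1:3]), "no fit provided")
})
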