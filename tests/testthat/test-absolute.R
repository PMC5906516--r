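test_that("rate_to_probability implements 1 - exp(-rt)", {
  expect_equal(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(0.38, 1), 0.316138590787644,
               tolerance = 1e-12)
  expect_equal(rate_to_probability(50, 1), 1, tolerance = 1e-12)
  expect_equal(rate_to_probability(0.38, 0), 0)
  expect_equal(rate_to_probability(c(0.1, 0.2), 2), 1 - exp(-c(0.2, 0.4)))
  expect_error(rate_to_probability(-0.1, 1), "domain error")
  expect_error(rate_to_probability(0.1, -1), "domain error")
})

test_that("null relative effects reproduce the baseline for every treatment", {
  bfit <- fake_baseline_fit(log(seq(0.2, 0.6, length.out = 50)))
  fit <- fake_nma_fit(c(0, 0, 0), n_draws = 50)
  p <- combine_absolute(bfit, fit, t = 1, n_draws = 50)
  p1 <- 1 - exp(-exp(bfit$draws[, "m"]))
  expect_equal(sort(p[, 1]), sort(p1), tolerance = 1e-12)
  expect_equal(p[, 1], p[, 2])
  expect_equal(p[, 1], p[, 3])
})

test_that("cloglog combination obeys p_k = 1 - (1 - p1)^HR for degenerate draws", {
  # baseline probability 0.17 at 1 year on the cloglog scale
  m <- log(-log(1 - 0.17))
  bfit <- fake_baseline_fit(rep(m, 20), scale = "cloglog")
  fit <- fake_nma_fit(c(0, log(2)), n_draws = 20)
  p <- combine_absolute(bfit, fit, t = 1, n_draws = 20)
  expect_equal(unique(p[, 2]), 1 - (1 - 0.17)^2, tolerance = 1e-12)
  expect_equal(unique(p[, 2]), 0.3111, tolerance = 1e-12)
})

test_that("Poisson combination matches rate_to_probability for degenerate draws", {
  bfit <- fake_baseline_fit(rep(log(0.38), 20))
  fit <- fake_nma_fit(c(0, 0), n_draws = 20, likelihood = "poisson_log")
  p <- combine_absolute(bfit, fit, t = 1, n_draws = 20)
  expect_equal(unique(p[, 2]), rate_to_probability(0.38, 1), tolerance = 1e-12)
})

test_that("baseline scale and model scale must match", {
  bfit <- fake_baseline_fit(0, scale = "logit")
  fit <- fake_nma_fit(c(0, 0), likelihood = "poisson_log")
  expect_error(combine_absolute(bfit, fit), "configuration error")
  fit2 <- fake_nma_fit(c(0, 0), likelihood = "binomial_logit")
  expect_error(combine_absolute(fake_baseline_fit(0), fit2),
               "configuration error")
  # logit + logit is fine and uses the inverse-logit combination
  p <- combine_absolute(bfit, fit2, n_draws = 10)
  expect_equal(unique(p[, 1]), 0.5)
})

test_that("ranking is draw-wise with deterministic tie-breaks", {
  draws <- cbind("1" = rep(0.3, 50), "2" = rep(0.1, 50))
  rk <- rank_treatments(draws)
  expect_equal(rk$median_rank, c(2, 1))
  expect_equal(rk$lower, c(2, 1))
  expect_equal(rk$upper, c(2, 1))
  # all-equal draws: ties broken by treatment code
  tied <- matrix(0.2, 30, 3, dimnames = list(NULL, 1:3))
  expect_equal(rank_treatments(tied)$median_rank, c(1, 2, 3))
  # higher-is-better direction flips the order
  expect_equal(rank_treatments(draws, direction = "higher")$median_rank,
               c(1, 2))
  expect_error(rank_treatments(draws[, 1, drop = FALSE]), "data error")
})

test_that("exchangeable draws rank symmetrically", {
  set.seed(12)
  reps <- 40
  mean_ranks <- matrix(NA_real_, reps, 3)
  for (i in seq_len(reps)) {
    draws <- matrix(rnorm(3 * 300), 300, 3, dimnames = list(NULL, 1:3))
    ranks <- t(apply(draws, 1, rank, ties.method = "first"))
    mean_ranks[i, ] <- colMeans(ranks)
  }
  expect_true(all(abs(colMeans(mean_ranks) - 2) < 0.05))
})

test_that("costs and disutilities are draw-wise linear in the probability", {
  set.seed(7)
  p <- matrix(runif(200, 0, 0.5), 100, 2, dimnames = list(NULL, 1:2))
  inputs <- economic_inputs()
  ct <- expected_cost(p, inputs)
  du <- expected_disutility(p, inputs)
  expect_equal(ct$mean / inputs$cost_per_event, colMeans(p),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(du$mean / inputs$utility_decrement, colMeans(p),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(ct$mean / inputs$cost_per_event,
               du$mean / inputs$utility_decrement, tolerance = 1e-12)
  # doubling the decrement doubles the disutility exactly
  du2 <- expected_disutility(p, economic_inputs(utility_decrement = -0.024))
  expect_equal(du2$mean, du$mean * 2, tolerance = 1e-12)
})

test_that("degenerate probabilities reproduce printed arithmetic", {
  p29 <- matrix(0.29, 10, 1, dimnames = list(NULL, "1"))
  expect_equal(expected_cost(p29)$mean, 96.57, tolerance = 1e-12)
  expect_equal(expected_disutility(p29)$mean, -0.00348, tolerance = 1e-12)
  p0 <- matrix(0, 10, 1, dimnames = list(NULL, "1"))
  expect_equal(expected_cost(p0)$mean, 0)
  expect_equal(expected_disutility(p0)$mean, 0)
  expect_error(expected_cost(matrix(1.2, 2, 1)), "domain error")
})

test_that("events-based costing charges c * r * t instead of c * p", {
  r_draws <- matrix(0.38, 10, 1, dimnames = list(NULL, "1"))
  inputs <- economic_inputs(horizon = 1)
  ct <- expected_cost(r_draws, inputs, events_based = TRUE)
  expect_equal(ct$mean, 333 * 0.38, tolerance = 1e-12)
  # probability-based costing of the same rate is strictly lower
  p <- rate_to_probability(r_draws, 1)
  expect_lt(expected_cost(p, inputs)$mean, ct$mean)
})

test_that("treatments with HR > 1 in every draw cost more than baseline", {
  set.seed(3)
  bfit <- fake_baseline_fit(log(0.38) + rnorm(300, 0, 0.2))
  fit <- fake_nma_fit(c(0, 0.4, -0.4), n_draws = 300)
  p <- combine_absolute(bfit, fit, t = 1, n_draws = 300, seed = 2)
  ct <- expected_cost(p)
  expect_gt(mean(p[, 2]), mean(p[, 1]))
  expect_lt(mean(p[, 3]), mean(p[, 1]))
  expect_equal(order(colMeans(p)), order(ct$mean))
})

test_that("the outcome table assembles all posterior summaries per treatment", {
  net <- simulate_network(basal_insulin_config(seed = 8))$network
  fit <- fit_nma(net, nma_model("poisson_log", "random", mcmc = quick_mcmc(21)))
  bfit <- fit_baseline(net, "log_rate", "random", mcmc = quick_mcmc(22))
  tab <- absolute_outcome_table(bfit, fit, label = "poisson", seed = 5)
  expect_s3_class(tab, "outcome_table")
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$prob_mean >= 0 & tab$prob_mean <= 1))
  expect_true(all(tab$rank_median >= 1 & tab$rank_median <= 8))
  expect_equal(tab$cost_mean, tab$prob_mean * 333, tolerance = 1e-9)
  expect_equal(tab$disutility_mean, tab$prob_mean * -0.012, tolerance = 1e-9)
  expect_equal(sort(unique(tab$treatment)), 1:8)
})
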