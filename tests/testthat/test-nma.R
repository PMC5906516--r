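test_that("fixed-effects Poisson recovers the log count ratio at large counts", {
  net <- single_rate_study(y = c(100, 50), E = c(100, 100))
  fit <- fit_nma(net, nma_model("poisson_log", "fixed", mcmc = quick_mcmc(1)))
  d2 <- mean(fit$draws[, "d[2]"])
  expect_lt(abs(d2 - log(0.5)), 0.05)
  rel <- relative_effects(fit)
  expect_equal(rel$measure[1], "HR")
  expect_lt(abs(rel$median[2] - 0.5), 0.05)
})

test_that("fixed-effects logit recovers the log odds ratio at large counts", {
  net <- single_risk_study(r = c(500, 250), n = c(1000, 1000))
  fit <- fit_nma(net, nma_model("binomial_logit", "fixed", mcmc = quick_mcmc(2)))
  lor <- log((250 / 750) / (500 / 500))
  expect_lt(abs(mean(fit$draws[, "d[2]"]) - lor), 0.05)
  expect_equal(relative_effects(fit)$measure[1], "OR")
})

test_that("cloglog uses follow-up as a log-time offset (per-year hazards)", {
  # same risks observed at T = 0.5 vs T = 1 imply a doubled hazard
  fit1 <- fit_nma(single_risk_study(r = c(300, 300), n = c(1000, 1000),
                                    followup = 1),
                  nma_model("binomial_cloglog", "fixed", mcmc = quick_mcmc(3)))
  fit2 <- fit_nma(single_risk_study(r = c(300, 300), n = c(1000, 1000),
                                    followup = 0.5),
                  nma_model("binomial_cloglog", "fixed", mcmc = quick_mcmc(3)))
  mu1 <- mean(fit1$draws[, "mu[1]"])
  mu2 <- mean(fit2$draws[, "mu[1]"])
  expect_equal(mu2 - mu1, log(2), tolerance = 0.05)
})

test_that("identical seeds give identical posterior summaries", {
  net <- simulate_network(basal_insulin_config(seed = 4))$network
  spec <- nma_model("shared", "random", mcmc = quick_mcmc(7))
  f1 <- fit_nma(net, spec)
  f2 <- fit_nma(net, spec)
  expect_identical(f1$draws, f2$draws)
  spec2 <- nma_model("shared", "random", mcmc = quick_mcmc(8))
  f3 <- fit_nma(net, spec2)
  expect_false(identical(f1$draws[, "d[2]"], f3$draws[, "d[2]"]))
})

test_that("model/format mismatches and estimability problems are caught", {
  rate_only <- single_rate_study()
  expect_error(fit_nma(rate_only, nma_model("binomial_logit")),
               "configuration error")
  risk_only <- single_risk_study(r = c(10, 12), n = c(100, 100))
  expect_error(fit_nma(risk_only, nma_model("poisson_log")),
               "configuration error")
  # treatment 3 never observed in risk records
  net <- evidence_network(
    data.frame(code = 1:3, label = c("A", "B", "C")),
    risk = data.frame(study_id = c("s1", "s1"), treatment_code = 1:2,
                      r = c(5, 6), n = c(50, 50), followup = 1),
    rate = data.frame(study_id = c("s2", "s2"), treatment_code = c(1, 3),
                      y = c(4, 6), person_years = c(40, 40)))
  expect_error(fit_nma(net, nma_model("binomial_cloglog")),
               "estimability error")
  # disconnected graph
  disc <- evidence_network(
    data.frame(code = 1:4, label = paste0("T", 1:4)),
    rate = data.frame(study_id = rep(c("s1", "s2"), each = 2),
                      treatment_code = c(1, 2, 3, 4),
                      y = c(5, 6, 7, 8), person_years = 50))
  expect_error(fit_nma(disc, nma_model("poisson_log")), "disconnected")
})

test_that("re-referencing matches per-draw recomputation", {
  net <- simulate_network(basal_insulin_config(seed = 10))$network
  fit <- fit_nma(net, nma_model("poisson_log", "random", mcmc = quick_mcmc(9)))
  rel1 <- relative_effects(fit, reference = 1)
  expect_equal(rel1$median[1], 1)
  expect_equal(rel1$lower[1], 1)
  expect_equal(rel1$upper[1], 1)
  rel2 <- relative_effects(fit, reference = 2)
  # brute-force per-draw oracle for treatment 3 vs treatment 2
  hr32 <- exp(fit$draws[, "d[3]"] - fit$draws[, "d[2]"])
  expect_equal(rel2$median[3], unname(quantile(hr32, 0.5)), tolerance = 1e-12)
  expect_equal(rel2$lower[3], unname(quantile(hr32, 0.025)), tolerance = 1e-12)
  expect_equal(rel2$median[2], 1)
  expect_error(relative_effects(fit, reference = 99), "coding error")
})

test_that("degenerate draws exponentiate exactly", {
  fit <- fake_nma_fit(c(0, log(2)))
  rel <- relative_effects(fit)
  expect_equal(rel$median[2], 2)
  expect_equal(rel$lower[2], 2)
  expect_equal(rel$upper[2], 2)
})

test_that("the inconsistency model frees one parameter per observed comparison", {
  # triangle network: edges 1-2, 1-3, 2-3
  risk <- data.frame(
    study_id = rep(c("s1", "s2", "s3"), each = 2),
    treatment_code = c(1, 2, 1, 3, 2, 3),
    r = c(30, 28, 25, 30, 27, 33), n = 200, followup = 1)
  net <- evidence_network(data.frame(code = 1:3, label = c("A", "B", "C")),
                          risk = risk)
  cons <- fit_nma(net, nma_model("binomial_logit", "fixed", mcmc = quick_mcmc(3)))
  ume <- fit_inconsistency(net, nma_model("binomial_logit", "fixed",
                                          mcmc = quick_mcmc(3)))
  expect_equal(sum(grepl("^d\\[", colnames(cons$draws))) - 1L, 2L)  # d[1] fixed
  expect_length(grep("^dd\\[", colnames(ume$draws)), 3L)
  expect_equal(ume$pair_key, c("1-2", "1-3", "2-3"))
})

test_that("on consistent data the inconsistency model agrees edge-wise", {
  cfg <- generator_config(
    n_treatments = 3, n_studies = 6, true_logHR = c(0, 0.3, -0.3),
    true_sigma = 0, baseline_lograte_mean = log(0.5), baseline_lograte_sd = 0.2,
    followup_range = c(1, 1), n_range = c(2000, 2000),
    format_mix = c(both = 6, risk_only = 0, rate_only = 0), seed = 31)
  net <- simulate_network(cfg)$network
  spec <- nma_model("poisson_log", "fixed", mcmc = quick_mcmc(11))
  cons <- fit_nma(net, spec)
  ume <- fit_inconsistency(net, spec)
  ce <- comparison_effects(cons)
  ue <- comparison_effects(ume)
  for (j in seq_len(nrow(ue))) {
    want <- ce$mean[ce$treatment1 == ue$treatment1[j] &
                    ce$treatment2 == ue$treatment2[j]]
    expect_lt(abs(ue$mean[j] - want), 0.1)
  }
})

test_that("with a single comparison the two structures coincide", {
  net <- single_rate_study(y = c(80, 60), E = c(100, 100))
  spec <- nma_model("poisson_log", "fixed", mcmc = quick_mcmc(12))
  cons <- fit_nma(net, spec)
  ume <- fit_inconsistency(net, spec)
  m1 <- mean(cons$draws[, "d[2]"])
  m2 <- mean(ume$draws[, "dd[1]"])
  joint_se <- sqrt(sd(cons$draws[, "d[2]"])^2 / coda::effectiveSize(coda::mcmc(cons$draws[, "d[2]"])) +
                   sd(ume$draws[, "dd[1]"])^2 / coda::effectiveSize(coda::mcmc(ume$draws[, "dd[1]"])))
  expect_lt(abs(m1 - m2), 4 * joint_se + 0.01)
})

test_that("shared model on an all-rate network reproduces the Poisson model", {
  cfg <- basal_insulin_config(seed = 17)
  cfg$format_mix <- c(both = 0L, risk_only = 0L, rate_only = 20L)
  net <- simulate_network(cfg)$network
  spec <- nma_model("poisson_log", "random", mcmc = quick_mcmc(13))
  pois <- fit_nma(net, spec)
  spec$likelihood <- "shared"
  shared <- fit_nma(net, spec)
  expect_identical(pois$draws[, "d[2]"], shared$draws[, "d[2]"])
  expect_identical(pois$draws[, "sd"], shared$draws[, "sd"])
})

test_that("rate records take precedence in the shared model", {
  sim <- simulate_network(basal_insulin_config(seed = 19))
  fit <- fit_nma(sim$network, nma_model("shared", "random",
                                        mcmc = quick_mcmc(14)))
  idx <- fit$fitted
  both_ids <- names(Filter(function(s) length(s$formats) == 2,
                           sim$network$studies))
  # studies reporting both formats contribute only Poisson points
  expect_true(all(idx$likelihood[idx$study_id %in% both_ids] == "poisson"))
  # risk-only studies contribute binomial points
  risk_only <- setdiff(unique(sim$network$risk$study_id), both_ids)
  expect_true(all(idx$likelihood[idx$study_id %in% risk_only] == "binomial"))
  expect_equal(nrow(idx), 40)  # 16 rate studies + 4 risk-only, two arms each
})

test_that("odds and hazard ratios agree for rare events", {
  cfg <- generator_config(
    n_treatments = 3, n_studies = 8, true_logHR = c(0, 0.4, -0.4),
    true_sigma = 0, baseline_lograte_mean = log(0.015),
    baseline_lograte_sd = 0.1, followup_range = c(1, 1),
    n_range = c(5000, 5000),
    format_mix = c(both = 8, risk_only = 0, rate_only = 0), seed = 23)
  net <- simulate_network(cfg)$network
  logit <- fit_nma(net, nma_model("binomial_logit", "fixed",
                                  mcmc = quick_mcmc(15)))
  clog <- fit_nma(net, nma_model("binomial_cloglog", "fixed",
                                 mcmc = quick_mcmc(15)))
  or <- relative_effects(logit)$median[-1]
  hr <- relative_effects(clog)$median[-1]
  expect_true(all(abs(or / hr - 1) < 0.05))
})

test_that("a three-arm trial fits under the conditional random-effects construction", {
  cfg <- generator_config(
    n_treatments = 4, n_studies = 8, true_logHR = c(0, 0.2, -0.2, 0.1),
    true_sigma = 0.2, baseline_lograte_mean = log(0.4),
    baseline_lograte_sd = 0.3, followup_range = c(0.5, 1.5),
    n_range = c(200, 400), arms_per_study = 3,
    format_mix = c(both = 8, risk_only = 0, rate_only = 0), seed = 27)
  net <- simulate_network(cfg)$network
  fit <- fit_nma(net, nma_model("poisson_log", "random", mcmc = quick_mcmc(16)))
  expect_length(grep("^d\\[", colnames(fit$draws)), 4L)
  expect_true(all(fit$draws[, "sd"] >= 0))
  fs <- compute_fit(fit)
  expect_equal(fs$n_datapoints, 24)
})
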