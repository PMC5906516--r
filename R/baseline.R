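#' Single-arm meta-analysis of reference-treatment arms
#'
#' Estimates the absolute event burden on one treatment (by default the
#' network reference) by pooling its arms across studies on one of three
#' scales:
#' \describe{
#'   \item{logit}{\code{r_i ~ Binomial(n_i, p_i)}, \code{logit(p_i) =
#'     theta_i}: the pooled quantity is a probability of at least one event
#'     over the contributing studies' own follow-ups (no time dimension).}
#'   \item{cloglog}{\code{cloglog(p_i) = log(T_i) + theta_i}: theta is a log
#'     hazard, so the pooled probability refers to a chosen horizon.}
#'   \item{log_rate}{\code{y_i ~ Poisson(E_i exp(theta_i))}: theta is a log
#'     event rate per person-year, allowing repeat events.}
#' }
#' Under random effects \code{theta_i ~ Normal(m, sd_m^2)}; under fixed
#' effects all arms share \code{m}. The reported baseline uses the posterior
#' of the summary mean \code{m} (set \code{predictive = TRUE} in
#' \code{\link{baseline_probability}} draws for a new-study predictive
#' baseline).
#'
#' @param network an \code{\link{evidence_network}} (arms are taken from it),
#'   or a data.frame of arm records in the matching format.
#' @param scale \code{"logit"}, \code{"cloglog"} (risk records) or
#'   \code{"log_rate"} (rate records).
#' @param effects \code{"random"} or \code{"fixed"}.
#' @param treatment treatment code whose arms are pooled (default 1).
#' @param priors a \code{\link{prior_spec}} (uses \code{mu_sd} for m and
#'   \code{sigma_upper} for sd_m).
#' @param mcmc an \code{\link{mcmc_settings}}.
#' @return An object of class \code{baseline_fit} with posterior draws of
#'   \code{m} (and \code{sd_m}), fitted values for deviance computation, and
#'   convergence summaries.
#' @export
fit_baseline <- function(network, scale = c("cloglog", "logit", "log_rate"),
                         effects = c("random", "fixed"), treatment = 1L,
                         priors = prior_spec(), mcmc = mcmc_settings()) {
  scale <- match.arg(scale)
  effects <- match.arg(effects)

  if (inherits(network, "evidence_network")) {
    arms <- if (scale == "log_rate") network$rate else network$risk
    arms <- arms[arms$treatment_code == treatment, , drop = FALSE]
  } else {
    arms <- as.data.frame(network)
  }
  if (!nrow(arms)) stop("data error: no arms for treatment ", treatment,
                        " in the ", scale, " records")
  need <- if (scale == "log_rate") c("y", "person_years") else
    c("r", "n", if (scale == "cloglog") "followup")
  miss <- setdiff(need, names(arms))
  if (length(miss)) stop("configuration error: ", scale,
                         " scale needs column(s): ", paste(miss, collapse = ", "))

  lik <- switch(scale,
    logit = "    r[i] ~ dbin(p[i], n[i])\n    logit(p[i]) <- theta[i]",
    cloglog = paste0("    r[i] ~ dbin(p[i], n[i])\n",
                     "    cloglog(p[i]) <- log(time[i]) + theta[i]"),
    log_rate = "    y[i] ~ dpois(th[i])\n    th[i] <- E[i] * exp(theta[i])")
  eff <- if (effects == "random") "    theta[i] ~ dnorm(m, tau_m)" else
    "    theta[i] <- m"
  tail <- c("  m ~ dnorm(0, prec_m)",
            if (effects == "random") c("  sd_m ~ dunif(0, sd_upper)",
                                       "  tau_m <- pow(sd_m, -2)"))
  code <- paste(c("model {", "  for (i in 1:ns) {", lik, eff, "  }", tail, "}"),
                collapse = "\n")

  data <- list(ns = nrow(arms), prec_m = 1 / priors$mu_sd^2)
  if (scale == "log_rate") {
    data$y <- arms$y
    data$E <- arms$person_years
  } else {
    data$r <- arms$r
    data$n <- arms$n
    if (scale == "cloglog") data$time <- arms$followup
  }
  if (effects == "random") data$sd_upper <- priors$sigma_upper

  monitors <- c("m", if (effects == "random") "sd_m",
                if (scale == "log_rate") "th" else "p")
  res <- run_jags(code, data, monitors, mcmc)

  fitted <- data.frame(
    param = if (scale == "log_rate") sprintf("th[%d]", seq_len(nrow(arms)))
            else sprintf("p[%d]", seq_len(nrow(arms))),
    likelihood = if (scale == "log_rate") "poisson" else "binomial",
    study_id = arms$study_id, treatment_code = arms$treatment_code,
    events = if (scale == "log_rate") arms$y else arms$r,
    size = if (scale == "log_rate") arms$person_years else arms$n)

  conv <- convergence_table(res$chains, c("m", "sd_m"))
  warn <- NULL
  if (any(conv$rhat > 1.05, na.rm = TRUE)) {
    warn <- "split-Rhat above 1.05 for baseline parameters"
    warning(warn, call. = FALSE)
  }
  structure(list(scale = scale, effects = effects, treatment = treatment,
                 draws = res$draws, chains = res$chains, fitted = fitted,
                 convergence = conv, warning = warn),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat("Baseline meta-analysis on the", x$scale, "scale (", x$effects,
      "effects ),", nrow(x$fitted), "arms\n")
  s <- draw_summary(x$draws[, "m"])
  cat(sprintf("  summary mean m: %.3f (95%% CrI %.3f to %.3f)\n",
              s["median"], s["lower"], s["upper"]))
  invisible(x)
}

# Per-draw baseline on the linear-predictor scale.
baseline_m_draws <- function(bfit, predictive = FALSE) {
  m <- bfit$draws[, "m"]
  if (predictive && bfit$effects == "random") {
    m <- m + stats::rnorm(length(m), 0, bfit$draws[, "sd_m"])
  }
  m
}

# Per-draw transformed baseline probability.
baseline_probability_draws <- function(bfit, t = 1, predictive = FALSE) {
  if (t < 0) stop("domain error: t must be >= 0")
  m <- baseline_m_draws(bfit, predictive)
  switch(bfit$scale,
    logit = stats::plogis(m),
    cloglog = ,
    log_rate = 1 - exp(-exp(m) * t))
}

#' Posterior baseline event probability
#'
#' Transforms the posterior of the summary mean \code{m} into an event
#' probability, draw by draw, then summarises: inverse-logit for the logit
#' scale (the horizon is ignored, that model carries no time dimension), and
#' \code{1 - exp(-exp(m) t)} for the cloglog and log-rate scales (constant
#' hazard over the horizon).
#'
#' @param bfit a \code{\link{fit_baseline}} result.
#' @param t horizon in years (>= 0).
#' @param predictive if TRUE, use the predictive distribution for a new study
#'   rather than the posterior of the summary mean.
#' @return A list: \code{mean}, \code{median}, \code{lower}, \code{upper}
#'   (95\% equal-tailed CrI) and the per-draw probabilities in \code{draws}.
#' @export
baseline_probability <- function(bfit, t = 1, predictive = FALSE) {
  stopifnot(inherits(bfit, "baseline_fit"))
  p <- baseline_probability_draws(bfit, t = t, predictive = predictive)
  s <- draw_summary(p)
  list(mean = unname(s["mean"]), median = unname(s["median"]),
       lower = unname(s["lower"]), upper = unname(s["upper"]), draws = p)
}

#' Posterior baseline event rate (log-rate scale only)
#'
#' @param bfit a \code{\link{fit_baseline}} result on the \code{log_rate}
#'   scale.
#' @return A list: \code{mean}, \code{median}, \code{lower}, \code{upper} of
#'   the event rate in events per person-year, and the per-draw rates.
#' @export
baseline_rate <- function(bfit) {
  stopifnot(inherits(bfit, "baseline_fit"))
  if (bfit$scale != "log_rate") {
    stop("configuration error: baseline_rate needs a log_rate fit")
  }
  r <- exp(bfit$draws[, "m"])
  s <- draw_summary(r)
  list(mean = unname(s["mean"]), median = unname(s["median"]),
       lower = unname(s["lower"]), upper = unname(s["upper"]), draws = r)
}
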