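#' Configure the trial-data simulator
#'
#' The simulator draws arm-level trial summaries from a homogeneous Poisson
#' event process with known ground truth, in both reporting formats. Per
#' study i it draws a baseline log event rate \code{mu_i} and (under
#' heterogeneity) a trial-specific log hazard ratio around the true
#' \code{d}; each patient's event count over follow-up \code{T_i} is Poisson
#' with mean \code{lambda * T_i}. The risk summary counts patients with at
#' least one event; the rate summary sums all events over exposure
#' \code{n * T_i}. Both formats therefore derive from the same latent
#' per-patient counts, which is exactly the coherence the shared-parameter
#' model assumes.
#'
#' @param n_treatments number of treatments (code 1 is the reference).
#' @param n_studies number of two-arm studies (see \code{arms_per_study}).
#' @param true_logHR numeric vector of true log hazard ratios versus the
#'   reference, length \code{n_treatments}, first element 0.
#' @param true_sigma between-study SD of the log hazard ratios (>= 0).
#' @param baseline_lograte_mean,baseline_lograte_sd normal distribution of
#'   study baseline log rates (log events per person-year).
#' @param followup_range (min, max) follow-up in years; follow-up is drawn
#'   log-uniformly over the range (trial durations cluster at the short end
#'   in this literature, and a log-uniform draw keeps the mean follow-up
#'   under a year for the default range).
#' @param n_range (min, max) patients randomised per arm.
#' @param format_mix named integer vector \code{c(both=, risk_only=,
#'   rate_only=)}; must sum to \code{n_studies}.
#' @param arms_per_study 2 (default) or 3; with 3, a second comparator is
#'   added to every study.
#' @param labels optional treatment labels.
#' @param seed integer seed.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(n_treatments, n_studies, true_logHR, true_sigma,
                             baseline_lograte_mean, baseline_lograte_sd,
                             followup_range = c(0.5, 2),
                             n_range = c(50, 500),
                             format_mix = c(both = n_studies, risk_only = 0,
                                            rate_only = 0),
                             arms_per_study = 2, labels = NULL, seed = 1) {
  if (length(true_logHR) != n_treatments || true_logHR[1] != 0) {
    stop("config error: true_logHR must have length n_treatments with first element 0")
  }
  if (true_sigma < 0) stop("config error: true_sigma must be >= 0")
  if (!(followup_range[1] > 0) || followup_range[2] < followup_range[1]) {
    stop("config error: invalid followup_range")
  }
  if (!all(c("both", "risk_only", "rate_only") %in% names(format_mix))) {
    stop("config error: format_mix needs counts both/risk_only/rate_only")
  }
  if (sum(format_mix) != n_studies) {
    stop("config error: format_mix must sum to n_studies")
  }
  if (sum(format_mix) == 0) stop("config error: empty format mix")
  stopifnot(arms_per_study %in% c(2, 3), n_treatments >= 2)
  if (is.null(labels)) labels <- paste("treatment", seq_len(n_treatments))
  structure(list(
    n_treatments = as.integer(n_treatments),
    n_studies = as.integer(n_studies),
    true_logHR = as.numeric(true_logHR), true_sigma = true_sigma,
    baseline_lograte_mean = baseline_lograte_mean,
    baseline_lograte_sd = baseline_lograte_sd,
    followup_range = followup_range, n_range = as.integer(n_range),
    format_mix = format_mix[c("both", "risk_only", "rate_only")],
    arms_per_study = as.integer(arms_per_study),
    labels = labels, seed = as.integer(seed)
  ), class = "generator_config")
}

#' Generator configuration emulating the basal-insulin evidence base
#'
#' The motivating evidence base: 20 two-arm randomised trials of 8 basal
#' insulin regimens for type 1 diabetes with severe hypoglycaemia as the
#' outcome, 12 studies reporting both risk and rate, 4 risk-only and 4
#' rate-only, follow-up ranging from 4 weeks to 2 years, a reference-arm
#' (glargine once daily) event rate centred at 0.38 events per person-year,
#' modest true effects (|log HR| <= 0.3) and between-study SD 0.3 on the
#' log-hazard scale.
#'
#' @param seed integer seed.
#' @return A \code{\link{generator_config}}.
#' @export
basal_insulin_config <- function(seed = 1) {
  generator_config(
    n_treatments = 8, n_studies = 20,
    true_logHR = c(0, 0.15, -0.25, 0.1, -0.1, 0.2, 0.25, -0.2),
    true_sigma = 0.3,
    baseline_lograte_mean = log(0.38), baseline_lograte_sd = 0.5,
    followup_range = c(4 / 52.18, 2),
    n_range = c(50, 500),
    format_mix = c(both = 12, risk_only = 4, rate_only = 4),
    labels = c("glargine (once)", "NPH (twice)", "detemir (once)",
               "detemir (twice)", "degludec (once)", "NPH (once)",
               "NPH (once/twice)", "detemir (once/twice)"),
    seed = seed
  )
}

#' Simulate an evidence network with known ground truth
#'
#' Study designs cycle the comparator over treatments 2..K against the
#' reference (treatment 1), so every format subset of the default
#' configuration forms a connected star network. Identical seeds give
#' bit-identical output.
#'
#' @param config a \code{\link{generator_config}}.
#' @return An object of class \code{simulated_network}: a list with
#'   \code{network} (an \code{\link{evidence_network}} holding the reported
#'   summaries) and \code{truth} (true \code{d}, \code{sigma}, per-study
#'   \code{mu}, per-arm rates \code{lambda}, and the seed).
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  K <- config$n_treatments
  ns <- config$n_studies
  formats <- rep(c("both", "risk_only", "rate_only"), config$format_mix)

  risk <- list()
  rate <- list()
  truth_mu <- numeric(ns)
  arms <- list()

  for (i in seq_len(ns)) {
    comparator <- ((i - 1L) %% (K - 1L)) + 2L
    trts <- c(1L, comparator)
    if (config$arms_per_study == 3L) {
      second <- (comparator %% (K - 1L)) + 2L
      trts <- c(trts, second)
    }
    mu_i <- stats::rnorm(1, config$baseline_lograte_mean,
                         config$baseline_lograte_sd)
    truth_mu[i] <- mu_i
    # trial-specific deviations share a common study effect so that any pair
    # of contrasts has covariance sigma^2 / 2
    nd <- length(trts) - 1L
    if (config$true_sigma > 0) {
      b <- stats::rnorm(1, 0, config$true_sigma / sqrt(2))
      delta <- config$true_logHR[trts[-1]] +
        b + stats::rnorm(nd, 0, config$true_sigma / sqrt(2))
    } else {
      delta <- config$true_logHR[trts[-1]]
    }
    lr <- stats::runif(1, log(config$followup_range[1]),
                       log(config$followup_range[2]))
    T_i <- exp(lr)
    id <- sprintf("study_%02d", i)
    for (a in seq_along(trts)) {
      n_a <- config$n_range[1] +
        sample.int(config$n_range[2] - config$n_range[1] + 1L, 1L) - 1L
      loglam <- mu_i + if (a == 1) 0 else delta[a - 1]
      lam <- exp(loglam)
      counts <- stats::rpois(n_a, lam * T_i)
      arms[[length(arms) + 1L]] <- data.frame(
        study_id = id, treatment_code = trts[a], lambda = lam, n = n_a,
        followup = T_i)
      if (formats[i] %in% c("both", "risk_only")) {
        risk[[length(risk) + 1L]] <- data.frame(
          study_id = id, treatment_code = trts[a],
          r = sum(counts >= 1L), n = n_a, followup = T_i)
      }
      if (formats[i] %in% c("both", "rate_only")) {
        rate[[length(rate) + 1L]] <- data.frame(
          study_id = id, treatment_code = trts[a],
          y = sum(counts), person_years = n_a * T_i)
      }
    }
  }

  treatments <- data.frame(code = seq_len(K), label = config$labels)
  network <- evidence_network(
    treatments,
    risk = if (length(risk)) do.call(rbind, risk) else NULL,
    rate = if (length(rate)) do.call(rbind, rate) else NULL
  )
  truth <- list(d = config$true_logHR, sigma = config$true_sigma,
                mu = truth_mu, arms = do.call(rbind, arms),
                formats = formats, seed = config$seed)
  structure(list(network = network, truth = truth, config = config),
            class = "simulated_network")
}

#' @export
print.simulated_network <- function(x, ...) {
  cat("Simulated evidence network (seed", x$truth$seed, ")\n")
  print(x$network)
  invisible(x)
}

#' Write a simulated network and its ground truth to disk
#'
#' Writes the standard network CSV files (\code{\link{write_network}}) plus a
#' \code{truth.json} sidecar holding the generating values.
#'
#' @param sim a \code{\link{simulate_network}} result.
#' @param dir output directory.
#' @return Invisibly, the files written.
#' @export
write_simulated <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_network"))
  files <- write_network(sim$network, dir)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(d = sim$truth$d, sigma = sim$truth$sigma, mu = sim$truth$mu,
         lambda = sim$truth$arms[, c("study_id", "treatment_code", "lambda")],
         seed = sim$truth$seed),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(files, truth = truth_path))
}
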