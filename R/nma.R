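#' Specify a network meta-analysis model
#'
#' The four likelihood/link combinations for event data:
#' \describe{
#'   \item{\code{binomial_logit}}{risk records; log-odds scale; follow-up
#'     ignored (a patient's chance of a first event is treated as independent
#'     of trial duration).}
#'   \item{\code{binomial_cloglog}}{risk records; complementary log-log link
#'     with the natural log of follow-up (years) as an offset, so parameters
#'     are log-hazards and relative effects are per-year hazard ratios.}
#'   \item{\code{poisson_log}}{rate records; log link over person-years, also
#'     a log-hazard scale.}
#'   \item{\code{shared}}{mixed reporting: risk-only studies contribute via
#'     the cloglog likelihood and studies with rate records via the Poisson
#'     likelihood (rate records are preferred when a study reports both),
#'     all informing common relative-effect parameters d (and a common
#'     heterogeneity SD under random effects).}
#' }
#'
#' @param likelihood one of \code{"binomial_logit"}, \code{"binomial_cloglog"},
#'   \code{"poisson_log"}, \code{"shared"}.
#' @param effects \code{"fixed"} or \code{"random"} study effects.
#' @param structure \code{"consistency"} (basic parameters versus the
#'   reference, all other contrasts derived) or \code{"inconsistency"} (one
#'   unrelated mean-effect parameter per observed comparison).
#' @param priors a \code{\link{prior_spec}}.
#' @param mcmc an \code{\link{mcmc_settings}}.
#' @return An object of class \code{nma_model_spec}.
#' @export
nma_model <- function(likelihood = c("binomial_cloglog", "binomial_logit",
                                     "poisson_log", "shared"),
                      effects = c("random", "fixed"),
                      structure = c("consistency", "inconsistency"),
                      priors = prior_spec(), mcmc = mcmc_settings()) {
  structure(list(likelihood = match.arg(likelihood),
                 effects = match.arg(effects),
                 structure = match.arg(structure),
                 priors = priors, mcmc = mcmc),
            class = "nma_model_spec")
}

# ---- data preparation ------------------------------------------------------

# Arrange an arm table into the matrix layout JAGS consumes: one row per
# study, arms ordered by treatment code so column 1 is the study baseline.
arm_matrices <- function(df, value_cols) {
  ids <- unique(df$study_id)
  ns <- length(ids)
  na <- vapply(ids, function(id) sum(df$study_id == id), integer(1))
  mx <- max(na)
  mats <- lapply(value_cols, function(cl) matrix(NA_real_, ns, mx))
  names(mats) <- value_cols
  t_mat <- matrix(NA_integer_, ns, mx)
  rows <- matrix(NA_integer_, ns, mx)  # original row index per cell
  for (i in seq_len(ns)) {
    sub <- df[df$study_id == ids[i], , drop = FALSE]
    ord <- order(sub$treatment_code)
    t_mat[i, seq_len(nrow(sub))] <- sub$treatment_code[ord]
    rows[i, seq_len(nrow(sub))] <- as.integer(rownames(sub))[ord]
    for (cl in value_cols) {
      mats[[cl]][i, seq_len(nrow(sub))] <- sub[[cl]][ord]
    }
  }
  c(list(ids = ids, ns = ns, na = na, t = t_mat, rows = rows), mats)
}

# Records each model consumes. The shared model takes rate records from every
# study that reports them and risk records only from risk-only studies.
model_records <- function(network, likelihood) {
  risk <- network$risk
  rate <- network$rate
  if (likelihood %in% c("binomial_logit", "binomial_cloglog")) {
    if (!nrow(risk)) stop("configuration error: ", likelihood,
                          " requires risk records")
    rownames(risk) <- seq_len(nrow(risk))
    return(list(risk = risk, rate = empty_rate()))
  }
  if (likelihood == "poisson_log") {
    if (!nrow(rate)) stop("configuration error: poisson_log requires rate records")
    rownames(rate) <- seq_len(nrow(rate))
    return(list(risk = empty_risk(), rate = rate))
  }
  # shared
  if (!nrow(risk) && !nrow(rate)) stop("configuration error: no records")
  rate_ids <- unique(rate$study_id)
  risk <- risk[!(risk$study_id %in% rate_ids), , drop = FALSE]
  if (nrow(risk)) rownames(risk) <- seq_len(nrow(risk))
  if (nrow(rate)) rownames(rate) <- seq_len(nrow(rate))
  list(risk = risk, rate = rate)
}

check_estimable <- function(network, records, likelihood) {
  present <- sort(unique(c(records$risk$treatment_code,
                           records$rate$treatment_code)))
  missing <- setdiff(network$treatments$code, present)
  if (length(missing)) {
    stop("estimability error: treatment(s) ", paste(missing, collapse = ", "),
         " do not appear in the records the ", likelihood, " model consumes")
  }
  subset <- switch(likelihood, binomial_logit = "risk",
                   binomial_cloglog = "risk", poisson_log = "rate", "shared")
  conn <- validate_connectivity(network, subset)
  if (!conn$connected) {
    stop("estimability error: comparison network is disconnected (",
         conn$n_components, " components) for the ", likelihood, " model")
  }
}

# ---- JAGS code generation --------------------------------------------------

effects_lines <- function(effects, structure, d1, d2, delta, md, taud, w, sw,
                          na, pr) {
  ref <- if (structure == "consistency") {
    paste0("d[", d2, "] - d[", d1, "]")
  } else {
    paste0("dd[", pr, "]")
  }
  if (effects == "fixed") {
    return(c(
      paste0("    ", delta, "[i,1] <- 0"),
      paste0("    for (k in 2:", na, "[i]) {"),
      paste0("      ", delta, "[i,k] <- ", ref),
      "    }"))
  }
  if (structure == "inconsistency") {
    # unrelated mean effects: contrasts exchange nothing, no multi-arm
    # correction applies
    return(c(
      paste0("    ", delta, "[i,1] <- 0"),
      paste0("    for (k in 2:", na, "[i]) {"),
      paste0("      ", delta, "[i,k] ~ dnorm(", ref, ", tau)"),
      "    }"))
  }
  # random effects, consistency: conditional sequential construction so the
  # delta of a >2-arm study have the correct 0.5*sigma^2 covariance
  c(paste0("    ", delta, "[i,1] <- 0"),
    paste0("    ", w, "[i,1] <- 0"),
    paste0("    for (k in 2:", na, "[i]) {"),
    paste0("      ", delta, "[i,k] ~ dnorm(", md, "[i,k], ", taud, "[i,k])"),
    paste0("      ", md, "[i,k] <- ", ref, " + ", sw, "[i,k]"),
    paste0("      ", taud, "[i,k] <- tau * 2 * (k - 1) / k"),
    paste0("      ", w, "[i,k] <- ", delta, "[i,k] - (", ref, ")"),
    paste0("      ", sw, "[i,k] <- sum(", w, "[i,1:(k-1)]) / (k - 1)"),
    "    }")
}

build_jags_code <- function(risk_link, has_rate, effects, structure) {
  lines <- "model {"
  if (risk_link != "none") {
    link <- if (risk_link == "logit") {
      "      logit(p[i,k]) <- mu[i] + delta[i,k]"
    } else {
      "      cloglog(p[i,k]) <- log(time[i]) + mu[i] + delta[i,k]"
    }
    lines <- c(lines,
      "  for (i in 1:ns_r) {",
      "    for (k in 1:na_r[i]) {",
      "      r[i,k] ~ dbin(p[i,k], n[i,k])",
      link,
      "    }",
      effects_lines(effects, structure, "t_r[i,1]", "t_r[i,k]",
                    "delta", "md", "taud", "w", "sw", "na_r", "pr_r[i,k]"),
      "  }")
  }
  if (has_rate) {
    lines <- c(lines,
      "  for (i in 1:ns_y) {",
      "    for (k in 1:na_y[i]) {",
      "      y[i,k] ~ dpois(th[i,k])",
      "      th[i,k] <- E[i,k] * lam[i,k]",
      "      log(lam[i,k]) <- mu[ofs + i] + deltay[i,k]",
      "    }",
      effects_lines(effects, structure, "t_y[i,1]", "t_y[i,k]",
                    "deltay", "mdy", "taudy", "wy", "swy", "na_y", "pr_y[i,k]"),
      "  }")
  }
  lines <- c(lines,
    "  for (j in 1:ns_all) { mu[j] ~ dnorm(0, prec_mu) }")
  if (structure == "consistency") {
    lines <- c(lines,
      "  d[1] <- 0",
      "  for (k in 2:nt) { d[k] ~ dnorm(0, prec_d) }")
  } else {
    lines <- c(lines,
      "  for (j in 1:ncomp) { dd[j] ~ dnorm(0, prec_d) }")
  }
  if (effects == "random") {
    lines <- c(lines,
      "  sd ~ dunif(0, sd_upper)",
      "  tau <- pow(sd, -2)")
  }
  paste(c(lines, "}"), collapse = "\n")
}

# ---- fitting ---------------------------------------------------------------

#' Fit a Bayesian network meta-analysis of event data
#'
#' Fits the model described by \code{spec} to the arm records it consumes
#' (see \code{\link{nma_model}}) with MCMC via JAGS. Study baselines
#' \code{mu_i} are unrelated nuisance parameters; non-baseline arms carry a
#' trial-specific effect \code{delta_ik} that under fixed effects equals the
#' relative effect and under random effects is drawn around it with
#' between-study SD \code{sigma} (conditional sequential construction for
#' multi-arm trials). Under consistency all contrasts derive from basic
#' parameters \code{d_k} versus the reference treatment; under inconsistency
#' each observed comparison gets its own unrelated mean effect.
#'
#' A warning (also stored on the result) is attached when any reported
#' parameter has split-Rhat above 1.05.
#'
#' @param network an \code{\link{evidence_network}}.
#' @param spec an \code{\link{nma_model}} specification.
#' @return An object of class \code{nma_fit}: posterior draws, per-chain
#'   matrices, convergence summaries, and the bookkeeping needed by
#'   \code{\link{relative_effects}} and \code{\link{compute_fit}}.
#' @export
fit_nma <- function(network, spec) {
  stopifnot(inherits(network, "evidence_network"),
            inherits(spec, "nma_model_spec"))
  records <- model_records(network, spec$likelihood)
  check_estimable(network, records, spec$likelihood)

  risk_link <- switch(spec$likelihood,
    binomial_logit = "logit", binomial_cloglog = "cloglog",
    shared = if (nrow(records$risk)) "cloglog" else "none",
    poisson_log = "none")
  has_rate <- nrow(records$rate) > 0

  data <- list(prec_d = 1 / spec$priors$d_sd^2,
               prec_mu = 1 / spec$priors$mu_sd^2)
  blocks <- list()
  pair_key <- character(0)

  if (risk_link != "none") {
    am <- arm_matrices(records$risk, c("r", "n", "followup"))
    blocks$risk <- am
    data$ns_r <- am$ns
    data$na_r <- am$na
    data$t_r <- am$t
    data$r <- am$r
    data$n <- am$n
    if (risk_link == "cloglog") data$time <- am$followup[, 1]
  }
  if (has_rate) {
    am <- arm_matrices(records$rate, c("y", "person_years"))
    blocks$rate <- am
    data$ns_y <- am$ns
    data$na_y <- am$na
    data$t_y <- am$t
    data$y <- am$y
    data$E <- am$person_years
    data$ofs <- if (is.null(data$ns_r)) 0L else data$ns_r
  }
  data$ns_all <- (if (is.null(data$ns_r)) 0L else data$ns_r) +
                 (if (is.null(data$ns_y)) 0L else data$ns_y)

  if (spec$structure == "consistency") {
    data$nt <- nrow(network$treatments)
  } else {
    # index observed (baseline, arm) comparisons; shared across blocks
    collect <- function(am) {
      if (is.null(am)) return(character(0))
      k <- character(0)
      for (i in seq_len(am$ns)) {
        for (j in 2:am$na[i]) {
          k <- c(k, paste(am$t[i, 1], am$t[i, j], sep = "-"))
        }
      }
      k
    }
    pair_key <- sort(unique(c(collect(blocks$risk), collect(blocks$rate))))
    index_pairs <- function(am) {
      pr <- matrix(NA_integer_, am$ns, ncol(am$t))
      for (i in seq_len(am$ns)) {
        for (j in 2:am$na[i]) {
          pr[i, j] <- match(paste(am$t[i, 1], am$t[i, j], sep = "-"), pair_key)
        }
      }
      pr
    }
    if (!is.null(blocks$risk)) data$pr_r <- index_pairs(blocks$risk)
    if (!is.null(blocks$rate)) data$pr_y <- index_pairs(blocks$rate)
    data$ncomp <- length(pair_key)
    data$t_r <- NULL  # treatment indices enter only through the pair index
    data$t_y <- NULL
  }
  if (spec$effects == "random") data$sd_upper <- spec$priors$sigma_upper

  code <- build_jags_code(risk_link, has_rate, spec$effects, spec$structure)
  monitors <- c(if (spec$structure == "consistency") "d" else "dd",
                if (spec$effects == "random") "sd",
                "mu",
                if (risk_link != "none") "p",
                if (has_rate) "th")
  res <- run_jags(code, data, monitors, spec$mcmc)

  fitted <- fitted_index(blocks, records)
  key <- grep("^(d\\[|dd\\[|sd$)", colnames(res$draws), value = TRUE)
  conv <- convergence_table(res$chains, key)
  warn <- NULL
  if (any(conv$rhat > 1.05, na.rm = TRUE)) {
    warn <- paste("split-Rhat above 1.05 for:",
                  paste(conv$param[which(conv$rhat > 1.05)], collapse = ", "))
    warning(warn, call. = FALSE)
  }

  structure(list(spec = spec, draws = res$draws, chains = res$chains,
                 treatments = network$treatments, pair_key = pair_key,
                 fitted = fitted, convergence = conv, warning = warn),
            class = "nma_fit")
}

# Map each consumed data point to its fitted-value column in the draws.
fitted_index <- function(blocks, records) {
  out <- list()
  if (!is.null(blocks$risk)) {
    am <- blocks$risk
    rows <- data.frame(param = character(0), likelihood = character(0),
                       study_id = character(0), treatment_code = integer(0),
                       events = numeric(0), size = numeric(0))
    for (i in seq_len(am$ns)) {
      for (k in seq_len(am$na[i])) {
        rows <- rbind(rows, data.frame(
          param = sprintf("p[%d,%d]", i, k), likelihood = "binomial",
          study_id = am$ids[i], treatment_code = am$t[i, k],
          events = am$r[i, k], size = am$n[i, k]))
      }
    }
    out$risk <- rows
  }
  if (!is.null(blocks$rate)) {
    am <- blocks$rate
    rows <- data.frame(param = character(0), likelihood = character(0),
                       study_id = character(0), treatment_code = integer(0),
                       events = numeric(0), size = numeric(0))
    for (i in seq_len(am$ns)) {
      for (k in seq_len(am$na[i])) {
        rows <- rbind(rows, data.frame(
          param = sprintf("th[%d,%d]", i, k), likelihood = "poisson",
          study_id = am$ids[i], treatment_code = am$t[i, k],
          events = am$y[i, k], size = am$person_years[i, k]))
      }
    }
    out$rate <- rows
  }
  do.call(rbind, out)
}

#' @export
print.nma_fit <- function(x, ...) {
  cat("Bayesian NMA fit:", x$spec$likelihood, "/", x$spec$effects, "effects /",
      x$spec$structure, "\n")
  cat("  draws:", nrow(x$draws), "(", length(x$chains), "chains )\n")
  if (nrow(x$convergence)) {
    cat("  max split-Rhat:", round(max(x$convergence$rhat, na.rm = TRUE), 3),
        " min ESS:", round(min(x$convergence$ess, na.rm = TRUE)), "\n")
  }
  if (!is.null(x$warning)) cat("  WARNING:", x$warning, "\n")
  invisible(x)
}

#' Fit an unrelated-mean-effects (inconsistency) model
#'
#' Convenience wrapper for \code{\link{fit_nma}} with
#' \code{structure = "inconsistency"}: every observed comparison gets its own
#' basic parameter and no consistency equations are imposed. Comparing its
#' fit statistics with the consistency model's probes for inconsistency
#' between direct and indirect evidence.
#'
#' @inheritParams fit_nma
#' @return An \code{nma_fit}.
#' @export
fit_inconsistency <- function(network, spec) {
  spec$structure <- "inconsistency"
  fit_nma(network, spec)
}

# Draws of the basic parameters d_k (consistency fits), as a matrix with one
# column per treatment code (column for the reference is all zero).
d_draws <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  if (fit$spec$structure != "consistency") {
    stop("coding error: basic-parameter draws require a consistency fit")
  }
  K <- nrow(fit$treatments)
  out <- matrix(0, nrow(fit$draws), K)
  colnames(out) <- fit$treatments$code
  for (k in 2:K) out[, k] <- fit$draws[, sprintf("d[%d]", k)]
  out
}

#' Posterior relative effects versus a reference treatment
#'
#' Posterior median and equal-tailed 95\% credible interval of each
#' treatment's effect relative to \code{reference}, exponentiated onto the
#' reporting scale: odds ratios for the logit model, hazard ratios for the
#' cloglog, Poisson and shared models. The reference row is exactly 1.
#'
#' @param fit a consistency \code{nma_fit}.
#' @param reference treatment code to report against (default 1).
#' @return data.frame: treatment code, label, measure (\code{"OR"} or
#'   \code{"HR"}), median, lower, upper.
#' @export
relative_effects <- function(fit, reference = 1L) {
  dm <- d_draws(fit)
  codes <- fit$treatments$code
  if (!reference %in% codes) {
    stop("coding error: unknown reference treatment ", reference)
  }
  measure <- if (fit$spec$likelihood == "binomial_logit") "OR" else "HR"
  ref_col <- match(reference, codes)
  out <- data.frame(treatment = codes, label = fit$treatments$label,
                    measure = measure, median = NA_real_,
                    lower = NA_real_, upper = NA_real_)
  for (j in seq_along(codes)) {
    if (codes[j] == reference) {
      out[j, c("median", "lower", "upper")] <- 1
    } else {
      ex <- exp(dm[, j] - dm[, ref_col])
      q <- stats::quantile(ex, c(0.5, 0.025, 0.975), names = FALSE)
      out[j, c("median", "lower", "upper")] <- q
    }
  }
  out
}

#' Posterior summaries of every observed or derivable comparison
#'
#' For a consistency fit, contrasts \code{d_k - d_b} for the requested pairs;
#' for an inconsistency fit, the unrelated mean-effect parameter of each
#' observed comparison. Summaries are on the linear-predictor (log) scale.
#'
#' @param fit an \code{nma_fit}.
#' @return data.frame: treatment1, treatment2, mean, median, lower, upper.
#' @export
comparison_effects <- function(fit) {
  if (fit$spec$structure == "inconsistency") {
    sp <- strsplit(fit$pair_key, "-", fixed = TRUE)
    out <- data.frame(treatment1 = as.integer(vapply(sp, `[`, "", 1)),
                      treatment2 = as.integer(vapply(sp, `[`, "", 2)))
    sm <- t(vapply(seq_along(fit$pair_key), function(j) {
      draw_summary(fit$draws[, sprintf("dd[%d]", j)])
    }, numeric(4)))
  } else {
    dm <- d_draws(fit)
    K <- ncol(dm)
    pairs <- utils::combn(seq_len(K), 2)
    out <- data.frame(treatment1 = fit$treatments$code[pairs[1, ]],
                      treatment2 = fit$treatments$code[pairs[2, ]])
    sm <- t(vapply(seq_len(ncol(pairs)), function(j) {
      draw_summary(dm[, pairs[2, j]] - dm[, pairs[1, j]])
    }, numeric(4)))
  }
  out$mean <- sm[, 1]; out$median <- sm[, 2]
  out$lower <- sm[, 3]; out$upper <- sm[, 4]
  out
}
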