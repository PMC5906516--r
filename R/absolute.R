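#' Economic inputs for event costs and disutilities
#'
#' @param cost_per_event currency cost per severe event (default 333 GBP).
#' @param utility_decrement utility change per event-experiencer (default
#'   -0.012).
#' @param horizon time horizon in years for event probabilities (default 1).
#' @return An object of class \code{economic_inputs}.
#' @export
economic_inputs <- function(cost_per_event = 333, utility_decrement = -0.012,
                            horizon = 1) {
  if (!(horizon > 0)) stop("domain error: horizon must be > 0")
  structure(list(cost_per_event = cost_per_event,
                 utility_decrement = utility_decrement, horizon = horizon),
            class = "economic_inputs")
}

#' Convert a constant event rate to an event probability
#'
#' \code{p = 1 - exp(-r t)}: the probability of at least one event by time
#' \code{t} under a constant rate \code{r}.
#'
#' @param r event rate(s), events per person-year (>= 0).
#' @param t time period of interest in years (>= 0).
#' @return Probabilities in [0, 1].
#' @export
rate_to_probability <- function(r, t) {
  if (any(r < 0) || any(t < 0)) stop("domain error: r and t must be >= 0")
  1 - exp(-r * t)
}

#' Combine baseline and relative-effect posteriors into absolute probabilities
#'
#' Pairs draws from a baseline meta-analysis with draws of the basic
#' parameters \code{d_k} from an NMA fitted on the matching scale, and maps
#' each pair to a per-treatment absolute event probability:
#' \itemize{
#'   \item logit baseline + logit NMA: \code{p_k = expit(m + d_k)};
#'   \item cloglog or log-rate baseline + log-hazard NMA (cloglog, Poisson or
#'     shared): \code{p_k = 1 - exp(-exp(m + d_k) t)}, i.e.
#'     \code{cloglog(p_k) = cloglog(p_1) + d_k}.
#' }
#' The two posteriors come from separate models, so draws are paired
#' independently after resampling both to a common length with a fixed seed.
#'
#' @param bfit a \code{\link{fit_baseline}} result.
#' @param fit a consistency \code{\link{nma_fit}} on the matching scale.
#' @param t horizon in years (ignored on the logit scale).
#' @param n_draws number of paired draws (default: the larger of the two).
#' @param seed seed for the pairing resample.
#' @param predictive use the predictive baseline for a new study.
#' @return Matrix of probability draws, one column per treatment code.
#' @export
combine_absolute <- function(bfit, fit, t = 1, n_draws = NULL, seed = 1,
                             predictive = FALSE) {
  stopifnot(inherits(bfit, "baseline_fit"), inherits(fit, "nma_fit"))
  logit_model <- fit$spec$likelihood == "binomial_logit"
  if (logit_model != (bfit$scale == "logit")) {
    stop("configuration error: baseline scale '", bfit$scale,
         "' does not match the ", fit$spec$likelihood, " model")
  }
  m <- baseline_m_draws(bfit, predictive)
  dm <- d_draws(fit)
  if (is.null(n_draws)) n_draws <- max(length(m), nrow(dm))
  m <- as.vector(resample_rows(matrix(m), n_draws, seed))
  dm <- resample_rows(dm, n_draws, seed + 1)
  p <- if (logit_model) {
    stats::plogis(m + dm)
  } else {
    1 - exp(-exp(m + dm) * t)
  }
  colnames(p) <- colnames(dm)
  p
}

#' Rank treatments draw by draw
#'
#' Within each posterior draw, treatments are ranked by the supplied effect
#' (by default lower is better: fewest events ranks first); ties are broken
#' by treatment code so ranking is deterministic. Reports the posterior
#' median rank and 95\% CrI per treatment.
#'
#' @param draws matrix of per-treatment draws (columns named by treatment
#'   code), e.g. probabilities from \code{\link{combine_absolute}} or
#'   exponentiated effects.
#' @param direction \code{"lower"} (default) if smaller values are better.
#' @return data.frame: treatment, median_rank, lower, upper.
#' @export
rank_treatments <- function(draws, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("data error: ranking needs >= 2 treatments")
  x <- if (direction == "lower") draws else -draws
  ranks <- t(apply(x, 1, rank, ties.method = "first"))
  q <- apply(ranks, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
             names = FALSE)
  data.frame(
    treatment = if (is.null(colnames(draws))) seq_len(ncol(draws))
                else as.integer(colnames(draws)),
    median_rank = q[1, ], lower = q[2, ], upper = q[3, ])
}

summarise_linear <- function(p_draws, factor) {
  draws <- p_draws * factor
  sm <- apply(draws, 2, draw_summary)
  data.frame(
    treatment = if (is.null(colnames(p_draws))) seq_len(ncol(p_draws))
                else as.integer(colnames(p_draws)),
    mean = sm["mean", ], lower = sm["lower", ], upper = sm["upper", ])
}

#' Expected per-patient event cost
#'
#' Multiplies each probability draw by the cost per event and summarises.
#' Note this costs the probability of at least one event, not the expected
#' number of events, so it understates costs when repeat events occur; see
#' \code{events_based = TRUE} for the events-based alternative
#' \code{cost * r * t} given rate draws.
#'
#' @param p_draws matrix of probability draws (columns = treatments), or rate
#'   draws when \code{events_based = TRUE}.
#' @param inputs an \code{\link{economic_inputs}}.
#' @param events_based if TRUE, treat \code{p_draws} as rate draws and cost
#'   the expected number of events over the horizon (default FALSE).
#' @return data.frame: treatment, mean, lower, upper (95\% CrI).
#' @export
expected_cost <- function(p_draws, inputs = economic_inputs(),
                          events_based = FALSE) {
  p_draws <- as.matrix(p_draws)
  if (events_based) {
    return(summarise_linear(p_draws * inputs$horizon, inputs$cost_per_event))
  }
  if (any(p_draws < 0 | p_draws > 1)) {
    stop("domain error: probability draws must lie in [0, 1]")
  }
  summarise_linear(p_draws, inputs$cost_per_event)
}

#' Expected disutility of experiencing an event
#'
#' Draw-wise product of the event probability with the utility decrement.
#'
#' @inheritParams expected_cost
#' @return data.frame: treatment, mean, lower, upper (95\% CrI).
#' @export
expected_disutility <- function(p_draws, inputs = economic_inputs()) {
  p_draws <- as.matrix(p_draws)
  if (any(p_draws < 0 | p_draws > 1)) {
    stop("domain error: probability draws must lie in [0, 1]")
  }
  summarise_linear(p_draws, inputs$utility_decrement)
}

#' Per-treatment absolute outcome table
#'
#' The full per-model reporting surface: absolute event probability, median
#' rank, expected cost and expected disutility per treatment, each with 95\%
#' CrIs, from one baseline fit and one NMA fit on the matching scale.
#'
#' @inheritParams combine_absolute
#' @param inputs an \code{\link{economic_inputs}} (its \code{horizon} is the
#'   probability horizon).
#' @param label model label recorded in the table.
#' @return An object of class \code{outcome_table} (a data.frame).
#' @export
absolute_outcome_table <- function(bfit, fit, inputs = economic_inputs(),
                                   label = fit$spec$likelihood, seed = 1) {
  p <- combine_absolute(bfit, fit, t = inputs$horizon, seed = seed)
  pr <- apply(p, 2, draw_summary)
  rk <- rank_treatments(p)
  ct <- expected_cost(p, inputs)
  du <- expected_disutility(p, inputs)
  out <- data.frame(
    model = label,
    treatment = as.integer(colnames(p)),
    label = fit$treatments$label[match(as.integer(colnames(p)),
                                       fit$treatments$code)],
    prob_mean = pr["mean", ], prob_lower = pr["lower", ],
    prob_upper = pr["upper", ],
    rank_median = rk$median_rank, rank_lower = rk$lower, rank_upper = rk$upper,
    cost_mean = ct$mean, cost_lower = ct$lower, cost_upper = ct$upper,
    disutility_mean = du$mean, disutility_lower = du$lower,
    disutility_upper = du$upper)
  rownames(out) <- NULL
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' @export
print.outcome_table <- function(x, digits = 3, ...) {
  cat("Absolute outcomes (", x$model[1], ")\n", sep = "")
  show <- data.frame(
    treatment = x$label,
    probability = sprintf("%.*f (%.*f-%.*f)", digits, x$prob_mean,
                          digits, x$prob_lower, digits, x$prob_upper),
    rank = sprintf("%g (%g-%g)", x$rank_median, x$rank_lower, x$rank_upper),
    cost = sprintf("%.2f (%.2f-%.2f)", x$cost_mean, x$cost_lower,
                   x$cost_upper),
    disutility = sprintf("%.4f (%.4f-%.4f)", x$disutility_mean,
                         x$disutility_lower, x$disutility_upper))
  print(show, row.names = FALSE)
  invisible(x)
}
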