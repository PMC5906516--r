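#' Per-point residual deviance for binomial data
#'
#' Saturated-model deviance contribution of one (or several) binomial data
#' points, the quantity whose posterior mean is compared with the number of
#' data points to judge model fit:
#' \deqn{2 [ r \log(r / (n \hat p)) + (n - r) \log((n - r)/(n - n \hat p)) ]}
#' with the convention \eqn{0 \log 0 = 0} for zero cells.
#'
#' @param r events (0 <= r <= n).
#' @param n denominators (>= 1).
#' @param p_hat fitted probabilities, strictly inside (0, 1).
#' @return Numeric vector of deviance contributions (>= 0).
#' @export
deviance_binomial <- function(r, n, p_hat) {
  if (any(p_hat <= 0 | p_hat >= 1)) {
    stop("domain error: fitted probabilities must lie strictly in (0, 1)")
  }
  if (any(r < 0 | r > n)) stop("domain error: need 0 <= r <= n")
  2 * (xlogy(r, r / (n * p_hat)) + xlogy(n - r, (n - r) / (n - n * p_hat)))
}

#' Per-point residual deviance for Poisson data
#'
#' \deqn{2 [ (\hat\theta - y) + y \log(y / \hat\theta) ]} with
#' \eqn{0 \log 0 = 0}, where \eqn{\hat\theta} is the fitted mean count
#' (rate times exposure).
#'
#' @param y observed event counts (>= 0).
#' @param theta_hat fitted mean counts (> 0).
#' @return Numeric vector of deviance contributions (>= 0).
#' @export
deviance_poisson <- function(y, theta_hat) {
  if (any(theta_hat <= 0)) stop("domain error: fitted mean counts must be > 0")
  if (any(y < 0)) stop("domain error: counts must be >= 0")
  2 * ((theta_hat - y) + xlogy(y, y / theta_hat))
}

# x * log(y) with the 0 log 0 = 0 convention; broadcasts like `*`
xlogy <- function(x, y) {
  out <- x * log(y)
  out[rep_len(x == 0, length(out))] <- 0
  out
}

#' Residual deviance, pD and DIC of a fitted model
#'
#' Computes the posterior mean residual deviance \code{Dbar} (summed
#' per-point saturated deviances, averaged over draws), the effective number
#' of parameters \code{pD = Dbar - D(posterior mean fitted values)} (the
#' classic plug-in form), and \code{DIC = Dbar + pD}. In a well-fitting model
#' \code{Dbar} is close to the number of data points.
#'
#' @param fit an \code{\link{nma_fit}} or \code{\link{fit_baseline}} result
#'   (anything carrying per-draw fitted values and the observed data).
#' @return An object of class \code{fit_stats}: \code{Dbar}, \code{pD},
#'   \code{DIC}, \code{n_datapoints} and a \code{pointwise} data.frame of
#'   posterior mean per-point contributions.
#' @export
compute_fit <- function(fit) {
  idx <- fit$fitted
  if (is.null(idx) || !nrow(idx)) {
    stop("contract error: fit carries no per-draw fitted values")
  }
  draws <- fit$draws[, idx$param, drop = FALSE]
  dev <- matrix(NA_real_, nrow(draws), nrow(idx))
  for (j in seq_len(nrow(idx))) {
    dev[, j] <- if (idx$likelihood[j] == "binomial") {
      deviance_binomial(idx$events[j], idx$size[j], draws[, j])
    } else {
      deviance_poisson(idx$events[j], draws[, j])
    }
  }
  pointwise <- colMeans(dev)
  Dbar <- sum(pointwise)
  mean_fit <- colMeans(draws)
  dev_at_mean <- sum(vapply(seq_len(nrow(idx)), function(j) {
    if (idx$likelihood[j] == "binomial") {
      deviance_binomial(idx$events[j], idx$size[j], mean_fit[j])
    } else {
      deviance_poisson(idx$events[j], mean_fit[j])
    }
  }, numeric(1)))
  pD <- Dbar - dev_at_mean
  structure(list(
    Dbar = Dbar, pD = pD, DIC = Dbar + pD, n_datapoints = nrow(idx),
    pointwise = data.frame(study_id = idx$study_id,
                           treatment_code = idx$treatment_code,
                           likelihood = idx$likelihood, dev = pointwise)
  ), class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("Residual deviance %.1f on %d data points; pD %.1f; DIC %.1f\n",
              x$Dbar, x$n_datapoints, x$pD, x$DIC))
  invisible(x)
}

#' Compare models by DIC with a parsimony rule
#'
#' Selects the model with the lowest DIC, except that when a simpler model's
#' DIC is within 3 of the minimum the simpler model is preferred (DIC
#' differences under 3 are not considered meaningful). Simplicity is the
#' order of \code{fits}: list models simplest first (e.g. fixed before
#' random effects, consistency before inconsistency).
#'
#' @param fits named list of \code{\link{fit_stats}} over identical data
#'   points, ordered from simplest to most complex.
#' @param inconsistency optional name(s) of fits that are inconsistency
#'   models; if such a fit attains the smallest Dbar or DIC the comparison is
#'   flagged as showing potential inconsistency.
#' @return A list: \code{table} (name, Dbar, pD, DIC, selected),
#'   \code{selected} (name), \code{inconsistency_flag}.
#' @export
compare_models <- function(fits, inconsistency = character(0)) {
  stopifnot(length(fits) >= 2, !is.null(names(fits)))
  nd <- vapply(fits, function(f) f$n_datapoints, numeric(1))
  if (length(unique(nd)) != 1) {
    stop("comparison error: fits cover different numbers of data points")
  }
  dic <- vapply(fits, function(f) f$DIC, numeric(1))
  dbar <- vapply(fits, function(f) f$Dbar, numeric(1))
  candidates <- which(dic - min(dic) < 3)
  selected <- names(fits)[min(candidates)]
  flag <- length(inconsistency) > 0 &&
    (names(fits)[which.min(dic)] %in% inconsistency ||
     names(fits)[which.min(dbar)] %in% inconsistency)
  tab <- data.frame(model = names(fits), Dbar = dbar,
                    pD = vapply(fits, function(f) f$pD, numeric(1)),
                    DIC = dic, selected = names(fits) == selected)
  rownames(tab) <- NULL
  list(table = tab, selected = selected, inconsistency_flag = flag)
}
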