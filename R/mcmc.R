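#' Prior specification for the Bayesian models
#'
#' Vague priors in the style used throughout the evidence-synthesis
#' literature: Normal(0, sd^2) on relative effects and study baselines (on the
#' model's linear-predictor scale) and Uniform(0, upper) on the between-study
#' standard deviation.
#'
#' @param d_sd prior SD for basic relative-effect parameters (default 100).
#' @param mu_sd prior SD for study baseline parameters (default 100).
#' @param sigma_upper upper bound of the uniform prior on the heterogeneity
#'   SD (default 2, generous for a log-hazard/log-odds scale).
#' @return An object of class \code{prior_spec}.
#' @export
prior_spec <- function(d_sd = 100, mu_sd = 100, sigma_upper = 2) {
  stopifnot(d_sd > 0, mu_sd > 0, sigma_upper > 0)
  structure(list(d_sd = d_sd, mu_sd = mu_sd, sigma_upper = sigma_upper),
            class = "prior_spec")
}

#' MCMC sampler settings
#'
#' @param chains number of chains (>= 2 for split-Rhat diagnostics).
#' @param draws posterior draws kept per chain (after burn-in, before any
#'   thinning).
#' @param burnin iterations discarded per chain; roughly half are used for
#'   JAGS adaptation.
#' @param thin thinning interval.
#' @param seed integer seed; each chain gets \code{seed + chain - 1}.
#' @return An object of class \code{mcmc_settings}.
#' @export
mcmc_settings <- function(chains = 4, draws = 2000, burnin = 1000, thin = 1,
                          seed = 1) {
  stopifnot(chains >= 2, draws > 0, burnin >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), draws = as.integer(draws),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

# Run a JAGS model and return per-chain draw matrices plus diagnostics.
# monitors: character vector of variable names.
run_jags <- function(code, data, monitors, mcmc) {
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (mcmc$seed + ch - 1L) %% .Machine$integer.max)
  })
  n_adapt <- max(100L, mcmc$burnin %/% 2L)
  model <- rjags::jags.model(textConnection(code), data = data, inits = inits,
                             n.chains = mcmc$chains, n.adapt = n_adapt,
                             quiet = TRUE)
  extra_burn <- max(0L, mcmc$burnin - n_adapt)
  if (extra_burn > 0) stats::update(model, n.iter = extra_burn,
                                    progress.bar = "none")
  samp <- rjags::coda.samples(model, variable.names = monitors,
                              n.iter = mcmc$draws * mcmc$thin,
                              thin = mcmc$thin, progress.bar = "none")
  chains <- lapply(samp, function(m) {
    m <- as.matrix(m)
    m <- m[, !is.na(colSums(m)), drop = FALSE]  # drop padding of ragged arrays
    # coda drops the index from length-1 array monitors; restore it for the
    # variables that are arrays by construction
    arrays <- c("mu", "dd", "p", "th", "theta")
    hit <- colnames(m) %in% arrays
    colnames(m)[hit] <- paste0(colnames(m)[hit], "[1]")
    m
  })
  list(chains = chains, draws = do.call(rbind, chains))
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift is detected as well as between-chain
#' disagreement. Values near 1 indicate convergence.
#'
#' @param chains list of equal-length numeric vectors, one per chain.
#' @return The split-Rhat statistic (NA for constant chains).
#' @export
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Convergence table for selected columns of per-chain draw matrices.
convergence_table <- function(chains, params) {
  params <- intersect(params, colnames(chains[[1]]))
  keep <- vapply(params, function(p) {
    stats::var(unlist(lapply(chains, function(m) m[, p]))) > 0
  }, logical(1))
  params <- params[keep]
  if (!length(params)) {
    return(data.frame(param = character(), rhat = numeric(), ess = numeric()))
  }
  mcl <- coda::as.mcmc.list(lapply(chains, function(m) {
    coda::mcmc(m[, params, drop = FALSE])
  }))
  ess <- coda::effectiveSize(mcl)
  rhat <- vapply(params, function(p) {
    split_rhat(lapply(chains, function(m) m[, p]))
  }, numeric(1))
  data.frame(param = params, rhat = unname(rhat), ess = unname(ess[params]))
}

# Equal-tailed credible interval plus median/mean of a draw vector.
draw_summary <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  q <- stats::quantile(x, c(a, 0.5, 1 - a), names = FALSE)
  c(mean = mean(x), median = q[2], lower = q[1], upper = q[3])
}

# Resample rows so two draw matrices can be paired independently.
resample_rows <- function(x, size, seed) {
  x <- as.matrix(x)
  if (nrow(x) == size) return(x)
  set.seed(seed %% .Machine$integer.max)
  x[sample.int(nrow(x), size, replace = TRUE), , drop = FALSE]
}

# Polynomial rolling hash of a character scalar: a stable config fingerprint
# without external digest dependencies.
config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
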