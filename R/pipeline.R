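#' Configure an end-to-end analysis run
#'
#' A run either simulates an evidence network (supply \code{generator}) or
#' reads one from disk (supply \code{input}), fits the requested models with
#' random or fixed effects under a consistency or inconsistency structure,
#' computes fit statistics, runs the matching baseline meta-analyses, and
#' propagates everything into absolute probabilities, ranks, costs and
#' disutilities. All randomness flows from one master seed, split per stage.
#'
#' @param models character subset of \code{c("logit", "cloglog", "poisson",
#'   "shared")}.
#' @param generator a \code{\link{generator_config}}, or NULL when reading.
#' @param input named character vector of file paths (\code{risk},
#'   \code{rate}, \code{treatments}; risk/rate optional), or NULL.
#' @param effects,structure passed to every \code{\link{nma_model}}.
#' @param baseline_effects effects structure of the baseline meta-analyses.
#' @param econ an \code{\link{economic_inputs}}.
#' @param priors a \code{\link{prior_spec}}.
#' @param mcmc an \code{\link{mcmc_settings}} (its seed is overridden by the
#'   stage seeds derived from \code{seed}).
#' @param out_dir output directory for run artifacts.
#' @param seed master seed.
#' @param verbose print stage progress.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(models = c("logit", "cloglog", "poisson", "shared"),
                       generator = NULL, input = NULL,
                       effects = "random", structure = "consistency",
                       baseline_effects = "random",
                       econ = economic_inputs(), priors = prior_spec(),
                       mcmc = mcmc_settings(), out_dir = tempfile("run_"),
                       seed = 1, verbose = FALSE) {
  if (!length(models)) stop("configuration error: at least one model required")
  models <- match.arg(models, c("logit", "cloglog", "poisson", "shared"),
                      several.ok = TRUE)
  if (is.null(generator) && is.null(input)) {
    stop("configuration error: supply a generator config or input paths")
  }
  structure(list(models = models, generator = generator, input = input,
                 effects = effects, structure = structure,
                 baseline_effects = baseline_effects, econ = econ,
                 priors = priors, mcmc = mcmc, out_dir = out_dir,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

model_likelihood <- function(model) {
  switch(model, logit = "binomial_logit", cloglog = "binomial_cloglog",
         poisson = "poisson_log", shared = "shared",
         stop("configuration error: unknown model '", model, "'"))
}

model_baseline_scale <- function(model) {
  switch(model, logit = "logit", cloglog = "cloglog",
         poisson = "log_rate", shared = "log_rate")
}

stage_seed <- function(seed, offset) (seed + offset) %% 2147483647L

#' Run the full analysis pipeline
#'
#' Executes simulate/read, model fitting, fit statistics, baseline
#' meta-analysis and absolute-outcome stages for every requested model, and
#' writes all artifacts (network CSVs, relative-effect and outcome tables,
#' basic-parameter draws, fit and run metadata JSON) into
#' \code{config$out_dir}. Every artifact-producing stage derives its own
#' seed from the master seed, so identical configs give identical runs.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list with the run directory, the network, and
#'   per-model fits, baselines and outcome tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(...)
  t0 <- Sys.time()
  timings <- list()
  stamp <- function(stage) {
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  }

  if (!is.null(config$generator)) {
    say("stage: simulate")
    gen <- config$generator
    gen$seed <- stage_seed(config$seed, 0L)
    sim <- simulate_network(gen)
    network <- sim$network
    write_simulated(sim, config$out_dir)
  } else {
    say("stage: read")
    paths <- config$input
    data_paths <- paths[setdiff(names(paths), "treatments")]
    network <- read_network(data_paths, paths[["treatments"]],
                            format = "mixed")
    write_network(network, config$out_dir)
  }
  stamp("data")

  fits <- list()
  baselines <- list()
  outcomes <- list()
  convergence <- list()
  for (j in seq_along(config$models)) {
    model <- config$models[j]
    say("stage: fit ", model)
    mc <- config$mcmc
    mc$seed <- stage_seed(config$seed, 100L + j)
    spec <- nma_model(model_likelihood(model), effects = config$effects,
                      structure = config$structure, priors = config$priors,
                      mcmc = mc)
    fit <- tryCatch(fit_nma(network, spec), error = function(e) {
      stop("stage 'fit ", model, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    fits[[model]] <- fit
    stats <- compute_fit(fit)
    convergence[[model]] <- fit$convergence
    utils::write.csv(fit$draws[, grep("^(d|dd)\\[", colnames(fit$draws)),
                               drop = FALSE],
                     file.path(config$out_dir, paste0("draws_", model, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(Dbar = stats$Dbar, pD = stats$pD, DIC = stats$DIC,
           n_datapoints = stats$n_datapoints, pointwise = stats$pointwise,
           max_rhat = suppressWarnings(max(fit$convergence$rhat, na.rm = TRUE)),
           min_ess = suppressWarnings(min(fit$convergence$ess, na.rm = TRUE))),
      file.path(config$out_dir, paste0("fit_", model, ".json")),
      auto_unbox = TRUE, digits = NA)

    if (config$structure == "consistency") {
      rel <- relative_effects(fit)
      utils::write.csv(rel, file.path(config$out_dir,
                                      paste0("relative_effects_", model, ".csv")),
                       row.names = FALSE)
      say("stage: baseline ", model)
      mcb <- config$mcmc
      mcb$seed <- stage_seed(config$seed, 200L + j)
      bfit <- fit_baseline(network, scale = model_baseline_scale(model),
                           effects = config$baseline_effects,
                           priors = config$priors, mcmc = mcb)
      baselines[[model]] <- bfit
      say("stage: absolute ", model)
      tab <- absolute_outcome_table(bfit, fit, inputs = config$econ,
                                    label = model,
                                    seed = stage_seed(config$seed, 300L + j))
      outcomes[[model]] <- tab
      utils::write.csv(tab, file.path(config$out_dir,
                                      paste0("outcomes_", model, ".csv")),
                       row.names = FALSE)
    }
    stamp(paste0("model_", model))
  }

  meta <- list(
    seed = config$seed,
    config_hash = config_hash(paste(deparse(config), collapse = "")),
    models = config$models, effects = config$effects,
    structure = config$structure,
    timings_sec = timings,
    convergence = lapply(convergence, function(cv) {
      list(max_rhat = suppressWarnings(max(cv$rhat, na.rm = TRUE)),
           min_ess = suppressWarnings(min(cv$ess, na.rm = TRUE)))
    }))
  jsonlite::write_json(meta, file.path(config$out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = config$out_dir, network = network, fits = fits,
                 baselines = baselines, outcomes = outcomes))
}

#' Assemble a cross-model comparison report from a run directory
#'
#' Pure function of the artifacts written by \code{\link{run_pipeline}}:
#' re-reads the per-model tables and lays the models side by side — relative
#' effects per scale, baseline (reference-treatment) probabilities, absolute
#' probabilities, expected costs and disutilities. This is the package's
#' analogue of a publication's model-comparison tables.
#'
#' @param dir a completed run directory.
#' @return A list of data.frames: \code{relative_effects},
#'   \code{absolute_probabilities}, \code{baseline}, \code{costs},
#'   \code{disutilities}, plus \code{meta}.
#' @export
render_report <- function(dir) {
  run_file <- file.path(dir, "run.json")
  if (!file.exists(run_file)) {
    stop("reporting error: missing artifact run.json in ", dir)
  }
  meta <- jsonlite::read_json(run_file, simplifyVector = TRUE)
  models <- meta$models

  get <- function(prefix, model) {
    f <- file.path(dir, paste0(prefix, "_", model, ".csv"))
    if (!file.exists(f)) stop("reporting error: missing artifact ", basename(f))
    utils::read.csv(f, stringsAsFactors = FALSE)
  }

  rel_list <- lapply(models, function(m) get("relative_effects", m))
  out_list <- lapply(models, function(m) get("outcomes", m))

  fmt <- function(m, l, u, digits = 2) {
    sprintf("%.*f (%.*f to %.*f)", digits, m, digits, l, digits, u)
  }
  base <- rel_list[[1]][, c("treatment", "label")]
  relative <- base
  absolute <- base
  costs <- base
  disut <- base
  for (j in seq_along(models)) {
    rl <- rel_list[[j]]
    ot <- out_list[[j]]
    i1 <- match(base$treatment, rl$treatment)
    i2 <- match(base$treatment, ot$treatment)
    relative[[paste0(models[j], " (", rl$measure[1], ")")]] <-
      fmt(rl$median[i1], rl$lower[i1], rl$upper[i1])
    absolute[[models[j]]] <- fmt(ot$prob_mean[i2], ot$prob_lower[i2],
                                 ot$prob_upper[i2])
    costs[[models[j]]] <- fmt(ot$cost_mean[i2], ot$cost_lower[i2],
                              ot$cost_upper[i2])
    disut[[models[j]]] <- fmt(ot$disutility_mean[i2], ot$disutility_lower[i2],
                              ot$disutility_upper[i2], digits = 4)
  }
  baseline <- do.call(rbind, lapply(seq_along(models), function(j) {
    ot <- out_list[[j]]
    ref <- ot[ot$treatment == 1, ]
    data.frame(model = models[j], prob_mean = ref$prob_mean,
               prob_lower = ref$prob_lower, prob_upper = ref$prob_upper)
  }))
  list(relative_effects = relative, absolute_probabilities = absolute,
       baseline = baseline, costs = costs, disutilities = disut, meta = meta)
}
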