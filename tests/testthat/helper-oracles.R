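# Independent breadth-first-search component oracle (no igraph).
bfs_components <- function(n_nodes, edges) {
  # edges: 2-column matrix of node indices
  adj <- vector("list", n_nodes)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  comp <- integer(n_nodes)
  cur <- 0L
  for (s in seq_len(n_nodes)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in adj[[v]]) {
        if (comp[u] == 0L) {
          comp[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}

# Short chains for unit tests; acceptance tests use larger settings.
quick_mcmc <- function(seed = 1, chains = 2, draws = 1200, burnin = 600) {
  mcmc_settings(chains = chains, draws = draws, burnin = burnin, seed = seed)
}

# A three-treatment network: two 2-arm risk studies AB and BC.
chain_network <- function() {
  evidence_network(
    treatments = data.frame(code = 1:3, label = c("A", "B", "C")),
    risk = data.frame(
      study_id = c("s1", "s1", "s2", "s2"),
      treatment_code = c(1L, 2L, 2L, 3L),
      r = c(10, 12, 9, 14), n = c(100, 100, 120, 120),
      followup = c(1, 1, 0.5, 0.5))
  )
}

# Degenerate hand-built fits for closed-form checks: an nma_fit whose d
# draws are fixed constants, and a baseline_fit whose m draws are constant.
fake_nma_fit <- function(d_values, n_draws = 200,
                         likelihood = "binomial_cloglog") {
  K <- length(d_values)
  stopifnot(d_values[1] == 0)
  draws <- matrix(rep(d_values[-1], each = n_draws), n_draws, K - 1)
  colnames(draws) <- sprintf("d[%d]", 2:K)
  structure(list(
    spec = nma_model(likelihood, "fixed", "consistency"),
    draws = draws,
    treatments = data.frame(code = seq_len(K),
                            label = paste0("T", seq_len(K)))),
    class = "nma_fit")
}

fake_baseline_fit <- function(m_values, scale = "log_rate",
                              effects = "fixed") {
  draws <- matrix(m_values, ncol = 1, dimnames = list(NULL, "m"))
  structure(list(scale = scale, effects = effects, treatment = 1L,
                 draws = draws),
            class = "baseline_fit")
}

# One large two-arm rate study: the large-count limit where the posterior
# mean log hazard ratio approaches the log count ratio.
single_rate_study <- function(y = c(100, 50), E = c(100, 100)) {
  evidence_network(
    treatments = data.frame(code = 1:2, label = c("ref", "new")),
    rate = data.frame(study_id = "s1", treatment_code = 1:2,
                      y = y, person_years = E)
  )
}

single_risk_study <- function(r, n, followup = 1) {
  evidence_network(
    treatments = data.frame(code = 1:2, label = c("ref", "new")),
    risk = data.frame(study_id = "s1", treatment_code = 1:2,
                      r = r, n = n, followup = followup)
  )
}
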