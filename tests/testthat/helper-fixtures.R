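# Shared fixtures and independent oracles, all built in code.

# Compact event-table builder: each argument row is
# c(half, t, team, actor, action, receiver, completed, zone, restart).
ev_row <- function(half, t, team, actor, action, receiver = NA, zone = 2,
                   restart = "open_play",
                   completed = (action == "pass" && !is.na(receiver))) {
  tibble::tibble(match_id = "m1", half = as.integer(half), t = t,
                 team = team, actor = as.integer(actor), action = action,
                 receiver = as.integer(receiver), completed = completed,
                 zone = as.integer(zone), restart = restart)
}

ev_bind <- function(...) do.call(rbind, list(...))

# A well-formed 10-event log: one play per team plus an incomplete pass.
tiny_log <- function() {
  ev <- ev_bind(
    ev_row(1,   0, "A", 5, "pass", 6, zone = 2, restart = "kickoff"),
    ev_row(1,   4, "A", 6, "pass", 8, zone = 2),
    ev_row(1,   9, "A", 8, "pass", 9, zone = 3),
    ev_row(1,  12, "A", 9, "loss", zone = 3),
    ev_row(1,  40, "B", 4, "pass", 7, zone = 1),
    ev_row(1,  44, "B", 7, "contact", zone = 2),
    ev_row(1,  47, "B", 7, "pass", 10, zone = 2),
    ev_row(1,  52, "B", 10, "shot", zone = 4),
    ev_row(2,   0, "B", 5, "pass", 6, zone = 2, restart = "kickoff"),
    ev_row(2,   6, "B", 6, "pass", NA, completed = FALSE, zone = 2))
  match_log("m1", c("A", "B"), c(2700, 2700), ev)
}

# Brute-force directed local-clustering oracle: explicit loops over all
# ordered neighbour pairs, independent of the package implementation.
clustering_oracle <- function(adj) {
  adj <- (adj > 0) * 1L
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- c()
    for (j in seq_len(n))
      if (j != i && (adj[i, j] == 1L || adj[j, i] == 1L)) nbrs <- c(nbrs, j)
    k <- length(nbrs)
    if (k < 2) { ci[i] <- 0; next }
    links <- 0L
    for (j in nbrs) for (l in nbrs)
      if (j != l && adj[j, l] == 1L) links <- links + 1L
    ci[i] <- links / (k * (k - 1))
  }
  mean(ci)
}

# Random 11x11 directed binary adjacency with zero diagonal.
random_adj <- function(p = 0.15) {
  m <- matrix(rbinom(121, 1, p), 11, 11)
  diag(m) <- 0L
  m
}

# Derivative-free logistic maximum-likelihood oracle (Nelder-Mead on the
# negative log-likelihood), independent of the glm fitting path.
logistic_ml_oracle <- function(y, X) {
  nll <- function(b) {
    eta <- as.vector(X %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  fit <- optim(rep(0, ncol(X)), nll, method = "Nelder-Mead",
               control = list(maxit = 50000, reltol = 1e-15))
  # one restart from the first solution to tighten convergence
  optim(fit$par, nll, method = "Nelder-Mead",
        control = list(maxit = 50000, reltol = 1e-15))$par
}

# Cached small synthetic study shared across test files (12 matches).
.study_cache <- new.env(parent = emptyenv())
demo_study <- function() {
  if (is.null(.study_cache$study))
    .study_cache$study <- simulate_study(sim_params(seed = 20260922))
  .study_cache$study
}

demo_cases <- function() {
  if (is.null(.study_cache$cases)) {
    study <- demo_study()
    .study_cache$cases <- do.call(rbind, lapply(study$logs, function(log)
      compute_cases(build_networks(filter_plays(segment_plays(log)),
                                   log$team_ids))))
  }
  .study_cache$cases
}
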