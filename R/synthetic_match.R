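#' Simulation parameters for synthetic matches
#'
#' Bundles and validates the knobs of the synthetic match generator. The
#' generator emits alternating possessions, each a chain of passes drawn
#' from a per-team passer-to-receiver preference matrix, with zone
#' progression toward the finishing zone, shots, set-piece starts, and an
#' optional planted logistic dependence of network-level success on total
#' passes and density.
#'
#' @param seed Integer base seed; match `i` derives its stream from
#'   `seed + 1000 * i`.
#' @param n_matches Number of matches to simulate (default 12, two teams
#'   each, yielding 24 network cases per match).
#' @param base_half_duration Regulation half length in seconds (default
#'   2700); each half adds stoppage time drawn uniformly from
#'   `stoppage_range`.
#' @param stoppage_range Length-2 numeric, stoppage-time bounds in seconds.
#' @param mean_possessions_per_period Expected possessions (both teams) in
#'   each sixth of the match.
#' @param pass_complete_prob Probability a pass attempt reaches a teammate.
#' @param pass_continue_prob Probability a completed pass is followed by
#'   another pass attempt rather than a loss.
#' @param preference_concentration Concentration of the symmetric Dirichlet
#'   from which each passer's receiver preferences are drawn, once per team
#'   per match. Low values concentrate passes on few partner pairs (high
#'   repeat rate, low network density); high values spread them (high
#'   density).
#' @param zone_advance_prob Probability the ball advances one zone after a
#'   completed pass.
#' @param shot_prob_in_z4 Probability of a shot per action while in the
#'   finishing zone.
#' @param set_piece_rate Fraction of (non-kickoff) possessions starting
#'   from a set piece (corner, throw-in, or a free kick delivered directly
#'   into the finishing zone — all neutral play starts).
#' @param success_model `NULL` for fully natural play outcomes, or a named
#'   numeric vector `c(a, b_total_passes, c_density10)` planting
#'   \eqn{\mathrm{logit}\,P(\text{success}) = a + b\,\mathrm{passes} +
#'   c\,(10\times\mathrm{density})} at the network level (see
#'   [simulate_match()]).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, n_matches = 12L,
                       base_half_duration = 2700,
                       stoppage_range = c(60, 300),
                       mean_possessions_per_period = 22,
                       pass_complete_prob = 0.82,
                       pass_continue_prob = 0.78,
                       preference_concentration = 1,
                       zone_advance_prob = 0.35,
                       shot_prob_in_z4 = 0.35,
                       set_piece_rate = 0.12,
                       success_model = c(a = -0.615, b_total_passes = 0.079,
                                         c_density10 = -1.32)) {
  p <- list(seed = as.integer(seed), n_matches = as.integer(n_matches),
            base_half_duration = base_half_duration,
            stoppage_range = stoppage_range,
            mean_possessions_per_period = mean_possessions_per_period,
            pass_complete_prob = pass_complete_prob,
            pass_continue_prob = pass_continue_prob,
            preference_concentration = preference_concentration,
            zone_advance_prob = zone_advance_prob,
            shot_prob_in_z4 = shot_prob_in_z4,
            set_piece_rate = set_piece_rate,
            success_model = success_model)
  stopifnot(p$n_matches >= 1L, p$base_half_duration > 0,
            length(p$stoppage_range) == 2L, all(p$stoppage_range >= 0),
            p$stoppage_range[1] <= p$stoppage_range[2],
            p$mean_possessions_per_period > 0,
            p$pass_complete_prob > 0, p$pass_complete_prob <= 1,
            p$pass_continue_prob > 0, p$pass_continue_prob <= 1,
            p$preference_concentration > 0,
            p$zone_advance_prob > 0, p$zone_advance_prob <= 1,
            p$shot_prob_in_z4 > 0, p$shot_prob_in_z4 <= 1,
            p$set_piece_rate >= 0, p$set_piece_rate < 1)
  if (!is.null(p$success_model) && length(p$success_model) != 3L)
    stop("success_model must be NULL or 3 coefficients (a, b, c)",
         call. = FALSE)
  class(p) <- "sim_params"
  p
}

# One row of receiver preferences per passer: symmetric Dirichlet over the
# 10 possible receivers, drawn once per team per match.
draw_preferences <- function(concentration) {
  pref <- matrix(0, N_POSITIONS, N_POSITIONS)
  for (i in seq_len(N_POSITIONS)) {
    g <- stats::rgamma(N_POSITIONS - 1L, shape = concentration)
    if (sum(g) <= 0) g[sample.int(N_POSITIONS - 1L, 1L)] <- 1
    pref[i, -i] <- g / sum(g)
  }
  pref
}

# Simulate one possession as parallel event-column vectors. `limit` is the
# last admissible timestamp; `at_half_end` says whether hitting it means
# the half-time whistle (possession retained) or the next possession.
sim_possession <- function(params, team, pref, start_t, limit, at_half_end,
                           restart, z0, zmax, allow_shot, fk_direct) {
  n_alloc <- 40L
  actor <- integer(n_alloc); action <- character(n_alloc)
  receiver <- rep(NA_integer_, n_alloc); completed <- logical(n_alloc)
  zone <- integer(n_alloc); t <- numeric(n_alloc)
  restart_v <- character(n_alloc)
  k <- 0L
  emit <- function(a, act, rec, comp, z, tm, rst) {
    k <<- k + 1L
    actor[k] <<- a; action[k] <<- act; receiver[k] <<- rec
    completed[k] <<- comp; zone[k] <<- z; t[k] <<- tm; restart_v[k] <<- rst
  }
  dt <- function() round(stats::runif(1, 2, 8), 1)

  holder <- sample.int(N_POSITIONS, 1L)
  z <- z0
  tm <- start_t
  reached4 <- FALSE; shot <- FALSE; fk_delivered <- FALSE
  terminal <- if (at_half_end) "retained" else "cut"
  first <- TRUE
  n_passes <- 0L

  repeat {
    # pass attempt by the holder
    comp <- stats::runif(1) < params$pass_complete_prob
    rec <- if (comp) {
      sample.int(N_POSITIONS, 1L, prob = pref[holder, ])
    } else NA_integer_
    emit(holder, "pass", rec, comp, z,
         tm, if (first) restart else "open_play")
    if (!comp) { terminal <- "incomplete_pass"; break }
    n_passes <- n_passes + 1L
    if (first && fk_direct) {
      # free-kick delivery straight into the finishing zone: the reception
      # is a contact in zone 4, after which play resumes outside it
      tm <- tm + dt()
      if (tm > limit) break
      emit(rec, "contact", NA_integer_, FALSE, 4L, tm, "open_play")
      fk_delivered <- TRUE
      z <- 3L
    }
    first <- FALSE
    holder <- rec
    tm <- tm + dt()
    if (stats::runif(1) < params$zone_advance_prob) z <- min(zmax, z + 1L)
    if (z == 4L && !reached4) {
      if (tm > limit) break
      emit(holder, "contact", NA_integer_, FALSE, 4L, tm, "open_play")
      reached4 <- TRUE
      tm <- tm + dt()
    }
    if (z == 4L && allow_shot && stats::runif(1) < params$shot_prob_in_z4) {
      if (tm > limit) break
      emit(holder, "shot", NA_integer_, FALSE, 4L, tm, "open_play")
      shot <- TRUE; terminal <- "shot"; break
    }
    if (stats::runif(1) >= params$pass_continue_prob) {
      if (tm > limit) break
      emit(holder, "loss", NA_integer_, FALSE, z, tm, "open_play")
      terminal <- "loss"; break
    }
    if (tm > limit) break
  }

  idx <- seq_len(k)
  list(team = team, restart = restart, start_t = start_t,
       events = list(actor = actor[idx], action = action[idx],
                     receiver = receiver[idx], completed = completed[idx],
                     zone = zone[idx], t = t[idx],
                     restart = restart_v[idx]),
       n_passes = n_passes, terminal = terminal,
       reached4 = reached4, shot = shot, fk_delivered = fk_delivered)
}

# Natural play category from the generator's own bookkeeping (NA when the
# possession produced no completed pass and hence no play). A free kick
# whose direct delivery was cut off by the whistle or the next possession
# never showed its zone-4 reception, so it reads as an ordinary lost (or
# retained) possession.
natural_category <- function(pos, kind) {
  if (pos$n_passes == 0L) return(NA_character_)
  if (kind == "open") {
    if (pos$shot || pos$reached4) return("SOP")
    if (pos$terminal == "retained") return("neutral")
    return("UOP")
  }
  if (pos$restart == "free_kick" && !pos$fk_delivered) {
    if (pos$terminal == "retained") return("neutral")
    return("UOP")
  }
  "neutral"
}

#' Simulate one synthetic match with ground truth
#'
#' Generates a full match event log: possessions alternate between the two
#' teams at Poisson-distributed start times, each half opens with a
#' kickoff, set pieces start neutral plays, and open-play possessions chain
#' completed passes (receivers drawn from the team's preference matrix),
#' advance zones toward the finishing zone, and end with a loss, an
#' incomplete pass, a shot, or the half-time whistle. Entry into the
#' finishing zone is recorded as a contact event in zone 4.
#'
#' When `params$success_model` is set, network-level success is planted by
#' a matched-pair relabeling: within each (team, period) cell the naturally
#' successful and naturally unsuccessful play groups compete for the
#' successful label, which goes to the natural assignment with probability
#' \eqn{p_1(1-p_2) / [p_1(1-p_2) + p_2(1-p_1)]} where each group's
#' \eqn{p_g} is the planted logit evaluated on its total passes and
#' density — the paired (conditional-logistic) form of the planted model,
#' which degenerates to a fair coin when the slope coefficients are zero.
#' A swap relabels both groups and edits only zones and terminal actions
#' (a demoted play has its zone-4 events lowered and its shot turned into
#' a loss; a promoted play has its final completed pass relocated to the
#' finishing zone), so pass counts and link structure are untouched.
#'
#' @param params A [sim_params()] object.
#' @param match_index Positive integer; determines the match's RNG stream
#'   and identifier.
#' @return A list with `log` (a [match_log()]) and `truth`, the ground-truth
#'   channel: `plays` (one row per play: team, half, start time, period,
#'   final category, completed passes, terminal kind), `possessions` (one
#'   row per possession with its period), and `planted` (one row per
#'   relabeling decision: cell, natural label, group passes and density,
#'   planted probability, drawn label).
#' @export
simulate_match <- function(params, match_index = 1L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 1000L * as.integer(match_index))
  match_id <- sprintf("M%02d", match_index)
  team_ids <- paste0(match_id, c("_A", "_B"))
  half_durations <- params$base_half_duration +
    round(stats::runif(2, params$stoppage_range[1], params$stoppage_range[2]))
  pref_a <- draw_preferences(params$preference_concentration)
  pref_b <- draw_preferences(params$preference_concentration)

  possessions <- list()   # each: sim_possession() result + half + kind
  for (half in 1:2) {
    dur <- half_durations[half]
    n_pos <- stats::rpois(1, 3 * params$mean_possessions_per_period)
    if (n_pos < 1L) next
    starts <- sort(round(stats::runif(n_pos, 0, dur - 10), 1))
    starts[1] <- 0                      # kickoff opens the half
    kick_team <- team_ids[half]         # teams swap the kickoff at half-time
    teams <- rep(c(kick_team, setdiff(team_ids, kick_team)),
                 length.out = n_pos)
    for (i in seq_len(n_pos)) {
      limit <- if (i < n_pos) starts[i + 1L] else dur
      at_half_end <- i == n_pos
      if (i == 1L) {
        kind <- "open"; restart <- "kickoff"; z0 <- 2L
      } else if (stats::runif(1) < params$set_piece_rate) {
        sp <- sample(c("corner", "throw_in", "free_kick"), 1L,
                     prob = c(0.3, 0.4, 0.3))
        kind <- sp; restart <- sp
        z0 <- switch(sp, corner = 3L, throw_in = sample(1:3, 1L),
                     free_kick = sample(2:3, 1L))
      } else {
        kind <- "open"; restart <- "open_play"
        z0 <- sample(1:3, 1L, prob = c(0.3, 0.5, 0.2))
      }
      pref <- if (teams[i] == team_ids[1]) pref_a else pref_b
      pos <- sim_possession(
        params, teams[i], pref, starts[i], limit, at_half_end, restart, z0,
        zmax = if (kind == "open") 4L else 3L,
        allow_shot = kind == "open",
        fk_direct = kind == "free_kick")
      pos$half <- half
      pos$kind <- if (kind == "open") "open" else "set_piece"
      pos$category <- natural_category(pos, pos$kind)
      possessions[[length(possessions) + 1L]] <- pos
    }
  }

  planted <- plant_success(params, possessions, half_durations)
  possessions <- planted$possessions

  log <- assemble_log(match_id, team_ids, half_durations, possessions)
  plays <- possessions[!vapply(possessions,
                               function(p) is.na(p$category), logical(1))]
  truth_plays <- tibble::tibble(
    match_id = match_id,
    team = vapply(plays, function(p) p$team, character(1)),
    half = vapply(plays, function(p) as.integer(p$half), integer(1)),
    start_t = vapply(plays, function(p) p$start_t, numeric(1)),
    category = vapply(plays, function(p) p$category, character(1)),
    n_passes = vapply(plays, function(p) as.integer(p$n_passes), integer(1)),
    terminal = vapply(plays, function(p) p$terminal, character(1)))
  truth_plays$period <- match_period(truth_plays$half, truth_plays$start_t,
                                     half_durations)
  truth_poss <- tibble::tibble(
    match_id = match_id,
    team = vapply(possessions, function(p) p$team, character(1)),
    half = vapply(possessions, function(p) as.integer(p$half), integer(1)),
    start_t = vapply(possessions, function(p) p$start_t, numeric(1)))
  truth_poss$period <- match_period(truth_poss$half, truth_poss$start_t,
                                    half_durations)

  list(log = log,
       truth = list(plays = truth_plays, possessions = truth_poss,
                    planted = planted$decisions))
}

# Plant the success model at the network level with a matched-pair
# assignment. Each (team, period) cell has two candidate play groups: the
# naturally successful plays and the naturally unsuccessful ones. Writing
# p_g = plogis(a + b*passes_g + c*density10_g) for each group's planted
# success probability, the successful label goes to group 1 with
# probability p1(1-p2) / [p1(1-p2) + p2(1-p1)] — the conditional
# (paired-logistic) form of the planted model, so the within-cell contrast
# of the labels follows the planted coefficients exactly. When b = c = 0
# this is a fair coin whatever the intercept, making the two networks of a
# cell exchangeable: an exact null. A swap relabels both groups; edits
# touch zones/terminals only, so pass structure is preserved.
plant_success <- function(params, possessions, half_durations) {
  decisions <- list()
  if (is.null(params$success_model))
    return(list(possessions = possessions, decisions = tibble::tibble()))
  sm <- unname(params$success_model)

  cats <- vapply(possessions,
                 function(p) if (is.na(p$category)) "" else p$category,
                 character(1))
  kinds <- vapply(possessions, function(p) p$kind %||% "open", character(1))
  eligible <- which(cats %in% c("SOP", "UOP") & kinds == "open")
  if (length(eligible) == 0L)
    return(list(possessions = possessions, decisions = tibble::tibble()))

  team <- vapply(possessions, function(p) p$team, character(1))
  period <- vapply(possessions, function(p)
    match_period(p$half, p$start_t, half_durations), integer(1))
  key <- paste(team, period, sep = "|")

  group_stats <- function(idx) {
    if (length(idx) == 0L) return(c(tp = 0, d10 = 0))
    tp <- sum(vapply(possessions[idx], function(p) p$n_passes, integer(1)))
    link <- matrix(FALSE, N_POSITIONS, N_POSITIONS)
    for (p in possessions[idx]) {
      cp <- p$events$action == "pass" & p$events$completed
      link[cbind(p$events$actor[cp], p$events$receiver[cp])] <- TRUE
    }
    c(tp = tp, d10 = 10 * sum(link) / (N_POSITIONS * (N_POSITIONS - 1)))
  }

  for (grp in unique(key[eligible])) {
    idx <- eligible[key[eligible] == grp]
    idx_s <- idx[cats[idx] == "SOP"]
    idx_u <- idx[cats[idx] == "UOP"]
    x1 <- group_stats(idx_s)     # natural successful group
    x2 <- group_stats(idx_u)     # natural unsuccessful group
    p1 <- stats::plogis(sm[1] + sm[2] * x1["tp"] + sm[3] * x1["d10"])
    p2 <- stats::plogis(sm[1] + sm[2] * x2["tp"] + sm[3] * x2["d10"])
    keep_prob <- p1 * (1 - p2) / (p1 * (1 - p2) + p2 * (1 - p1))
    swap <- stats::runif(1) >= keep_prob
    if (swap) {
      for (i in idx_s)
        possessions[[i]] <- relabel_play(possessions[[i]], "UOP",
                                         half_durations)
      for (i in idx_u)
        possessions[[i]] <- relabel_play(possessions[[i]], "SOP",
                                         half_durations)
    }
    decisions[[length(decisions) + 1L]] <- tibble::tibble(
      team = team[idx[1]], period = period[idx[1]],
      tp_s = unname(x1["tp"]), d10_s = unname(x1["d10"]),
      tp_u = unname(x2["tp"]), d10_u = unname(x2["d10"]),
      prob_keep = unname(keep_prob), swapped = swap)
  }
  list(possessions = possessions,
       decisions = do.call(rbind, decisions))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flip a play's outcome by editing zones and terminal actions only, so the
# pass-count and link structure of its cell's network is unchanged.
relabel_play <- function(pos, target, half_durations) {
  ev <- pos$events
  if (target == "UOP") {
    ev$zone[ev$zone == 4L] <- 3L
    sh <- ev$action == "shot"
    ev$action[sh] <- "loss"
    if (pos$terminal == "shot") pos$terminal <- "loss"
    if (pos$terminal == "retained") {
      last_t <- ev$t[length(ev$t)]
      nfin <- length(ev$t)
      holder <- if (ev$action[nfin] == "pass" && ev$completed[nfin])
        ev$receiver[nfin] else ev$actor[nfin]
      ev$actor <- c(ev$actor, holder)
      ev$action <- c(ev$action, "loss")
      ev$receiver <- c(ev$receiver, NA_integer_)
      ev$completed <- c(ev$completed, FALSE)
      ev$zone <- c(ev$zone, ev$zone[nfin])
      ev$t <- c(ev$t, min(last_t + 1, half_durations[pos$half]))
      ev$restart <- c(ev$restart, "open_play")
      pos$terminal <- "loss"
    }
    pos$shot <- FALSE; pos$reached4 <- FALSE
  } else {
    k <- which(ev$action == "pass" & ev$completed)
    k <- k[length(k)]
    ev$zone[k:length(ev$zone)] <- 4L
    pos$reached4 <- TRUE
  }
  pos$events <- ev
  pos$category <- target
  pos
}

# Concatenate possession events into a validated match_log.
assemble_log <- function(match_id, team_ids, half_durations, possessions) {
  if (length(possessions) == 0L)
    return(match_log(match_id, team_ids, half_durations, empty_events()))
  cols <- lapply(possessions, function(p) {
    n <- length(p$events$t)
    tibble::tibble(match_id = rep(match_id, n),
                   half = rep(as.integer(p$half), n),
                   t = p$events$t, team = rep(p$team, n),
                   actor = p$events$actor, action = p$events$action,
                   receiver = p$events$receiver,
                   completed = p$events$completed,
                   zone = p$events$zone, restart = p$events$restart)
  })
  ev <- do.call(rbind, cols)
  ev <- ev[order(ev$half, ev$t), ]
  match_log(match_id, team_ids, half_durations, ev)
}

#' Simulate a multi-match study
#'
#' Runs [simulate_match()] for `params$n_matches` matches and assembles the
#' ground-truth network-case table: one row per (match, period, team,
#' outcome-category) cell — 24 per match — with the cell's true total
#' passes from the ground-truth channel and, where a relabeling decision
#' was taken, the planted success probability.
#'
#' @param params A [sim_params()] object.
#' @return A list with `logs` (list of [match_log()]), `truth` (list of
#'   per-match ground-truth channels) and `cases` (tibble of
#'   `24 * n_matches` ground-truth cases).
#' @export
simulate_study <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  sims <- lapply(seq_len(params$n_matches),
                 function(i) simulate_match(params, i))
  cases <- lapply(sims, function(s) {
    tp <- s$truth$plays
    team_ids <- s$log$team_ids
    grid <- expand.grid(category = c("SOP", "UOP"), team = team_ids,
                        period = 1:6, stringsAsFactors = FALSE)
    grid <- grid[c("period", "team", "category")]
    grid$match_id <- s$log$match_id
    grid$outcome <- as.integer(grid$category == "SOP")
    grid$total_passes <- mapply(function(pd, tm, ct)
      sum(tp$n_passes[tp$period == pd & tp$team == tm & tp$category == ct]),
      grid$period, grid$team, grid$category)
    tibble::as_tibble(grid)
  })
  list(logs = lapply(sims, `[[`, "log"),
       truth = lapply(sims, `[[`, "truth"),
       cases = do.call(rbind, cases))
}

#' Check that preference concentration dials network density
#'
#' Simulates matches at several values of `preference_concentration` and
#' verifies that the mean realized density of non-empty networks is
#' non-decreasing in the concentration (within Monte-Carlo tolerance).
#'
#' @param params A [sim_params()] object (its other settings are kept).
#' @param levels Numeric vector of at least 3 concentration values.
#' @param n_matches Matches simulated per level (default 3).
#' @param tolerance Permitted decrease between consecutive levels.
#' @return A list with `table` (tibble of concentration and mean density)
#'   and `monotone` (logical).
#' @export
density_dial_check <- function(params, levels = c(0.05, 0.5, 5),
                               n_matches = 3L, tolerance = 0.01) {
  stopifnot(length(levels) >= 3L)
  levels <- sort(levels)
  mean_density <- vapply(seq_along(levels), function(li) {
    p <- params
    p$preference_concentration <- levels[li]
    p$n_matches <- n_matches
    p$seed <- params$seed + 10000L * li
    study <- simulate_study(p)
    dens <- unlist(lapply(study$logs, function(log) {
      nets <- build_networks(filter_plays(segment_plays(log)), log$team_ids)
      d <- vapply(nets, pass_density, numeric(1))
      d[vapply(nets, function(n) n$total_passes, numeric(1)) > 0]
    }))
    mean(dens)
  }, numeric(1))
  list(table = tibble::tibble(concentration = levels,
                              mean_density = mean_density),
       monotone = all(diff(mean_density) >= -tolerance))
}

#' Generate network-level regression cases directly
#'
#' A lightweight case-level generator for calibrating and validating the
#' regression suite without running full match simulations: draws total
#' passes and realized links per case, computes density, adds independent
#' clustering and centralization values, and draws the outcome from the
#' planted logit
#' \eqn{\mathrm{logit}\,P(y=1) = a + b\,\mathrm{passes} +
#' c\,(10 \times \mathrm{density})}.
#' Metrics are returned on their raw `[0, 1]` scale (see
#' [rescale_metrics()]).
#'
#' @param n Number of cases.
#' @param coef Length-3 numeric `(a, b, c)` of the planted logit.
#' @param mean_passes Mean of the Poisson total-pass draw.
#' @return A tibble of analysis-ready cases with a `prob` column holding
#'   the planted success probability.
#' @export
simulate_cases <- function(n, coef = c(-0.615, 0.079, -1.32),
                           mean_passes = 12) {
  stopifnot(length(coef) == 3L)
  total_passes <- stats::rpois(n, mean_passes)
  max_links <- N_POSITIONS * (N_POSITIONS - 1L)
  links <- stats::rbinom(n, size = pmin(total_passes, max_links), prob = 0.7)
  density <- links / max_links
  clustering <- stats::runif(n, 0, 0.3)
  centralization <- stats::runif(n, 0, 0.4)
  prob <- stats::plogis(coef[1] + coef[2] * total_passes +
                        coef[3] * 10 * density)
  tibble::tibble(
    match_id = NA_character_, team = NA_character_, period = NA_integer_,
    outcome = stats::rbinom(n, 1L, prob),
    total_passes = as.integer(total_passes),
    density = density, clustering = clustering,
    centralization = centralization, prob = prob)
}
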