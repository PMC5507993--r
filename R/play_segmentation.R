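#' Segment a match log into offensive plays
#'
#' Walks the event stream of each half and cuts it into possessions. A team
#' is considered in possession — and an offensive play starts — at its first
#' completed pass of a possession; the play ends at a possession-losing event
#' (a `loss`, an incomplete pass), at a `shot`, or at the end of the half.
#' Same-team events before the first completed pass (a stray contact, a
#' failed first pass) start no play. If the ball changes team without an
#' explicit possession-losing event the previous run is closed as an
#' unrecorded turnover and treated as a lost possession.
#'
#' @param log A [match_log()].
#' @return A list of uncategorized `offensive_play` objects, in match order.
#'   Each holds the play's team, half, start time, event table, completed
#'   pass count `n_passes`, and how it terminated (`"loss"`,
#'   `"incomplete_pass"`, `"shot"`, `"turnover_unrecorded"`, `"retained"`).
#' @seealso [categorize_play()], [assign_period()], [filter_plays()]
#' @export
segment_possessions <- function(log) {
  validate_match_log(log)
  ev <- log$events
  plays <- list()
  if (nrow(ev) == 0L) return(plays)

  is_terminal <- ev$action %in% c("shot", "loss") |
    (ev$action == "pass" & !ev$completed)
  terminal_kind <- ifelse(ev$action == "shot", "shot",
                   ifelse(ev$action == "loss", "loss", "incomplete_pass"))

  close_run <- function(idx, terminal) {
    first_pass <- idx[ev$action[idx] == "pass" & ev$completed[idx]]
    if (length(first_pass) == 0L) return(NULL)
    keep <- idx[idx >= first_pass[1]]
    pe <- ev[keep, ]
    structure(list(
      match_id = log$match_id,
      team = pe$team[1],
      half = pe$half[1],
      start_t = pe$t[1],
      events = pe,
      n_passes = sum(pe$action == "pass" & pe$completed),
      terminal = terminal,
      category = NA_character_,
      period = NA_integer_), class = "offensive_play")
  }

  for (h in unique(ev$half)) {
    rows <- which(ev$half == h)
    run <- integer(0)
    for (i in rows) {
      if (length(run) > 0L && ev$team[i] != ev$team[run[1]]) {
        p <- close_run(run, "turnover_unrecorded")
        if (!is.null(p)) plays[[length(plays) + 1L]] <- p
        run <- integer(0)
      }
      run <- c(run, i)
      if (is_terminal[i]) {
        p <- close_run(run, terminal_kind[i])
        if (!is.null(p)) plays[[length(plays) + 1L]] <- p
        run <- integer(0)
      }
    }
    if (length(run) > 0L) {
      p <- close_run(run, "retained")
      if (!is.null(p)) plays[[length(plays) + 1L]] <- p
    }
  }
  plays
}

#' @export
print.offensive_play <- function(x, ...) {
  cat(sprintf("<offensive_play> %s %s h%d t=%.1f: %d passes, terminal=%s, category=%s, period=%s\n",
              x$match_id, x$team, x$half, x$start_t, x$n_passes, x$terminal,
              x$category, x$period))
  invisible(x)
}

# TRUE for each event that counts as holding the ball in the finishing zone:
# a completed pass, a contact or a shot taken in zone 4. Possession-losing
# events (loss, incomplete pass) do not qualify.
qualifying_zone4 <- function(pe) {
  pe$zone == 4L &
    (pe$action %in% c("contact", "shot") | (pe$action == "pass" & pe$completed))
}

# A free kick whose first (completed) pass is delivered directly into the
# finishing zone: the delivery's reception (second event) is in zone 4.
free_kick_direct <- function(pe) {
  nrow(pe) >= 2L && pe$restart[1] == "free_kick" &&
    pe$action[1] == "pass" && pe$completed[1] && pe$zone[2] == 4L
}

#' Categorize an offensive play as SOP, UOP or neutral
#'
#' A play is a *successful offensive play* (SOP) when it contains a shot at
#' goal, or when the team holds the ball in the finishing zone (a completed
#' pass, contact or shot in zone 4). For plays started from a free kick
#' whose first pass is delivered directly into the finishing zone, that
#' delivery and its immediate reception do not count as finishing-zone
#' entry — such plays are *neutral* unless a later event meets an SOP
#' criterion. Plays started from an offensive corner or throw-in, and plays
#' truncated by the half-time whistle with possession retained, are neutral
#' when no SOP criterion is met. Every other play — possession lost without
#' meeting the SOP criteria — is an *unsuccessful offensive play* (UOP).
#'
#' @param play An `offensive_play` from [segment_possessions()].
#' @return The play with its `category` field set to `"SOP"`, `"UOP"` or
#'   `"neutral"`.
#' @export
categorize_play <- function(play) {
  stopifnot(inherits(play, "offensive_play"))
  pe <- play$events
  fk_direct <- free_kick_direct(pe)
  z4 <- qualifying_zone4(pe)
  if (fk_direct) z4[1:2] <- FALSE
  sop <- any(pe$action == "shot") || any(z4)

  play$category <- if (sop) {
    "SOP"
  } else if (pe$restart[1] %in% c("corner", "throw_in") || fk_direct ||
             play$terminal == "retained") {
    "neutral"
  } else {
    "UOP"
  }
  play
}

# Vectorized period formula: half 1 -> 1..3, half 2 -> 4..6; each half split
# into three equal fractions, half-open [lower, upper) except the last,
# which is closed at the half's end.
match_period <- function(half, t, half_durations) {
  dur <- half_durations[half]
  if (any(t > dur))
    stop("play start time exceeds the duration of its half", call. = FALSE)
  if (any(t < 0)) stop("play start time is negative", call. = FALSE)
  frac <- pmin(3L, as.integer(floor(3 * t / dur)) + 1L)
  3L * (as.integer(half) - 1L) + frac
}

#' Assign a play to one of six match periods
#'
#' Each half is divided into three fractions of equal duration (stoppage
#' time included, so the two halves may differ in length). A play belongs to
#' the fraction containing its first event; fraction boundaries are
#' half-open `[lower, upper)` except the final fraction, which is closed at
#' the half's end. Periods are numbered 1–3 in the first half and 4–6 in
#' the second.
#'
#' @param play An `offensive_play`.
#' @param half_durations Numeric length-2 half durations in seconds.
#' @return The play with its `period` field set to an integer in 1..6.
#' @export
assign_period <- function(play, half_durations) {
  stopifnot(inherits(play, "offensive_play"))
  play$period <- match_period(play$half, play$start_t, half_durations)
  play
}

#' Segment, categorize and period-assign all plays of a match
#'
#' Convenience wrapper chaining [segment_possessions()],
#' [categorize_play()] and [assign_period()].
#'
#' @param log A [match_log()].
#' @return A list of fully annotated `offensive_play` objects.
#' @export
segment_plays <- function(log) {
  plays <- segment_possessions(log)
  lapply(plays, function(p)
    assign_period(categorize_play(p), log$half_durations))
}

#' Drop neutral plays and split the rest by outcome
#'
#' Neutral offensive plays are excluded from the analysis; the remainder is
#' partitioned into successful (SOP) and unsuccessful (UOP) plays.
#'
#' @param plays A list of categorized `offensive_play` objects.
#' @return A list with elements `SOP` and `UOP`, each a list of plays.
#' @export
filter_plays <- function(plays) {
  cats <- vapply(plays, function(p) p$category, character(1))
  if (anyNA(cats))
    stop("plays must be categorized before filtering", call. = FALSE)
  list(SOP = plays[cats == "SOP"], UOP = plays[cats == "UOP"])
}

#' Tabulate plays for audit
#'
#' One row per play: match, team, half, start time, period, category,
#' completed-pass count and terminal event kind. Suitable for CSV export.
#'
#' @param plays A list of `offensive_play` objects.
#' @return A tibble.
#' @export
plays_table <- function(plays) {
  tibble::tibble(
    match_id = vapply(plays, function(p) p$match_id, character(1)),
    team     = vapply(plays, function(p) p$team, character(1)),
    half     = vapply(plays, function(p) p$half, integer(1)),
    start_t  = vapply(plays, function(p) p$start_t, numeric(1)),
    period   = vapply(plays, function(p) as.integer(p$period), integer(1)),
    category = vapply(plays, function(p) p$category, character(1)),
    n_passes = vapply(plays, function(p) as.integer(p$n_passes), integer(1)),
    terminal = vapply(plays, function(p) p$terminal, character(1)))
}
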