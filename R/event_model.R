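#' passnet: passing-network predictors of offensive play success
#'
#' Analyse directed ball-passing networks in association football and relate
#' their structure to the outcome of offensive plays. The pipeline runs from
#' raw match event logs through possession segmentation and per-period
#' network construction to a two-block hierarchical logistic regression with
#' full screening and goodness-of-fit diagnostics. A synthetic match
#' simulator with a ground-truth channel supports end-to-end validation.
#'
#' @section Pipeline:
#' \enumerate{
#'   \item [read_event_log()] / [simulate_match()] — obtain a `match_log`.
#'   \item [segment_possessions()], [categorize_play()], [assign_period()],
#'     [filter_plays()] — offensive plays.
#'   \item [build_networks()] — 24 passing networks per match.
#'   \item [compute_cases()] — one regression case per network, with
#'     [pass_density()], [avg_clustering()] and [degree_centralization()].
#'   \item [screen_cases()], [hierarchical_fit()], [model_report()] — the
#'     regression suite.
#' }
#'
#' @name passnet-package
#' @keywords internal
"_PACKAGE"

ACTIONS  <- c("pass", "contact", "shot", "loss")
RESTARTS <- c("open_play", "corner", "throw_in", "free_kick", "kickoff")
N_POSITIONS <- 11L

EVENT_COLS <- c("match_id", "half", "t", "team", "actor", "action",
                "receiver", "completed", "zone", "restart")

#' Construct a match event log
#'
#' A `match_log` bundles the ordered ball-event records of one match with its
#' match-level metadata. Each event records the acting team, the actor's
#' tactical position (1–11; substitutes inherit the position number), the
#' action (`pass`, `contact`, `shot`, `loss`), the receiver position for
#' completed passes, the pitch zone 1–4 coded in the acting team's attack
#' direction (4 = finishing zone), and the restart context.
#'
#' @param match_id Match identifier (scalar character).
#' @param team_ids Character vector of the two team identifiers.
#' @param half_durations Numeric length-2: full duration of each half in
#'   seconds, including stoppage time.
#' @param events A data frame with columns `match_id`, `half` (1 or 2), `t`
#'   (seconds from the start of the half), `team`, `actor` (1–11), `action`,
#'   `receiver` (1–11 or `NA`), `completed` (logical), `zone` (1–4),
#'   `restart`. Events must be ordered by half and non-decreasing `t`.
#' @return A validated object of class `match_log`.
#' @seealso [read_event_log()], [write_event_log()], [segment_possessions()]
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   match_id = "m1", half = 1L, t = c(0, 3, 6), team = "A",
#'   actor = c(5L, 6L, 8L), action = c("pass", "pass", "loss"),
#'   receiver = c(6L, 8L, NA), completed = c(TRUE, TRUE, FALSE),
#'   zone = c(2L, 2L, 3L), restart = c("kickoff", "open_play", "open_play"))
#' log <- match_log("m1", c("A", "B"), c(2700, 2700), ev)
match_log <- function(match_id, team_ids, half_durations, events) {
  events <- as_event_tibble(events)
  x <- structure(
    list(match_id = as.character(match_id),
         team_ids = as.character(team_ids),
         half_durations = as.numeric(half_durations),
         events = events),
    class = "match_log")
  validate_match_log(x)
  x
}

# Coerce an event data frame to the canonical column set and types.
as_event_tibble <- function(events) {
  events <- tibble::as_tibble(events)
  missing <- setdiff(EVENT_COLS, names(events))
  if (length(missing) > 0L)
    stop("event table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  events <- events[EVENT_COLS]
  events$match_id  <- as.character(events$match_id)
  events$half      <- as.integer(events$half)
  events$t         <- as.numeric(events$t)
  events$team      <- as.character(events$team)
  events$actor     <- as.integer(events$actor)
  events$action    <- as.character(events$action)
  events$receiver  <- as.integer(events$receiver)
  events$completed <- as.logical(events$completed)
  events$zone      <- as.integer(events$zone)
  events$restart   <- as.character(events$restart)
  events
}

#' Validate a match log
#'
#' Checks every structural invariant of the event schema and fails with a
#' message naming the offending row and field. Invariants: two distinct
#' teams; two positive half durations; per event, `half` in \{1, 2\},
#' `t >= 0` and within its half's duration, known team, positions in 1–11,
#' known action and restart, zone in 1–4; a receiver is present exactly for
#' completed passes and never equals the actor; timestamps are non-decreasing
#' within each half.
#'
#' @param x A `match_log`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_match_log <- function(x) {
  stopifnot(inherits(x, "match_log"))
  if (length(x$match_id) != 1L || is.na(x$match_id))
    stop("match_id must be a single non-missing identifier", call. = FALSE)
  if (length(x$team_ids) != 2L || anyNA(x$team_ids) ||
      x$team_ids[1] == x$team_ids[2])
    stop("team_ids must hold exactly two distinct team identifiers",
         call. = FALSE)
  if (length(x$half_durations) != 2L || anyNA(x$half_durations) ||
      any(x$half_durations <= 0))
    stop("half_durations must be two positive durations in seconds",
         call. = FALSE)

  ev <- x$events
  n <- nrow(ev)
  if (n == 0L) return(invisible(x))

  bad_row <- function(cond, field, why) {
    i <- which(cond)
    if (length(i) > 0L)
      stop(sprintf("event row %d: field '%s' %s", i[1], field, why),
           call. = FALSE)
  }
  bad_row(is.na(ev$match_id) | ev$match_id != x$match_id,
          "match_id", "does not match the log's match_id")
  bad_row(is.na(ev$half) | !(ev$half %in% c(1L, 2L)), "half",
          "must be 1 or 2")
  bad_row(is.na(ev$t) | ev$t < 0, "t", "must be a non-negative time")
  bad_row(ev$t > x$half_durations[ev$half], "t",
          "exceeds the duration of its half")
  bad_row(is.na(ev$team) | !(ev$team %in% x$team_ids), "team",
          "is not one of the match's team_ids")
  bad_row(is.na(ev$actor) | ev$actor < 1L | ev$actor > N_POSITIONS, "actor",
          "must be a tactical position in 1..11")
  bad_row(is.na(ev$action) | !(ev$action %in% ACTIONS), "action",
          paste0("must be one of ", paste(ACTIONS, collapse = "/")))
  bad_row(is.na(ev$completed), "completed", "must be TRUE or FALSE")
  bad_row(is.na(ev$zone) | ev$zone < 1L | ev$zone > 4L, "zone",
          "must be a pitch zone in 1..4")
  bad_row(is.na(ev$restart) | !(ev$restart %in% RESTARTS), "restart",
          paste0("must be one of ", paste(RESTARTS, collapse = "/")))

  has_rec <- !is.na(ev$receiver)
  bad_row(has_rec & (ev$receiver < 1L | ev$receiver > N_POSITIONS),
          "receiver", "must be a tactical position in 1..11")
  bad_row(has_rec & ev$receiver == ev$actor, "receiver",
          "equals actor (a player cannot pass to himself)")
  bad_row(ev$action == "pass" & ev$completed & !has_rec, "receiver",
          "must be present for a completed pass")
  bad_row(ev$action != "pass" & has_rec, "receiver",
          "must be absent unless the action is a completed pass")
  bad_row(ev$action != "pass" & ev$completed, "completed",
          "must be FALSE for non-pass actions")
  bad_row(ev$action == "pass" & !ev$completed & has_rec, "receiver",
          "must be absent for an incomplete pass")

  # monotone time within each half; halves must not interleave
  if (any(diff(ev$half) < 0L))
    stop(sprintf("event row %d: field 'half' decreases (halves must be contiguous)",
                 which(diff(ev$half) < 0L)[1] + 1L), call. = FALSE)
  for (h in unique(ev$half)) {
    th <- ev$t[ev$half == h]
    if (any(diff(th) < 0)) {
      i <- which(ev$half == h)[which(diff(th) < 0)[1] + 1L]
      stop(sprintf("event row %d: field 't' decreases within half %d", i, h),
           call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.match_log <- function(x, ...) {
  cat(sprintf("<match_log> %s: %s vs %s, %d events, halves %.0f + %.0f s\n",
              x$match_id, x$team_ids[1], x$team_ids[2], nrow(x$events),
              x$half_durations[1], x$half_durations[2]))
  invisible(x)
}

#' Read a match event log from CSV or JSON
#'
#' The CSV dialect is comma-separated UTF-8 with a header row of the exact
#' event field names; an absent receiver is encoded as an empty string.
#' Match-level metadata travel as comment lines above the header
#' (`#match_id: ...`, `#team_ids: A,B`, `#half_durations: 2700,2760`). The
#' JSON form is an object with keys `match_id`, `team_ids`, `half_durations`
#' and `events` (array of event records). Both formats round-trip losslessly
#' through [write_event_log()].
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return A validated [match_log()].
#' @export
read_event_log <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    ev <- obj$events
    if (is.null(ev) || length(ev) == 0L || NROW(ev) == 0L) ev <- empty_events()
    return(match_log(obj$match_id, obj$team_ids, obj$half_durations, ev))
  }

  head_lines <- readLines(path, n = 10L, encoding = "UTF-8")
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta_get <- function(key) {
    ln <- grep(paste0("^#", key, ":"), meta_lines, value = TRUE)
    if (length(ln) == 0L)
      stop("CSV event log lacks the '#", key, ":' metadata line", call. = FALSE)
    trimws(sub(paste0("^#", key, ":"), "", ln[1]))
  }
  match_id <- meta_get("match_id")
  team_ids <- trimws(strsplit(meta_get("team_ids"), ",")[[1]])
  half_durations <- as.numeric(strsplit(meta_get("half_durations"), ",")[[1]])

  ev <- utils::read.csv(path, comment.char = "#", na.strings = "",
                        stringsAsFactors = FALSE,
                        colClasses = c(
                          match_id = "character", half = "integer",
                          t = "numeric", team = "character",
                          actor = "integer", action = "character",
                          receiver = "integer", completed = "logical",
                          zone = "integer", restart = "character"))
  if (nrow(ev) == 0L) ev <- empty_events()
  match_log(match_id, team_ids, half_durations, ev)
}

#' Write a match event log to CSV or JSON
#'
#' @param log A [match_log()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, format = c("auto", "csv", "json")) {
  validate_match_log(log)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"

  if (format == "json") {
    obj <- list(match_id = log$match_id, team_ids = log$team_ids,
                half_durations = log$half_durations,
                events = as.data.frame(log$events))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
    return(invisible(path))
  }

  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("#match_id: ", log$match_id),
    paste0("#team_ids: ", paste(log$team_ids, collapse = ",")),
    paste0("#half_durations: ",
           paste(format(log$half_durations, digits = 15, scientific = FALSE),
                 collapse = ","))), con)
  ev <- as.data.frame(log$events)
  ev$t <- format(ev$t, digits = 15, scientific = FALSE, trim = TRUE)
  utils::write.csv(ev, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

empty_events <- function() {
  tibble::tibble(match_id = character(), half = integer(), t = numeric(),
                 team = character(), actor = integer(), action = character(),
                 receiver = integer(), completed = logical(), zone = integer(),
                 restart = character())
}
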