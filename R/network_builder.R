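#' Construct a passing network
#'
#' A `pass_network` is the directed ball-passing graph of one
#' (match, period, team, outcome-category) cell. Nodes are the 11 tactical
#' positions, always all present; `weight[i, j]` counts completed passes
#' from position `i` to position `j` and `link` is its binarization (a
#' *link* is a unique passer–receiver pair with at least one completed
#' pass).
#'
#' @param match_id,team,period,category Cell identity; `category` is
#'   `"SOP"` or `"UOP"`.
#' @param weight An 11x11 non-negative integer matrix of pass counts with a
#'   zero diagonal.
#' @return An object of class `pass_network` with fields `match_id`, `team`,
#'   `period`, `category`, `n_nodes` (fixed 11), `link`, `weight` and
#'   `total_passes`.
#' @export
pass_network <- function(match_id, team, period, category, weight) {
  weight <- as.matrix(weight)
  if (!all(dim(weight) == c(N_POSITIONS, N_POSITIONS)))
    stop("weight must be an 11x11 matrix", call. = FALSE)
  if (any(weight < 0) || any(weight != round(weight)))
    stop("weight must hold non-negative integer pass counts", call. = FALSE)
  if (any(diag(weight) != 0))
    stop("weight has non-zero diagonal entries (self-passes)", call. = FALSE)
  if (!category %in% c("SOP", "UOP"))
    stop("category must be 'SOP' or 'UOP'", call. = FALSE)
  storage.mode(weight) <- "integer"
  dimnames(weight) <- list(seq_len(N_POSITIONS), seq_len(N_POSITIONS))
  structure(list(
    match_id = as.character(match_id), team = as.character(team),
    period = as.integer(period), category = category,
    n_nodes = N_POSITIONS,
    link = (weight > 0L) * 1L,
    weight = weight,
    total_passes = sum(weight)), class = "pass_network")
}

#' @export
print.pass_network <- function(x, ...) {
  cat(sprintf("<pass_network> %s %s period %d %s: %d links, %d passes\n",
              x$match_id, x$team, x$period, x$category,
              sum(x$link), x$total_passes))
  invisible(x)
}

#' Build the 24 passing networks of one match
#'
#' Aggregates the categorized plays of a single match into one directed
#' passing network per (period x team x outcome-category) cell: 6 periods x
#' 2 teams x \{SOP, UOP\} = 24 networks per match. Neutral plays must
#' already have been removed (see [filter_plays()]). Cells with no plays
#' are materialized as all-zero networks so the 24-per-match contract is
#' structural; zero-pass SOP networks are dropped later, at screening.
#'
#' @param plays A list of categorized, period-assigned `offensive_play`
#'   objects from one match (categories `"SOP"`/`"UOP"` only), or the
#'   `SOP`/`UOP` list returned by [filter_plays()].
#' @param team_ids Character vector of the match's two team identifiers;
#'   required so empty cells can be materialized even for a team with no
#'   plays.
#' @return A list of 24 [pass_network()] objects, ordered by period, then
#'   team (order of `team_ids`), then category (SOP before UOP).
#' @export
build_networks <- function(plays, team_ids) {
  if (is.list(plays) && identical(sort(names(plays)), c("SOP", "UOP")) &&
      !inherits(plays, "offensive_play"))
    plays <- c(plays$SOP, plays$UOP)
  if (length(team_ids) != 2L || team_ids[1] == team_ids[2])
    stop("team_ids must name the match's two teams", call. = FALSE)

  mids <- unique(vapply(plays, function(p) p$match_id, character(1)))
  if (length(mids) > 1L)
    stop("build_networks expects plays from a single match; got: ",
         paste(mids, collapse = ", "), call. = FALSE)
  match_id <- if (length(mids) == 1L) mids else NA_character_

  cats <- vapply(plays, function(p) p$category, character(1))
  if (any(!cats %in% c("SOP", "UOP")))
    stop("plays must be categorized SOP/UOP (drop neutral plays first)",
         call. = FALSE)

  nets <- vector("list", 24L)
  k <- 0L
  for (period in 1:6) for (team in team_ids) for (cat in c("SOP", "UOP")) {
    w <- matrix(0L, N_POSITIONS, N_POSITIONS)
    sel <- plays[cats == cat &
                 vapply(plays, function(p) p$team, character(1)) == team &
                 vapply(plays, function(p) as.integer(p$period), integer(1)) == period]
    for (p in sel) {
      pe <- p$events
      cp <- pe$action == "pass" & pe$completed
      if (any(cp)) {
        idx <- cbind(pe$actor[cp], pe$receiver[cp])
        for (r in seq_len(nrow(idx)))
          w[idx[r, 1], idx[r, 2]] <- w[idx[r, 1], idx[r, 2]] + 1L
      }
    }
    k <- k + 1L
    nets[[k]] <- pass_network(match_id, team, period, cat, w)
  }
  nets
}

#' Export a passing network
#'
#' Writes a network as a weighted edge-list CSV (`source,target,weight`),
#' as GraphML (pass counts carried as the `weight` edge attribute, all 11
#' nodes present even when isolated), or as a full 11x11 adjacency CSV of
#' pass counts. All three are lossless for the weight matrix.
#'
#' @param net A [pass_network()].
#' @param path Output file path.
#' @param format `"edge_csv"`, `"graphml"` or `"adjacency_csv"`.
#' @return `path`, invisibly.
#' @seealso [import_network()]
#' @export
export_network <- function(net, path,
                           format = c("edge_csv", "graphml", "adjacency_csv")) {
  stopifnot(inherits(net, "pass_network"))
  format <- match.arg(format)
  if (format == "edge_csv") {
    idx <- which(net$weight > 0L, arr.ind = TRUE)
    df <- data.frame(source = idx[, 1], target = idx[, 2],
                     weight = net$weight[idx])
    df <- df[order(df$source, df$target), , drop = FALSE]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (format == "adjacency_csv") {
    utils::write.csv(as.data.frame(net$weight), path, row.names = FALSE,
                     quote = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(net$weight, mode = "directed",
                                             weighted = TRUE, diag = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a passing network written by [export_network()]
#'
#' @param path File path.
#' @param format `"edge_csv"`, `"graphml"` or `"adjacency_csv"`.
#' @param match_id,team,period,category Cell identity to attach (the export
#'   formats carry only the graph).
#' @return A [pass_network()].
#' @export
import_network <- function(path,
                           format = c("edge_csv", "graphml", "adjacency_csv"),
                           match_id = NA, team = NA, period = 1L,
                           category = "UOP") {
  format <- match.arg(format)
  w <- matrix(0L, N_POSITIONS, N_POSITIONS)
  if (format == "edge_csv") {
    df <- utils::read.csv(path)
    if (nrow(df) > 0L)
      w[cbind(df$source, df$target)] <- as.integer(df$weight)
  } else if (format == "adjacency_csv") {
    m <- as.matrix(utils::read.csv(path))
    if (!all(dim(m) == c(N_POSITIONS, N_POSITIONS)))
      stop("adjacency CSV must be 11x11", call. = FALSE)
    w[] <- as.integer(m)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::vcount(g) != N_POSITIONS)
      stop("GraphML network must have 11 nodes", call. = FALSE)
    m <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g) > 0L)
      "weight" else NULL, sparse = FALSE)
    w[] <- as.integer(m)
  }
  pass_network(match_id, team, period, category, w)
}
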