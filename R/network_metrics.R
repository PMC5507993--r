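#' Density of a passing network
#'
#' The interconnectedness of the 11 tactical positions: the ratio of
#' registered directed links L (unique passer-receiver pairs with at least
#' one completed pass) to the n(n-1) possible directed links of an 11-node
#' digraph,
#' \deqn{\Delta = \frac{L}{n(n-1)},\qquad n = 11.}
#' Pass counts beyond the first on a pair do not change density; 0 means no
#' links, 1 means every ordered pair of distinct positions is linked.
#'
#' @param net A [pass_network()], or an 11x11 binary/weighted adjacency
#'   matrix (zero diagonal).
#' @return Density in `[0, 1]`.
#' @export
pass_density <- function(net) {
  link <- net_link(net)
  n <- N_POSITIONS
  sum(link) / (n * (n - 1))
}

# Accept a pass_network or a raw adjacency matrix; return binary link matrix.
net_link <- function(net) {
  if (inherits(net, "pass_network")) return(net$link)
  m <- as.matrix(net)
  if (!all(dim(m) == c(N_POSITIONS, N_POSITIONS)))
    stop("adjacency matrix must be 11x11", call. = FALSE)
  if (any(diag(m) != 0))
    stop("adjacency matrix must have a zero diagonal", call. = FALSE)
  (m > 0) * 1L
}

#' Local clustering coefficient of one position
#'
#' For a directed passing graph, the neighborhood of position `i` is the
#' set of positions linked with it in either direction; the local
#' clustering coefficient is the fraction of directed links realized among
#' those \eqn{k_i} neighbors out of the \eqn{k_i(k_i - 1)} possible:
#' \deqn{C_i = \frac{|\{a_{jk}\in E : j, k \in N(i)\}|}{k_i (k_i - 1)}.}
#' Positions with fewer than two neighbors have an undefined ratio (0/0)
#' and contribute 0 by convention.
#'
#' @param net A [pass_network()] or 11x11 adjacency matrix.
#' @param i Node index in 1..11.
#' @return `C_i` in `[0, 1]`.
#' @export
local_clustering <- function(net, i) {
  link <- net_link(net)
  if (length(i) != 1L || is.na(i) || i < 1L || i > N_POSITIONS)
    stop("node index must lie in 1..11", call. = FALSE)
  nbrs <- which(link[i, ] > 0L | link[, i] > 0L)
  k <- length(nbrs)
  if (k < 2L) return(0)
  sum(link[nbrs, nbrs]) / (k * (k - 1))
}

#' Average local clustering coefficient
#'
#' The mean of [local_clustering()] over all 11 positions,
#' \eqn{\bar C = \frac{1}{n}\sum_i C_i}; isolated positions contribute 0,
#' so unused positions dilute the average.
#'
#' @param net A [pass_network()] or 11x11 adjacency matrix.
#' @return \eqn{\bar C} in `[0, 1]`.
#' @export
avg_clustering <- function(net) {
  link <- net_link(net)
  mean(vapply(seq_len(N_POSITIONS),
              function(i) local_clustering(link, i), numeric(1)))
}

#' Freeman degree centralization
#'
#' How dominant the most-connected position is: the sum of differences
#' between the maximal degree and every position's degree, normalized by
#' its maximum over graphs of the same size,
#' \deqn{C_D = \frac{\sum_i (\deg v^* - \deg v_i)}{n^2 - 3n + 2}.}
#' With `degree = "symmetrized"` (default) the degree of a position is the
#' number of distinct positions it exchanges passes with in either
#' direction; the denominator \eqn{(n-1)(n-2) = 90} then makes the star
#' attain exactly 1 and degree-regular graphs 0. The alternative
#' `degree = "directed_total"` uses in-degree + out-degree on the directed
#' link graph (a convention under which values may exceed 1); it is
#' provided for sensitivity checks.
#'
#' @param net A [pass_network()] or 11x11 adjacency matrix.
#' @param degree Degree convention, `"symmetrized"` or `"directed_total"`.
#' @return Centralization (in `[0, 1]` for the default convention).
#' @export
degree_centralization <- function(net, degree = c("symmetrized",
                                                  "directed_total")) {
  link <- net_link(net)
  degree <- match.arg(degree)
  deg <- if (degree == "symmetrized") {
    sym <- (link | t(link)) * 1L
    rowSums(sym)
  } else {
    rowSums(link) + colSums(link)
  }
  n <- N_POSITIONS
  sum(max(deg) - deg) / (n^2 - 3 * n + 2)
}

#' Build regression cases from passing networks
#'
#' Turns each network into one observation for the regression suite:
#' outcome 1 for successful-play (SOP) networks and 0 for unsuccessful
#' (UOP) ones, the total completed passes, and the three structural
#' metrics on their natural `[0, 1]` scale.
#'
#' @param networks A list of [pass_network()] objects.
#' @return A tibble with columns `match_id`, `team`, `period`, `outcome`,
#'   `total_passes`, `density`, `clustering`, `centralization`.
#' @export
compute_cases <- function(networks) {
  stopifnot(all(vapply(networks, inherits, logical(1), "pass_network")))
  tibble::tibble(
    match_id = vapply(networks, function(x) x$match_id, character(1)),
    team = vapply(networks, function(x) x$team, character(1)),
    period = vapply(networks, function(x) x$period, integer(1)),
    outcome = as.integer(
      vapply(networks, function(x) x$category, character(1)) == "SOP"),
    total_passes = vapply(networks, function(x) as.integer(x$total_passes),
                          integer(1)),
    density = vapply(networks, pass_density, numeric(1)),
    clustering = vapply(networks, avg_clustering, numeric(1)),
    centralization = vapply(networks, degree_centralization, numeric(1)))
}
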