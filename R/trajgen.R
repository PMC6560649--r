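# Location-choice mechanisms. Each chooser picks the next physical location
# for a non-routine stay, never returning the agent's current location:
#   d-EPR - exploration vs preferential return, exploration biased by a
#           gravity kernel over relevance and distance;
#   SWIM  - weight mixing closeness to home and location popularity;
#   LATP  - inverse-power preference for short trips from the current place.

#' Agent visitation state
#'
#' Tracks what a simulated agent has visited so far: the current location,
#' per-location visit counts (slots spent), and the home location. The home
#' is counted as visited from the start.
#'
#' @param home `location_id` of the agent's home.
#' @return An environment of class `agent_state` with fields `current`,
#'   `counts` (named numeric), `home`.
#' @export
agent_state <- function(home) {
  stopifnot(length(home) == 1L)
  e <- new.env(parent = emptyenv())
  e$home <- as.character(home)
  e$current <- e$home
  e$counts <- stats::setNames(1, e$home)
  class(e) <- "agent_state"
  e
}

#' @export
print.agent_state <- function(x, ...) {
  cat("Agent at", x$current, "| home", x$home, "|",
      length(x$counts), "distinct location(s) visited\n")
  invisible(x)
}

#' Number of distinct locations an agent has visited
#' @param agent An [agent_state()].
#' @export
n_distinct_locations <- function(agent) length(agent$counts)

#' d-EPR parameters
#'
#' Constants of the exploration probability `p_new = rho * N^(-gamma)`.
#'
#' @param rho Scale of the exploration probability (default 0.6).
#' @param gamma Decay exponent in the number of distinct visited locations
#'   (default 0.21).
#' @return A list of class `depr_params`.
#' @export
depr_params <- function(rho = 0.6, gamma = 0.21) {
  stopifnot(rho > 0, rho <= 1, gamma >= 0)
  structure(list(rho = rho, gamma = gamma), class = "depr_params")
}

#' Exploration probability of the d-EPR model
#'
#' `p_new = rho * N^(-gamma)` where `N` is the number of distinct locations
#' the agent has visited. Monotonically non-increasing in `N`: agents explore
#' greedily at first and settle into preferential return as their location
#' set grows.
#'
#' @param n_distinct Number of distinct visited locations (N >= 1).
#' @param params A [depr_params()].
#' @return Probability in (0, 1].
#' @examples
#' exploration_probability(1)  # 0.6 with the default constants
#' @export
exploration_probability <- function(n_distinct, params = depr_params()) {
  stopifnot(all(n_distinct >= 1))
  pmin(1, params$rho * n_distinct^(-params$gamma))
}

#' Choose the next location with the d-EPR mechanism
#'
#' With probability `p_new = rho * N^(-gamma)` the agent explores: an
#' unvisited location `j` different from the current one is sampled
#' proportionally to the gravity OD row of the current location, renormalized
#' over the unvisited candidates. Otherwise the agent returns: a previously
#' visited location (other than the current one) is sampled proportionally to
#' its visit count. If the branch selected by the coin flip has no eligible
#' candidate, the other branch is used; if both are empty an error is thrown.
#'
#' @param agent An [agent_state()].
#' @param od An `od_matrix` from [build_od_matrix()] on the same tessellation.
#' @param params A [depr_params()].
#' @param force `NULL` (coin flip), `"explore"` or `"return"` - mainly for
#'   mechanism tests.
#' @return The chosen `location_id`.
#' @export
depr_choose <- function(agent, od, params = depr_params(), force = NULL) {
  ids <- rownames(od)
  visited <- names(agent$counts)
  explore_cand <- setdiff(ids, c(visited, agent$current))
  return_cand <- setdiff(visited, agent$current)
  if (length(explore_cand) == 0L && length(return_cand) == 0L) {
    stop("d-EPR: no eligible candidate location")
  }
  p_new <- exploration_probability(length(visited), params)
  explore <- if (is.null(force)) stats::runif(1) < p_new else force == "explore"
  if (explore && length(explore_cand) == 0L) explore <- FALSE
  if (!explore && length(return_cand) == 0L) explore <- TRUE
  if (explore) {
    w <- od[agent$current, explore_cand]
    if (sum(w) <= 0) stop("d-EPR: gravity row has no mass over unvisited candidates")
    if (length(explore_cand) == 1L) return(explore_cand)
    sample(explore_cand, 1L, prob = w)
  } else {
    if (length(return_cand) == 1L) return(return_cand)
    sample(return_cand, 1L, prob = agent$counts[return_cand])
  }
}

#' SWIM parameters
#'
#' @param alpha Mixing weight between closeness to home and location
#'   popularity (default 0.75).
#' @return A list of class `swim_params`.
#' @export
swim_params <- function(alpha = 0.75) {
  stopifnot(alpha >= 0, alpha <= 1)
  structure(list(alpha = alpha), class = "swim_params")
}

#' Choose the next location with the SWIM mechanism
#'
#' Candidate `j != current` is sampled proportionally to
#' `alpha / (1 + dist(home, j))^2 + (1 - alpha) * r(j)`, where `r` is the
#' location relevance rescaled to `[0, 1]` by its maximum over the
#' tessellation. The rescaling keeps the two terms on a common scale so that
#' `alpha` is a meaningful mixing weight; distances are in kilometres.
#' There is no visited/unvisited distinction and no preferential return.
#'
#' @param agent An [agent_state()].
#' @param tess A [tessellation()].
#' @param params A [swim_params()].
#' @return The chosen `location_id`.
#' @export
swim_choose <- function(agent, tess, params = swim_params()) {
  home <- tess[tess$location_id == agent$home, ]
  if (nrow(home) != 1L) stop("agent home not in tessellation")
  cand <- tess$location_id != agent$current
  if (!any(cand)) stop("SWIM: empty candidate set")
  d <- haversine_km(home$lat, home$lon, tess$lat[cand], tess$lon[cand])
  r_hat <- tess$relevance[cand] / max(tess$relevance)
  w <- params$alpha / (1 + d)^2 + (1 - params$alpha) * r_hat
  ids <- tess$location_id[cand]
  if (length(ids) == 1L) return(ids)
  sample(ids, 1L, prob = w)
}

#' Choose the next location with the LATP mechanism
#'
#' Candidate `j != current` is sampled proportionally to
#' `dist(current, j)^(-1.5)`: a pure preference for short trips, blind to
#' relevance and to visit history.
#'
#' @param agent An [agent_state()].
#' @param tess A [tessellation()].
#' @param exponent Distance-decay exponent (default 1.5).
#' @return The chosen `location_id`.
#' @export
latp_choose <- function(agent, tess, exponent = 1.5) {
  cur <- tess[tess$location_id == agent$current, ]
  if (nrow(cur) != 1L) stop("agent current location not in tessellation")
  cand <- tess$location_id != agent$current
  if (!any(cand)) stop("LATP: empty candidate set")
  d <- haversine_km(cur$lat, cur$lon, tess$lat[cand], tess$lon[cand])
  w <- d^(-exponent)
  ids <- tess$location_id[cand]
  if (length(ids) == 1L) return(ids)
  sample(ids, 1L, prob = w)
}

#' Build a location chooser by name
#'
#' Convenience factory used by the simulation engine and the command line:
#' returns a function of one argument (the [agent_state()]) closing over the
#' tessellation and any precomputed structures.
#'
#' @param name `"depr"`, `"swim"` or `"latp"`.
#' @param tess A [tessellation()].
#' @param od An `od_matrix` (required for `"depr"`; built on the fly when
#'   omitted).
#' @param rho,gamma,alpha Optional parameter overrides.
#' @return A `function(agent) -> location_id`.
#' @export
make_chooser <- function(name = c("depr", "swim", "latp"), tess, od = NULL,
                         rho = 0.6, gamma = 0.21, alpha = 0.75) {
  name <- match.arg(name)
  switch(name,
    depr = {
      if (is.null(od)) od <- build_od_matrix(tess)
      params <- depr_params(rho, gamma)
      function(agent) depr_choose(agent, od, params)
    },
    swim = {
      params <- swim_params(alpha)
      function(agent) swim_choose(agent, tess, params)
    },
    latp = function(agent) latp_choose(agent, tess)
  )
}
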