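# Mobility measure suite: nine empirical distributions summarizing a cohort
# of sampled trajectories, plus RMSE and Kullback-Leibler comparison between
# a reference and a synthetic cohort. A "visit" is one maximal stay (an
# arrival event), not a slot.

#' Extract stays and trips from one agent's trajectory
#'
#' Stays are maximal runs of consecutive slots at one location; a trip links
#' each pair of consecutive stays and is stamped with the arrival slot (the
#' first slot of the destination stay). The number of trips is always the
#' number of stays minus one.
#'
#' @param traj Trajectory data frame for a single agent (columns `slot`,
#'   `location_id`), slot-complete and ordered.
#' @return List with `stays` (`location_id, start_slot, length_slots`) and
#'   `trips` (`origin, destination, arrival_slot`).
#' @export
extract_stays_and_trips <- function(traj) {
  stopifnot(nrow(traj) >= 1L)
  traj <- traj[order(traj$slot), ]
  r <- rle(as.character(traj$location_id))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  stays <- data.frame(location_id = r$values,
                      start_slot = traj$slot[starts],
                      length_slots = r$lengths,
                      stringsAsFactors = FALSE)
  k <- nrow(stays)
  trips <- if (k >= 2L) {
    data.frame(origin = stays$location_id[-k],
               destination = stays$location_id[-1L],
               arrival_slot = stays$start_slot[-1L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(origin = character(0), destination = character(0),
               arrival_slot = integer(0), stringsAsFactors = FALSE)
  }
  list(stays = stays, trips = trips)
}

#' Radius of gyration of one agent
#'
#' Visit-weighted RMS distance of an agent's locations from their centre of
#' mass: `r_g = sqrt(sum_i p_i * d(l_i, l_cm)^2)` with `p_i` the fraction of
#' the agent's visits (stays) at location `i` and `l_cm` the visit-weighted
#' mean point. The centre of mass is taken as the weighted mean of latitude
#' and longitude, adequate at the intra-country scales the simulator targets;
#' distances are great-circle kilometres.
#'
#' @param stays Stay table of one agent (from [extract_stays_and_trips()]).
#' @param tess A [tessellation()] supplying coordinates.
#' @return Radius of gyration in kilometres (0 for a single location).
#' @export
radius_of_gyration <- function(stays, tess) {
  stopifnot(nrow(stays) >= 1L)
  n_i <- table(stays$location_id)
  p <- as.numeric(n_i) / sum(n_i)
  m <- match(names(n_i), tess$location_id)
  if (anyNA(m)) stop("stay location missing from tessellation")
  lat <- tess$lat[m]; lon <- tess$lon[m]
  lat_cm <- sum(p * lat); lon_cm <- sum(p * lon)
  d <- haversine_km(lat, lon, lat_cm, lon_cm)
  sqrt(sum(p * d^2))
}

#' Mobility entropy of one agent
#'
#' Normalized Shannon entropy of the agent's visit frequencies:
#' `S = -sum_i p_i ln p_i / ln k` over the `k >= 2` distinct visited
#' locations; defined as 0 for a single location. Ranges in `[0, 1]`: near 0
#' for a highly regular (predictable) agent, 1 for uniform visitation.
#'
#' @param stays Stay table of one agent.
#' @return Entropy in `[0, 1]`.
#' @export
mobility_entropy <- function(stays) {
  stopifnot(nrow(stays) >= 1L)
  n_i <- table(stays$location_id)
  if (length(n_i) == 1L) return(0)
  p <- as.numeric(n_i) / sum(n_i)
  -sum(p * log(p)) / log(length(n_i))
}

# -- empirical distributions ------------------------------------------------

empdist <- function(edges, prob, measure = "") {
  stopifnot(length(edges) == length(prob) + 1L, all(diff(edges) > 0))
  prob[!is.finite(prob)] <- 0
  s <- sum(prob)
  if (s > 0) prob <- prob / s
  structure(list(edges = edges, prob = prob, measure = measure),
            class = "empdist")
}

#' @export
print.empdist <- function(x, ...) {
  cat("Empirical distribution", if (nzchar(x$measure)) paste0("'", x$measure, "'"),
      "-", length(x$prob), "bins on [", format(x$edges[1L]), ",",
      format(x$edges[length(x$edges)]), "]\n")
  invisible(x)
}

# Anchored logarithmic bins (growth factor `base`): the edge sequence is
# deterministic given the anchor, so two datasets produce nested edges and
# their distributions can be aligned by zero-padding.
log_bin <- function(x, anchor, base = 1.5, measure = "") {
  x <- x[is.finite(x)]
  stopifnot(length(x) > 0)
  kmax <- max(1L, ceiling(log(max(x, anchor) / anchor) / log(base) + 1e-9))
  edges <- c(0, anchor * base^(0:kmax))
  h <- graphics::hist(x, breaks = edges, plot = FALSE, right = FALSE)
  empdist(edges, h$counts / sum(h$counts), measure)
}

int_bin <- function(x, measure = "", min_val = min(x)) {
  x <- round(x)
  edges <- seq(min_val - 0.5, max(x) + 0.5)
  h <- graphics::hist(x, breaks = edges, plot = FALSE)
  empdist(edges, h$counts / sum(h$counts), measure)
}

#' Compute the nine-measure suite for a cohort
#'
#' The distributions are: trip distance (km, log bins), radius of gyration
#' per agent (km, log bins), mobility entropy per agent (20 linear bins on
#' `[0, 1]`), location frequency by rank (mean visit frequency at ranks
#' 1..20 across agents, normalized), visits per tessellation location (log
#' bins), distinct locations per agent (integer bins), trips per hour of day
#' (24 bins), trips per agent-day (integer bins, zero-trip days included)
#' and stay time (hours, log bins). All distributions are normalized to sum
#' to one; visits are stays (arrival events).
#'
#' @param traj Cohort trajectory data frame from [run_ditras()].
#' @param tess The [tessellation()] the cohort moved on.
#' @param slot_seconds Slot duration in seconds (default 3600).
#' @param max_rank Rank truncation for the location-frequency curve
#'   (default 20).
#' @return A `measure_suite`: named list of nine `empdist` objects.
#' @export
population_measures <- function(traj, tess, slot_seconds = 3600,
                                max_rank = 20L) {
  stopifnot(nrow(traj) >= 1L, inherits(tess, "tessellation"))
  slot_hours <- slot_seconds / 3600
  by_agent <- split(traj, traj$agent_id)
  st <- lapply(by_agent, extract_stays_and_trips)

  all_stays <- do.call(rbind, lapply(st, `[[`, "stays"))
  trip_list <- lapply(st, `[[`, "trips")
  all_trips <- do.call(rbind, trip_list)

  # trip distance
  if (nrow(all_trips) > 0L) {
    mo <- match(all_trips$origin, tess$location_id)
    md <- match(all_trips$destination, tess$location_id)
    dr <- haversine_km(tess$lat[mo], tess$lon[mo], tess$lat[md], tess$lon[md])
  } else {
    dr <- numeric(0)
  }
  trip_distance <- if (length(dr) > 0L) {
    log_bin(dr, anchor = 0.1, measure = "trip_distance")
  } else {
    empdist(c(0, 0.1), 0, "trip_distance")  # stationary cohort: no trips
  }

  # per-agent measures
  rg <- vapply(st, function(x) radius_of_gyration(x$stays, tess), 0)
  ent <- vapply(st, function(x) mobility_entropy(x$stays), 0)
  nu <- vapply(st, function(x) length(unique(x$stays$location_id)), 0L)

  ent_edges <- seq(0, 1, length.out = 21L)
  ent_h <- graphics::hist(pmin(ent, 1 - 1e-12), breaks = ent_edges, plot = FALSE)

  # location frequency by rank: mean over agents possessing the rank
  rank_freq <- matrix(NA_real_, nrow = length(st), ncol = max_rank)
  for (i in seq_along(st)) {
    cnt <- sort(table(st[[i]]$stays$location_id), decreasing = TRUE)
    f <- as.numeric(cnt) / sum(cnt)
    k <- min(length(f), max_rank)
    rank_freq[i, seq_len(k)] <- f[seq_len(k)]
  }
  fl <- colMeans(rank_freq, na.rm = TRUE)
  fl[!is.finite(fl)] <- 0

  # visits per tessellation location (zero-visit locations included)
  v <- table(factor(all_stays$location_id, levels = tess$location_id))

  # trips per hour of day, pooled then normalized
  hour_edges <- 0:24
  if (nrow(all_trips) > 0L) {
    hr <- floor((all_trips$arrival_slot - 1L) * slot_hours) %% 24
    t_counts <- tabulate(hr + 1L, nbins = 24L)
  } else {
    t_counts <- rep(0, 24L)
  }

  # trips per agent-day (zero days included)
  n_days <- max(1L, ceiling(max(traj$slot) * slot_hours / 24))
  d_counts <- unlist(lapply(trip_list, function(tr) {
    day <- floor((tr$arrival_slot - 1L) * slot_hours / 24)
    tabulate(day + 1L, nbins = n_days)
  }))
  if (is.null(d_counts)) d_counts <- rep(0, n_days)

  # stay time in hours
  dt <- all_stays$length_slots * slot_hours

  suite <- list(
    trip_distance = trip_distance,
    radius_of_gyration = log_bin(rg + 1e-12, anchor = 0.1,
                                 measure = "radius_of_gyration"),
    entropy = empdist(ent_edges, ent_h$counts / sum(ent_h$counts), "entropy"),
    location_frequency = empdist(seq(0.5, max_rank + 0.5), fl,
                                 "location_frequency"),
    visits_per_location = log_bin(as.numeric(v) + 1e-12, anchor = 1,
                                  measure = "visits_per_location"),
    locations_per_user = int_bin(nu, "locations_per_user", min_val = 1),
    trips_per_hour = empdist(hour_edges, t_counts, "trips_per_hour"),
    trips_per_day = int_bin(d_counts, "trips_per_day", min_val = 0),
    stay_time = log_bin(dt, anchor = slot_hours, measure = "stay_time")
  )
  class(suite) <- "measure_suite"
  suite
}

#' @export
print.measure_suite <- function(x, ...) {
  cat("Mobility measure suite (9 distributions):\n")
  for (nm in names(x)) cat(sprintf("  %-20s %d bins\n", nm, length(x[[nm]]$prob)))
  invisible(x)
}

# Align two distributions on nested anchored edges by zero-padding the
# shorter one. Errors if the edges are not prefixes of each other.
align_dists <- function(y, yhat) {
  e1 <- y$edges; e2 <- yhat$edges
  n <- min(length(e1), length(e2))
  if (!isTRUE(all.equal(e1[seq_len(n)], e2[seq_len(n)], tolerance = 1e-9))) {
    stop("bin mismatch: distributions were built with different bin edges")
  }
  k <- max(length(y$prob), length(yhat$prob))
  pad <- function(p) c(p, rep(0, k - length(p)))
  list(y = pad(y$prob), yhat = pad(yhat$prob))
}

#' Root mean square error between two distributions
#'
#' `sqrt(mean((yhat_i - y_i)^2))` over bins. Accepts two `empdist` objects
#' (aligned on their shared anchored bin edges) or two plain numeric vectors
#' of equal length. Symmetric in its arguments.
#'
#' @param y,yhat Distributions or numeric vectors to compare.
#' @return Non-negative RMSE.
#' @export
rmse <- function(y, yhat) {
  if (inherits(y, "empdist") && inherits(yhat, "empdist")) {
    al <- align_dists(y, yhat)
    y <- al$y; yhat <- al$yhat
  }
  stopifnot(length(y) == length(yhat))
  sqrt(mean((yhat - y)^2))
}

#' Kullback-Leibler divergence between two distributions
#'
#' `KL(y || yhat) = sum_i y_i * ln(y_i / yhat_i)` in nats, with additive
#' smoothing `eps` on both arguments (then renormalized) so empty synthetic
#' bins do not produce infinities. Non-negative; zero iff the distributions
#' coincide.
#'
#' @param y Reference distribution (`empdist` or numeric vector).
#' @param yhat Synthetic distribution.
#' @param eps Additive smoothing constant (default 1e-12).
#' @return KL divergence in nats.
#' @export
kl_divergence <- function(y, yhat, eps = 1e-12) {
  if (inherits(y, "empdist") && inherits(yhat, "empdist")) {
    al <- align_dists(y, yhat)
    y <- al$y; yhat <- al$yhat
  }
  stopifnot(length(y) == length(yhat))
  p <- (y + eps) / sum(y + eps)
  q <- (yhat + eps) / sum(yhat + eps)
  sum(p * log(p / q))
}

#' Compare two measure suites
#'
#' @param ref Reference `measure_suite` (e.g. from real data).
#' @param syn Synthetic `measure_suite`.
#' @return Data frame with one row per measure and columns `measure`,
#'   `rmse`, `kl`.
#' @export
compare_measures <- function(ref, syn) {
  stopifnot(inherits(ref, "measure_suite"), inherits(syn, "measure_suite"))
  out <- data.frame(measure = names(ref),
                    rmse = NA_real_, kl = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ref)) {
    nm <- names(ref)[i]
    out$rmse[i] <- rmse(ref[[nm]], syn[[nm]])
    out$kl[i] <- kl_divergence(ref[[nm]], syn[[nm]])
  }
  out
}

#' Write / read a measure suite as JSON
#'
#' @param suite A `measure_suite`.
#' @param path File path.
#' @export
write_measures <- function(suite, path) {
  stopifnot(inherits(suite, "measure_suite"))
  obj <- lapply(suite, function(d) list(edges = d$edges, prob = d$prob,
                                        measure = d$measure))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_measures
#' @export
read_measures <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  suite <- lapply(obj, function(d) empdist(d$edges, d$prob, d$measure))
  class(suite) <- "measure_suite"
  suite
}
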