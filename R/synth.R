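# Synthetic fixtures: toy tessellations with heavy-tailed relevance and
# CDR-like corpora with a planted circadian routine and known ground truth,
# so the full learning pipeline can be exercised and validated offline.

#' Generate a toy weighted spatial tessellation
#'
#' Scatters `m` locations uniformly over a lat/lon box and assigns
#' heavy-tailed relevances following a Zipf rank-size law
#' `r(rank) = scale * rank^(-exponent)` with ranks randomly permuted over the
#' locations. This emulates the strongly uneven popularity landscape of real
#' tessellations (a few dominant towers or cells, many marginal ones).
#'
#' @param m Number of locations (>= 2).
#' @param bbox Numeric `c(lat_min, lat_max, lon_min, lon_max)`; the default
#'   spans roughly a 200 x 200 km region.
#' @param zipf_exponent Rank-size exponent (default 1).
#' @param scale Relevance of the top-ranked location (default 1000).
#' @return A [tessellation()].
#' @export
generate_toy_tessellation <- function(m, bbox = c(43, 45, 9, 12),
                                      zipf_exponent = 1, scale = 1000) {
  stopifnot(m >= 2L, length(bbox) == 4L, bbox[1L] < bbox[2L], bbox[3L] < bbox[4L])
  lat <- stats::runif(m, bbox[1L], bbox[2L])
  lon <- stats::runif(m, bbox[3L], bbox[4L])
  relevance <- scale * seq_len(m)^(-zipf_exponent)
  relevance <- sample(relevance)  # random rank assignment over space
  tessellation(data.frame(
    location_id = sprintf("loc%04d", seq_len(m)),
    lat = lat, lon = lon, relevance = relevance,
    stringsAsFactors = FALSE
  ))
}

#' Specification of a synthetic CDR corpus
#'
#' The planted routine is week-periodic over hourly slots: at night
#' (22:00-06:59) a user is at home with probability `home_night_prob`,
#' otherwise on a single-slot excursion; on weekday working hours
#' (09:00-17:59, Mon-Fri) she is at her work location with probability
#' `work_day_prob`; in the remaining hours she is at home with probability
#' 0.5, otherwise on an excursion with a heavy-tailed stay length (Zipf
#' exponent 2.5, 1-6 slots, clipped at the night boundary so night slots
#' stay independent). Observed records thin the latent occupancy with a
#' Poisson call process.
#'
#' @param n_users Number of users (default 100).
#' @param n_locations Locations in the companion tessellation (default 50).
#' @param n_days Days of observation (default 28).
#' @param home_night_prob Probability of being at home in a night slot
#'   (default 0.9).
#' @param work_day_prob Probability of being at work in a working-hour slot
#'   (default 0.7).
#' @param call_rate_per_hour Poisson rate of calls per hour (default 1).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_users = 100L, n_locations = 50L, n_days = 28L,
                       home_night_prob = 0.9, work_day_prob = 0.7,
                       call_rate_per_hour = 1) {
  stopifnot(n_users >= 1L, n_locations >= 2L, n_days >= 1L,
            home_night_prob >= 0, home_night_prob <= 1,
            work_day_prob >= 0, work_day_prob <= 1,
            call_rate_per_hour > 0)
  structure(list(n_users = as.integer(n_users),
                 n_locations = as.integer(n_locations),
                 n_days = as.integer(n_days),
                 home_night_prob = home_night_prob,
                 work_day_prob = work_day_prob,
                 call_rate_per_hour = call_rate_per_hour),
            class = "synth_spec")
}

is_night_hour <- function(hd) hd >= 22 | hd <= 6

#' Generate a synthetic CDR corpus with planted ground truth
#'
#' Simulates the latent hourly occupancy of every user under the planted
#' routine of [synth_spec()], then thins it with a Poisson call process:
#' each slot emits `Pois(call_rate_per_hour)` records stamped with the
#' slot's latent location. Time starts at epoch 0 on a week boundary, so
#' slot `i` maps to period slot `(i - 1) mod 168` when fitting a weekly
#' Markov diary model.
#'
#' @param spec A [synth_spec()].
#' @param tess A [tessellation()] with at least `spec$n_locations` rows; see
#'   [generate_toy_tessellation()].
#' @return A list with `records` (data frame
#'   `timestamp, user_id, location_id`), and `truth`: `homes` and `works`
#'   (named character vectors) and `occupancy` (users x slots character
#'   matrix of the latent per-slot locations).
#' @export
generate_synthetic_cdr <- function(spec = synth_spec(), tess) {
  stopifnot(inherits(spec, "synth_spec"), inherits(tess, "tessellation"))
  n_slots <- spec$n_days * 24L
  hd <- (seq_len(n_slots) - 1L) %% 24L            # hour of day
  wd <- ((seq_len(n_slots) - 1L) %/% 24L) %% 7L   # day of week, 0 = Monday
  night <- is_night_hour(hd)
  working <- hd >= 9 & hd <= 17 & wd < 5

  ids <- tess$location_id
  rel <- tess$relevance
  user_ids <- sprintf("u%04d", seq_len(spec$n_users))
  homes <- works <- stats::setNames(character(spec$n_users), user_ids)
  occupancy <- matrix("", nrow = spec$n_users, ncol = n_slots,
                      dimnames = list(user_ids, NULL))
  rec_ts <- rec_user <- rec_loc <- vector("list", spec$n_users)

  for (u in seq_len(spec$n_users)) {
    home <- sample(ids, 1L, prob = rel)
    not_home <- ids != home
    work <- sample(ids[not_home], 1L, prob = rel[not_home])
    homes[u] <- home
    works[u] <- work

    lat <- character(n_slots)
    s <- 1L
    while (s <= n_slots) {
      if (night[s]) {
        lat[s] <- if (stats::runif(1) < spec$home_night_prob) home else
          sample(ids[not_home], 1L, prob = rel[not_home])
        s <- s + 1L
      } else if (working[s]) {
        if (stats::runif(1) < spec$work_day_prob) {
          lat[s] <- work
          s <- s + 1L
        } else {
          lat[s] <- sample(ids[not_home], 1L, prob = rel[not_home])
          s <- s + 1L
        }
      } else {
        if (stats::runif(1) < 0.5) {
          lat[s] <- home
          s <- s + 1L
        } else {
          # heavy-tailed excursion, clipped at the next night boundary
          len <- sample(1:6, 1L, prob = (1:6)^(-2.5))
          until_night <- which(night[s:n_slots])[1L]
          if (!is.na(until_night)) len <- min(len, until_night - 1L)
          len <- max(len, 1L)
          len <- min(len, n_slots - s + 1L)
          other <- sample(ids[not_home], 1L, prob = rel[not_home])
          lat[s:(s + len - 1L)] <- other
          s <- s + len
        }
      }
    }
    occupancy[u, ] <- lat

    n_calls <- stats::rpois(n_slots, spec$call_rate_per_hour)
    slots_with <- rep(seq_len(n_slots), n_calls)
    if (length(slots_with) == 0L) slots_with <- sample.int(n_slots, 1L)
    ts <- sort((slots_with - 1L) * 3600 + stats::runif(length(slots_with), 0, 3600))
    rec_ts[[u]] <- ts
    rec_user[[u]] <- rep(user_ids[u], length(ts))
    rec_loc[[u]] <- lat[floor(ts / 3600) + 1L]
  }

  records <- data.frame(timestamp = unlist(rec_ts),
                        user_id = unlist(rec_user),
                        location_id = unlist(rec_loc),
                        stringsAsFactors = FALSE)
  list(records = records,
       truth = list(homes = homes, works = works, occupancy = occupancy))
}
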