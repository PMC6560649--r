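# Mobility Diary Learner: turn raw per-user location records into per-slot
# abstract trajectories, fit a periodic 2N-state Markov chain over
# (slot-of-period, at-typical-location) states, and sample mobility diaries
# from the fitted chain.

#' Abstract a user's raw records into a per-slot trajectory
#'
#' Assigns one abstract location symbol to every time slot of the observation
#' span. If a slot contains records from a single location, that location is
#' chosen; with several, the most frequent location within the slot wins;
#' ties are broken by the highest overall frequency across the whole record
#' set, then by the lexicographically smaller id (deterministic). Slots with
#' no records inherit the previous slot's symbol (no movement assumed);
#' leading empty slots are backfilled from the first observed location.
#'
#' @param records Data frame with columns `timestamp` (seconds, numeric) and
#'   `location_id`, time-ordered, for a single user.
#' @param slot_seconds Slot duration in seconds (default 3600).
#' @param start_time Epoch second of slot 1's left edge. Defaults to the
#'   first record's timestamp floored to a slot boundary.
#' @param n_slots Number of slots in the span. Defaults to cover the last
#'   record.
#' @return Character vector of abstract location symbols, length `n_slots`.
#' @examples
#' rec <- data.frame(timestamp = c(0, 3600) + 10, location_id = c("A", "B"))
#' abstractify(rec, 3600)
#' @export
abstractify <- function(records, slot_seconds = 3600, start_time = NULL,
                        n_slots = NULL) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  ts <- as.numeric(records$timestamp)
  if (is.unsorted(ts)) stop("records must be time-ordered")
  loc <- as.character(records$location_id)
  if (is.null(start_time)) start_time <- floor(ts[1L] / slot_seconds) * slot_seconds
  slot <- floor((ts - start_time) / slot_seconds) + 1L
  keep <- slot >= 1L
  if (is.null(n_slots)) n_slots <- max(slot[keep])
  keep <- keep & slot <= n_slots
  if (!any(keep)) stop("no records fall inside the requested span")
  slot <- slot[keep]
  loc <- loc[keep]

  overall <- table(loc)
  out <- character(n_slots)
  for (s in unique(slot)) {
    in_slot <- loc[slot == s]
    cnt <- table(in_slot)
    best <- names(cnt)[cnt == max(cnt)]
    if (length(best) > 1L) {
      ov <- overall[best]
      best <- best[ov == max(ov)]
      best <- sort(best)  # lexicographic tie-break, deterministic
    }
    out[s] <- best[1L]
  }
  # gap filling: carry the previous slot forward; backfill the head
  first_obs <- which(out != "")[1L]
  if (first_obs > 1L) out[seq_len(first_obs - 1L)] <- out[first_obs]
  for (s in seq_len(n_slots)) {
    if (out[s] == "") out[s] <- out[s - 1L]
  }
  out
}

#' Estimate the typical (home) location of an abstract trajectory
#'
#' The single-location typical diary: the symbol occupying the most slots;
#' ties go to the lexicographically smaller id.
#'
#' @param abstract Character vector of per-slot abstract locations.
#' @return The home symbol (length-1 character).
#' @export
estimate_typical_diary <- function(abstract) {
  stopifnot(length(abstract) >= 1L)
  cnt <- table(as.character(abstract))
  best <- names(cnt)[cnt == max(cnt)]
  sort(best)[1L]
}

state_index <- function(h, R, n_period) h * 2L + R + 1L  # 1 .. 2 * n_period

#' Fit the periodic Markov diary model
#'
#' Builds the 2N-state chain over states `(h, R)` where `h` is the slot of
#' the period (default one week of hourly slots, N = 168, arithmetic modulo
#' N) and `R` flags whether the individual is at her typical location.
#' Transition probabilities are the empirical frequencies of four event
#' types, tallied at chain decision points:
#' \itemize{
#'   \item `(h,1) -> (h+1,1)`: stay at the typical location one more slot;
#'   \item `(h,1) -> (h+tau,0)`: break the routine for a `tau`-slot stay at
#'     one non-typical location;
#'   \item `(h,0) -> (h+1,1)`: return to the typical location;
#'   \item `(h,0) -> (h+tau,0)`: move to a different non-typical location
#'     for `tau` slots.
#' }
#' Every typical-location slot is a decision point; a non-typical stay's
#' decision point is its last slot. Stays cut off by the end of a trajectory
#' have no observable outgoing transition and are dropped; stays of
#' `n_period` slots or longer are right-censored into `tau = n_period - 1`.
#' Each observed row is normalized to sum to one. A single population-level
#' chain is fitted over all trajectories.
#'
#' @param trajectories List of abstract trajectories (character vectors),
#'   each assumed to start at period slot `h = 0`.
#' @param homes Optional character vector of typical locations, one per
#'   trajectory; estimated with [estimate_typical_diary()] when omitted.
#' @param n_period Slots per period (default 168: one week of hours).
#' @param slot_seconds Slot duration in seconds (default 3600).
#' @return A `markov_diary_model`: list with `n_period`, `slot_seconds`,
#'   `transitions` (data frame `h_from,R_from,h_to,R_to,prob,count`) and
#'   `observed` (logical per state, TRUE if the state has outgoing events).
#' @export
fit_markov <- function(trajectories, homes = NULL, n_period = 168L,
                       slot_seconds = 3600) {
  stopifnot(is.list(trajectories), length(trajectories) >= 1L, n_period >= 2L)
  if (is.null(homes)) {
    homes <- vapply(trajectories, estimate_typical_diary, "")
  }
  stopifnot(length(homes) == length(trajectories))
  n_states <- 2L * n_period
  tau_max <- n_period - 1L
  counts <- numeric(n_states * n_states)

  for (u in seq_along(trajectories)) {
    a <- as.character(trajectories[[u]])
    if (length(a) < 2L) stop("trajectory ", u, " has fewer than 2 slots")
    w <- homes[[u]]
    r <- rle(a)
    k <- length(r$values)
    ends <- cumsum(r$lengths)            # last position of each stay (1-based)
    starts <- ends - r$lengths + 1L
    is_home <- r$values == w

    add_event <- function(x, R_from, h_to, R_to) {
      # x: 1-based position of the decision slot; h = (x - 1) mod n_period
      h_from <- (x - 1L) %% n_period
      i <- state_index(h_from, R_from, n_period)
      j <- state_index(h_to %% n_period, R_to, n_period)
      counts[(i - 1L) * n_states + j] <<- counts[(i - 1L) * n_states + j] + 1
    }

    for (s in seq_len(k)) {
      if (is_home[s]) {
        # interior slots: routine continuation events
        if (r$lengths[s] > 1L) {
          for (x in starts[s]:(ends[s] - 1L)) {
            add_event(x, 1L, x %% n_period, 1L)  # h+1 = x mod n_period
          }
        }
        # boundary: break into a non-typical stay
        if (s < k) {
          len_next <- r$lengths[s + 1L]
          terminated <- (s + 1L < k) || len_next >= n_period
          if (terminated) {
            tau <- min(len_next, tau_max)
            add_event(ends[s], 1L, (ends[s] - 1L + tau) %% n_period, 0L)
          }
        }
      } else {
        # decision point: last slot of the non-typical stay
        if (s < k) {
          if (is_home[s + 1L]) {
            add_event(ends[s], 0L, ends[s] %% n_period, 1L)
          } else {
            len_next <- r$lengths[s + 1L]
            terminated <- (s + 1L < k) || len_next >= n_period
            if (terminated) {
              tau <- min(len_next, tau_max)
              add_event(ends[s], 0L, (ends[s] - 1L + tau) %% n_period, 0L)
            }
          }
        }
      }
    }
  }

  nz <- which(counts > 0)
  i <- (nz - 1L) %/% n_states + 1L
  j <- (nz - 1L) %% n_states + 1L
  trans <- data.frame(
    h_from = (i - 1L) %/% 2L, R_from = (i - 1L) %% 2L,
    h_to = (j - 1L) %/% 2L, R_to = (j - 1L) %% 2L,
    count = counts[nz]
  )
  row_tot <- tapply(trans$count, i, sum)
  trans$prob <- trans$count / as.numeric(row_tot[as.character(i)])
  trans <- trans[order(i, j), c("h_from", "R_from", "h_to", "R_to", "prob", "count")]
  rownames(trans) <- NULL
  observed <- logical(n_states)
  observed[unique(i)] <- TRUE
  new_markov_diary_model(n_period, slot_seconds, trans, observed)
}

#' Construct a Markov diary model from a transition table
#'
#' Builds the model directly from a data frame
#' `h_from, R_from, h_to, R_to, prob` - the same flat layout used by
#' [write_markov_model()]. Useful for hand-specified chains (e.g. planted
#' ground truth in simulation studies). Rows are validated to be stochastic
#' per origin state.
#'
#' @param n_period Slots per period.
#' @param slot_seconds Slot duration in seconds.
#' @param transitions Transition data frame; a `count` column is optional.
#' @return A `markov_diary_model`.
#' @export
markov_diary_model <- function(n_period, slot_seconds, transitions) {
  stopifnot(is.data.frame(transitions),
            all(c("h_from", "R_from", "h_to", "R_to", "prob") %in%
                  names(transitions)))
  if (is.null(transitions$count)) transitions$count <- NA_real_
  observed <- logical(2L * n_period)
  observed[unique(state_index(transitions$h_from, transitions$R_from,
                              n_period))] <- TRUE
  new_markov_diary_model(n_period, slot_seconds, transitions, observed)
}

new_markov_diary_model <- function(n_period, slot_seconds, transitions, observed) {
  n_states <- 2L * n_period
  idx <- state_index(transitions$h_from, transitions$R_from, n_period)
  bad <- tapply(transitions$prob, idx, sum)
  if (any(abs(bad - 1) > 1e-9)) stop("a transition row does not sum to 1")
  if (any(transitions$prob < 0)) stop("negative transition probability")
  by_state <- split(transitions[, c("h_to", "R_to", "prob")], idx)
  structure(list(n_period = as.integer(n_period),
                 slot_seconds = as.numeric(slot_seconds),
                 transitions = transitions,
                 observed = observed,
                 .by_state = by_state),
            class = "markov_diary_model")
}

#' @export
print.markov_diary_model <- function(x, ...) {
  cat("Markov diary model:", 2L * x$n_period, "states",
      sprintf("(period %d slots of %gs)\n", x$n_period, x$slot_seconds))
  cat("  observed states:", sum(x$observed), "/", 2L * x$n_period, "\n")
  cat("  transitions:", nrow(x$transitions), "\n")
  invisible(x)
}

#' Sample a mobility diary from a fitted Markov diary model
#'
#' Walks the chain from the initial state (default: at the typical location
#' at period slot 0). Routine continuations append '1'; a break appends
#' `'|' + '0' * tau`; a return appends `'|' + '1'`. The walk is truncated at
#' `n_slots`. States without fitted outgoing transitions fall back to the
#' deterministic return `(h, .) -> (h+1, 1)` and a single warning reports how
#' often the fallback fired.
#'
#' @param model A `markov_diary_model`.
#' @param n_slots Number of slots to emit (>= 1).
#' @param start_slot Period slot of the first emitted slot (default 0).
#' @return A `mobility_diary`.
#' @export
md_generate <- function(model, n_slots, start_slot = 0L) {
  stopifnot(inherits(model, "markov_diary_model"), n_slots >= 1L)
  n_period <- model$n_period
  h <- as.integer(start_slot) %% n_period
  R <- 1L
  out <- character(2L * n_slots + 2L)
  out[1L] <- "1"
  k <- 1L
  emitted <- 1L
  fallback_hits <- 0L
  while (emitted < n_slots) {
    idx <- state_index(h, R, n_period)
    rows <- model$.by_state[[as.character(idx)]]
    if (is.null(rows)) {
      fallback_hits <- fallback_hits + 1L
      h_to <- (h + 1L) %% n_period
      R_to <- 1L
    } else if (nrow(rows) == 1L) {
      h_to <- rows$h_to[1L]; R_to <- rows$R_to[1L]
    } else {
      pick <- sample.int(nrow(rows), 1L, prob = rows$prob)
      h_to <- rows$h_to[pick]; R_to <- rows$R_to[pick]
    }
    if (R_to == 1L) {
      if (R == 0L) { k <- k + 1L; out[k] <- "|" }
      k <- k + 1L; out[k] <- "1"
      emitted <- emitted + 1L
    } else {
      tau <- (h_to - h) %% n_period
      if (tau == 0L) tau <- n_period
      tau <- min(tau, n_slots - emitted)
      k <- k + 1L; out[k] <- "|"
      k <- k + 1L; out[k] <- strrep("0", tau)
      emitted <- emitted + tau
    }
    h <- h_to
    R <- R_to
  }
  if (fallback_hits > 0L) {
    warning("md_generate: ", fallback_hits,
            " transition(s) from unobserved states used the return-home fallback")
  }
  parse_diary(paste(out[seq_len(k)], collapse = ""))
}

#' Read / write a Markov diary model as CSV
#'
#' Flat table `h_from,R_from,h_to,R_to,prob,count` preceded by two header
#' comment lines carrying `n_period` and `slot_seconds`. The loader
#' re-validates row stochasticity.
#'
#' @param path File path.
#' @return `read_markov_model()` returns a `markov_diary_model`.
#' @export
read_markov_model <- function(path) {
  lines <- readLines(path, n = 2L)
  hdr <- lines[startsWith(lines, "#")]
  get_num <- function(key) {
    m <- hdr[grepl(key, hdr)]
    if (length(m) != 1L) stop("model file missing header '", key, "'")
    as.numeric(sub(paste0(".*", key, "\\s*=\\s*"), "", m))
  }
  n_period <- as.integer(get_num("n_period"))
  slot_seconds <- get_num("slot_seconds")
  trans <- utils::read.csv(path, comment.char = "#")
  observed <- logical(2L * n_period)
  observed[unique(state_index(trans$h_from, trans$R_from, n_period))] <- TRUE
  if (is.null(trans$count)) trans$count <- NA_real_
  new_markov_diary_model(n_period, slot_seconds, trans, observed)
}

#' @rdname read_markov_model
#' @param model A `markov_diary_model` to write.
#' @export
write_markov_model <- function(model, path) {
  stopifnot(inherits(model, "markov_diary_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_period = %d", model$n_period),
               sprintf("# slot_seconds = %g", model$slot_seconds)), con)
  utils::write.csv(model$transitions, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
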