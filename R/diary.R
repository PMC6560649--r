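# Mobility diaries: the symbolic temporal skeleton of a trajectory. A diary
# is a string over {1, 0, |}: '1' marks a slot spent at the agent's typical
# (home) location, '0' a slot at a non-typical location, and '|' a move
# between two different locations. Runs of identical symbols between
# separators are stays; two adjacent '1'-runs are impossible (staying home is
# not a move), while adjacent '0'-runs denote different non-typical places.

#' Parse and validate a mobility diary string
#'
#' Accepts strings of '|'-separated tokens where each token is a run of '1's
#' or a run of '0's, no token is empty, and no two consecutive tokens are both
#' '1'-runs. This is exactly the language emitted by the diary generators: a
#' separator appears precisely where the abstract location changes between
#' consecutive slots.
#'
#' @param text A single diary string, e.g. `"11|00|0|1"`.
#' @return A `mobility_diary`: list with `text`, `n_slots`, per-slot
#'   `routine` flags, and a `segments` data frame
#'   (`start_slot`, `length`, `routine`).
#' @examples
#' d <- parse_diary("11|00|0|1")
#' d$n_slots      # 6
#' d$segments     # 4 stays
#' @export
parse_diary <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || nchar(text) == 0L) {
    stop("diary must be a single non-empty string")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("0", "1", "|"))
  if (length(bad) > 0L) {
    stop("invalid diary character '", chars[bad[1L]], "' at position ", bad[1L])
  }
  if (chars[1L] == "|") stop("diary cannot start with a separator (position 1)")
  if (chars[length(chars)] == "|") {
    stop("diary cannot end with a separator (position ", length(chars), ")")
  }
  # token boundaries
  seg_start <- integer(0)
  seg_sym <- character(0)
  prev <- ""
  slot <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "|") {
      if (prev == "|") stop("adjacent separators at position ", i)
      prev <- ch
      next
    }
    slot <- slot + 1L
    if (prev == "" || prev == "|") {
      seg_start <- c(seg_start, slot)
      seg_sym <- c(seg_sym, ch)
    } else if (ch != prev) {
      stop("symbol change without separator at position ", i,
           " ('", prev, "' followed by '", ch, "')")
    }
    prev <- ch
  }
  if (length(seg_sym) > 1L) {
    both_one <- seg_sym[-length(seg_sym)] == "1" & seg_sym[-1L] == "1"
    if (any(both_one)) {
      stop("two consecutive routine stays (separator between two '1' runs) at segment ",
           which(both_one)[1L] + 1L)
    }
  }
  seg_len <- diff(c(seg_start, slot + 1L))
  segments <- data.frame(start_slot = seg_start, length = seg_len,
                         routine = seg_sym == "1")
  routine <- rep(segments$routine, segments$length)
  structure(list(text = text, n_slots = slot, routine = routine,
                 segments = segments),
            class = "mobility_diary")
}

#' @export
print.mobility_diary <- function(x, ...) {
  cat("Mobility diary:", x$n_slots, "slots,", nrow(x$segments), "stays,",
      sprintf("%.0f%% routine\n", 100 * mean(x$routine)))
  txt <- x$text
  if (nchar(txt) > 70) txt <- paste0(substr(txt, 1, 67), "...")
  cat(" ", txt, "\n")
  invisible(x)
}

#' @export
format.mobility_diary <- function(x, ...) x$text

#' Build a diary from an abstract trajectory and a typical diary
#'
#' Slot `i` is '1' iff the abstract location equals the typical (home)
#' location at `i`; a separator is inserted exactly where the abstract
#' location changes between consecutive slots.
#'
#' @param abstract Character vector of per-slot abstract location symbols.
#' @param home The typical-diary symbol (single home location for all slots).
#' @return A `mobility_diary`.
#' @examples
#' diary_from_abstract(c("A", "A", "A", "A", "B", "B"), "A")$text  # "1111|00"
#' @export
diary_from_abstract <- function(abstract, home) {
  stopifnot(length(abstract) >= 1L, length(home) == 1L)
  abstract <- as.character(abstract)
  sym <- ifelse(abstract == as.character(home), "1", "0")
  out <- character(2L * length(abstract))
  k <- 0L
  for (i in seq_along(abstract)) {
    if (i > 1L && abstract[i] != abstract[i - 1L]) {
      k <- k + 1L
      out[k] <- "|"
    }
    k <- k + 1L
    out[k] <- sym[i]
  }
  parse_diary(paste(out[seq_len(k)], collapse = ""))
}

#' Expand a diary back into an abstract trajectory
#'
#' The inverse of [diary_from_abstract()] up to relabelling of the
#' non-typical locations: '1' slots map to `home` and every '0'-run receives
#' a fresh synthetic symbol (distinct from its neighbours and from `home`).
#' Useful for refitting a Markov diary model to generated diaries.
#'
#' @param diary A `mobility_diary` or diary string.
#' @param home Symbol to use for routine slots.
#' @return Character vector of length `n_slots`.
#' @export
diary_to_abstract <- function(diary, home = "HOME") {
  diary <- as_diary(diary)
  seg <- diary$segments
  n_nonroutine <- 0L
  syms <- character(nrow(seg))
  for (j in seq_len(nrow(seg))) {
    if (seg$routine[j]) {
      syms[j] <- home
    } else {
      n_nonroutine <- n_nonroutine + 1L
      syms[j] <- sprintf("nr%06d", n_nonroutine)
    }
  }
  rep(syms, seg$length)
}

as_diary <- function(x) {
  if (inherits(x, "mobility_diary")) x else parse_diary(x)
}

#' Random Diary baseline generator
#'
#' A perpetually moving agent: in every slot it moves to a new non-typical
#' location, so the diary is `"0|0|...|0"`. Models no routine at all.
#'
#' @param n_slots Diary length in slots (>= 1).
#' @return A `mobility_diary`.
#' @export
rd_generate <- function(n_slots) {
  stopifnot(n_slots >= 1L)
  parse_diary(paste(rep("0", n_slots), collapse = "|"))
}

#' Parameters of the waiting-time diary generator
#'
#' @param beta Power-law exponent of the waiting-time distribution
#'   (default 0.8).
#' @param tau_hours Exponential cutoff in hours (default 17).
#' @return A list of class `wt_params`.
#' @export
wt_params <- function(beta = 0.8, tau_hours = 17) {
  stopifnot(beta > 0, tau_hours > 0)
  structure(list(beta = beta, tau_hours = tau_hours), class = "wt_params")
}

#' Sample waiting times from the truncated power law
#'
#' Draws stay durations (hours) from the density
#' `P(dt) ~ dt^(-1 - beta) * exp(-dt / tau)` by inverse-CDF interpolation on
#' a dense logarithmic grid. The support is `[slot_hours, 30 * tau]`: the
#' lower bound makes every stay representable as at least one slot, the upper
#' bound truncates the (already exponentially suppressed) tail.
#'
#' @param n Number of draws.
#' @param params A [wt_params()].
#' @param slot_hours Slot duration in hours (lower support bound).
#' @return Numeric vector of durations in hours.
#' @export
sample_waiting_times <- function(n, params = wt_params(), slot_hours = 1) {
  stopifnot(n >= 1L, slot_hours > 0)
  beta <- params$beta
  tau <- params$tau_hours
  lo <- slot_hours
  hi <- 30 * tau
  grid <- exp(seq(log(lo), log(hi), length.out = 4096L))
  dens <- grid^(-1 - beta) * exp(-grid / tau)
  # trapezoidal cumulative integral, normalized to a CDF on [lo, hi]
  dg <- diff(grid)
  cdf <- c(0, cumsum(dg * (dens[-1L] + dens[-length(dens)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, grid, xout = stats::runif(n), ties = "ordered")$y
}

#' Waiting-time baseline diary generator
#'
#' A sequence of non-routine stays whose durations are i.i.d. draws from the
#' truncated power law of [sample_waiting_times()], discretized to whole
#' slots (minimum one). Consecutive stays are separated by '|'; the final
#' stay is truncated so the diary has exactly `n_slots` slots. Like the
#' random-diary baseline, it has no routine ('1') slots.
#'
#' @param n_slots Diary length in slots (>= 1).
#' @param params A [wt_params()].
#' @param slot_seconds Slot duration in seconds (default 3600).
#' @return A `mobility_diary`.
#' @export
wt_generate <- function(n_slots, params = wt_params(), slot_seconds = 3600) {
  stopifnot(n_slots >= 1L)
  slot_hours <- slot_seconds / 3600
  lens <- integer(0)
  total <- 0L
  while (total < n_slots) {
    dt <- sample_waiting_times(32L, params, slot_hours)
    k <- pmax(1L, as.integer(floor(dt / slot_hours)))
    lens <- c(lens, k)
    total <- total + sum(k)
  }
  keep <- which(cumsum(lens) >= n_slots)[1L]
  lens <- lens[seq_len(keep)]
  lens[keep] <- lens[keep] - (sum(lens) - n_slots)  # truncate, keep exact length
  parse_diary(paste(vapply(lens, function(k) strrep("0", k), ""), collapse = "|"))
}

#' Read / write diary files
#'
#' One diary string per line, UTF-8; lines starting with `#` are comments.
#'
#' @param path File path.
#' @return `read_diaries()` returns a list of `mobility_diary` objects.
#' @export
read_diaries <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_diary)
}

#' @rdname read_diaries
#' @param diaries List of `mobility_diary` objects (or diary strings).
#' @param header Optional comment line written at the top of the file.
#' @export
write_diaries <- function(diaries, path, header = NULL) {
  texts <- vapply(diaries, function(d) as_diary(d)$text, "")
  lines <- c(if (!is.null(header)) paste0("# ", header), texts)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
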