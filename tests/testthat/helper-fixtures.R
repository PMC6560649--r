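# Shared fixtures, built in code. Degrees of longitude on the equator map to
# kilometres as km_per_deg = pi * 6371 / 180, so placing locations on the
# equator gives tessellations with exactly chosen pairwise distances.

km_per_deg <- pi * 6371 / 180

# Tessellation of locations on the equator at given east-west positions (km).
line_tess <- function(positions_km, relevances,
                      ids = sprintf("L%d", seq_along(positions_km))) {
  tessellation(data.frame(
    location_id = ids, lat = 0, lon = positions_km / km_per_deg,
    relevance = relevances, stringsAsFactors = FALSE
  ))
}

# A weekly circadian chain that is sparse in its stochastic rows: agents are
# home except a possible 9-slot workday excursion after 08:00 (p = 0.4) and a
# possible evening move from the away state at 17:00 (p = 0.15); every other
# observed row is deterministic. Used for parameter-recovery experiments.
sparse_circadian_chain <- function(n_period = 168L) {
  rows <- list()
  for (d in 0:6) {
    b <- 24L * d
    rows[[length(rows) + 1L]] <- data.frame(
      h_from = c(b + 8L, b + 8L, b + 17L, b + 17L, b + 21L),
      R_from = c(1L, 1L, 0L, 0L, 0L),
      h_to   = c(b + 9L, b + 17L, b + 18L, b + 21L, (b + 22L) %% n_period),
      R_to   = c(1L, 0L, 1L, 0L, 1L),
      prob   = c(0.6, 0.4, 0.85, 0.15, 1))
  }
  det <- setdiff(0:(n_period - 1L), 24L * (0:6) + 8L)
  rows[[length(rows) + 1L]] <- data.frame(
    h_from = det, R_from = 1L, h_to = (det + 1L) %% n_period, R_to = 1L,
    prob = 1)
  markov_diary_model(n_period, 3600, do.call(rbind, rows))
}

# Expensive fixtures computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# Default synthetic study corpus: 50-location heavy-tailed tessellation and a
# 100-user, 28-day CDR corpus with planted ground truth.
synth_study <- function() {
  cached_fixture("synth_study", {
    set.seed(20260401)
    tess <- generate_toy_tessellation(50)
    synth <- generate_synthetic_cdr(synth_spec(), tess)
    list(tess = tess, synth = synth)
  })
}

# Abstract trajectories for every user of the synthetic corpus.
synth_abstracts <- function() {
  cached_fixture("synth_abstracts", {
    st <- synth_study()
    users <- rownames(st$synth$truth$occupancy)
    n_slots <- ncol(st$synth$truth$occupancy)
    lapply(stats::setNames(users, users), function(u) {
      abstractify(st$synth$records[st$synth$records$user_id == u, ],
                  3600, start_time = 0, n_slots = n_slots)
    })
  })
}

# Weekly Markov diary model fitted to the synthetic corpus.
synth_model <- function() {
  cached_fixture("synth_model", fit_markov(synth_abstracts()))
}

transition_key <- function(d) paste(d$h_from, d$R_from, d$h_to, d$R_to)
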