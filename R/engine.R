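# Simulation engine: compose a diary generator and a location chooser over a
# tessellation into sampled mobility trajectories for a cohort of agents.
# Travel time is treated as negligible: every slot belongs wholly to one
# location.

#' Assign a physical home location to a typical diary
#'
#' Draws the home relevance-proportionally from the tessellation (see
#' [sample_by_relevance()]): relevant locations are more likely to host
#' agents, which reproduces a realistic distribution of agents across the
#' territory.
#'
#' @param tess A [tessellation()].
#' @return The home `location_id`.
#' @export
assign_home <- function(tess) sample_by_relevance(tess)

#' Translate one mobility diary into a sampled trajectory
#'
#' Routine ('1') slots emit the agent's home location. Each maximal run of
#' '0' slots triggers exactly one chooser call whose result must differ from
#' the home (the slot's typical location) and, by the chooser's contract,
#' from the immediately preceding location; the chosen location is repeated
#' for the whole run. The home-avoidance constraint is enforced by rejection
#' redraw, at most `max_redraws` attempts.
#'
#' @param diary A `mobility_diary` or diary string.
#' @param home The agent's home `location_id`.
#' @param tess A [tessellation()].
#' @param chooser A `function(agent) -> location_id`, e.g. from
#'   [make_chooser()].
#' @param agent_id Identifier stamped on the output rows.
#' @param max_redraws Rejection budget per non-routine stay (default 100).
#' @return Data frame `agent_id, slot, location_id, lat, lon` with one row
#'   per slot, slots numbered 1..n consecutively.
#' @export
diary_to_trajectory <- function(diary, home, tess, chooser, agent_id = 1L,
                                max_redraws = 100L) {
  diary <- as_diary(diary)
  stopifnot(inherits(tess, "tessellation"), home %in% tess$location_id)
  seg <- diary$segments
  agent <- agent_state(home)
  loc <- character(diary$n_slots)
  for (j in seq_len(nrow(seg))) {
    if (seg$routine[j]) {
      chosen <- home
    } else {
      chosen <- chooser(agent)
      tries <- 1L
      while (chosen == home && tries < max_redraws) {
        chosen <- chooser(agent)
        tries <- tries + 1L
      }
      if (chosen == home) {
        stop("chooser failed to propose a non-home location after ",
             max_redraws, " attempts")
      }
    }
    idx <- seg$start_slot[j]:(seg$start_slot[j] + seg$length[j] - 1L)
    loc[idx] <- chosen
    agent$counts[chosen] <- sum(agent$counts[chosen], seg$length[j], na.rm = TRUE)
    agent$current <- chosen
  }
  m <- match(loc, tess$location_id)
  data.frame(agent_id = agent_id, slot = seq_len(diary$n_slots),
             location_id = loc, lat = tess$lat[m], lon = tess$lon[m],
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param n_agents Number of agents (>= 1).
#' @param n_slots Number of slots per agent (>= 1).
#' @param slot_seconds Slot duration in seconds (default 3600).
#' @param diary Diary generator: `"md"`, `"rd"`, `"wt"`, or a
#'   `function(n_slots) -> mobility_diary`.
#' @param traj Location chooser: `"depr"`, `"swim"`, `"latp"`, or a
#'   `function(agent) -> location_id`.
#' @param model A `markov_diary_model`, required when `diary = "md"`.
#' @param seed Integer seed; each agent runs on a substream derived from
#'   `(seed, agent_id)` so cohorts are reproducible and order-independent.
#' @param rho,gamma,alpha,beta,tau_hours Generator parameter overrides.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_agents, n_slots, slot_seconds = 3600,
                              diary = "md", traj = "depr", model = NULL,
                              seed = 1L, rho = 0.6, gamma = 0.21,
                              alpha = 0.75, beta = 0.8, tau_hours = 17) {
  stopifnot(n_agents >= 1L, n_slots >= 1L, slot_seconds > 0)
  if (is.character(diary)) {
    diary <- match.arg(diary, c("md", "rd", "wt"))
    if (diary == "md" && !inherits(model, "markov_diary_model")) {
      stop("diary = \"md\" requires a fitted markov_diary_model")
    }
  }
  structure(list(n_agents = as.integer(n_agents), n_slots = as.integer(n_slots),
                 slot_seconds = slot_seconds, diary = diary, traj = traj,
                 model = model, seed = as.integer(seed), rho = rho,
                 gamma = gamma, alpha = alpha, beta = beta,
                 tau_hours = tau_hours),
            class = "simulation_config")
}

agent_seed <- function(seed, agent_id) {
  (as.numeric(seed) * 48271 + as.numeric(agent_id)) %% 2147483647
}

#' Run a cohort simulation
#'
#' For every agent: draw a home relevance-proportionally, generate a diary of
#' `n_slots`, and translate it with the configured chooser (see
#' [diary_to_trajectory()]). Each agent's randomness comes from a substream
#' seeded by `(seed, agent_id)`, so re-running the same configuration yields
#' identical trajectories regardless of agent order. An agent whose
#' translation fails is dropped with a warning and the run continues.
#'
#' @param cfg A [simulation_config()].
#' @param tess A [tessellation()].
#' @return Data frame `agent_id, slot, location_id, lat, lon` for all
#'   completed agents.
#' @export
run_ditras <- function(cfg, tess) {
  stopifnot(inherits(cfg, "simulation_config"), inherits(tess, "tessellation"))
  od <- if (identical(cfg$traj, "depr")) build_od_matrix(tess) else NULL
  make_diary <- if (is.function(cfg$diary)) {
    cfg$diary
  } else {
    switch(cfg$diary,
      md = function(n) suppressWarnings(md_generate(cfg$model, n)),
      rd = function(n) rd_generate(n),
      wt = function(n) wt_generate(n, wt_params(cfg$beta, cfg$tau_hours),
                                   cfg$slot_seconds))
  }
  chooser <- if (is.function(cfg$traj)) {
    cfg$traj
  } else {
    make_chooser(cfg$traj, tess, od = od, rho = cfg$rho, gamma = cfg$gamma,
                 alpha = cfg$alpha)
  }
  out <- vector("list", cfg$n_agents)
  for (a in seq_len(cfg$n_agents)) {
    set.seed(agent_seed(cfg$seed, a))
    res <- tryCatch({
      home <- assign_home(tess)
      diary <- make_diary(cfg$n_slots)
      diary_to_trajectory(diary, home, tess, chooser, agent_id = a)
    }, error = function(e) {
      warning("agent ", a, " aborted: ", conditionMessage(e))
      NULL
    })
    out[[a]] <- res
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) stop("all agents failed")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write trajectory files
#'
#' CSV with header `agent_id,slot,location_id,lat,lon`.
#'
#' @param path File path.
#' @return `read_trajectories()` returns the trajectory data frame.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$location_id <- as.character(df$location_id)
  df
}

#' @rdname read_trajectories
#' @param traj Trajectory data frame as produced by [run_ditras()].
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
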