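---
title: "Modelling spatio-temporal mobility routines with ditras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatio-temporal mobility routines with ditras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ditras)
```

## The modelling problem

Generative models of individual human mobility have to reconcile two facts
that pull in opposite directions. Movement is strongly *routinized*: most
people are at home at night, most weekday mornings look alike, and a handful
of locations absorb the bulk of everyone's time. Yet movement is also
*heterogeneous*: trip distances and stay durations are heavy-tailed, and
people occasionally abandon their schedule for excursions of unpredictable
length. Models built around one of these facts tend to fail on the other.

`ditras` addresses this by splitting the generative process into two
independently pluggable stages:

1. **When** — a *diary generator* emits a symbolic mobility diary: a string
   over `{1, 0, |}` where `1` means "at the typical (home) location for this
   time slot", `0` means "somewhere else", and `|` marks a move between two
   different locations. The diary fixes the temporal skeleton — when the
   agent is home, when it is away, and how long each away stay lasts —
   without committing to any geography.
2. **Where** — a *trajectory generator* (location chooser) maps that
   skeleton onto a weighted spatial tessellation: routine slots go to the
   agent's home; each away stay triggers exactly one location choice, held
   for the whole stay.

Any diary generator can be combined with any chooser, which is how the
package builds its 3 x 3 grid of models (`md`/`rd`/`wt` diaries times
`depr`/`swim`/`latp` choosers) for comparison studies.

## The diary grammar

A diary is a `|`-separated sequence of stays, each a run of identical
symbols; two consecutive `1`-runs cannot occur (staying at the typical
location is not a move), while consecutive `0`-runs denote *different*
non-typical locations. `parse_diary()` validates a string and decomposes it
into per-slot routine flags and stay segments:

```{r}
parse_diary("11|00|0|1")
```

Travel time is assumed negligible relative to the slot duration (an hour by
default): every slot belongs wholly to one location. This is the standard
reading for hourly slots; it degrades for much finer slots, where explicit
travel-time modelling would be needed.

## The Markov diary model and its learner

The data-driven diary generator is a periodic Markov chain over states
`(h, R)`, where `h` is the slot of a period and `R` flags whether the agent
is at its typical location. We fit one population-level chain with
`N_period = 168` hourly slots — one week — because weekly regularity is the
natural period of human schedules; the period is configurable. With
`N = 168` the chain has 336 states and four admissible transition families:
continue the routine `(h,1) -> (h+1,1)`; break it for a `tau`-slot stay at
one non-typical location `(h,1) -> (h+tau,0)`; return home
`(h,0) -> (h+1,1)`; or move to a *different* non-typical location
`(h,0) -> (h+tau,0)`. Slot arithmetic is modulo the period.

The learner (`abstractify()` + `fit_markov()`) proceeds from raw records:

* **Abstraction.** Each user's records are collapsed to one symbol per slot:
  the single observed location, else the most frequent location within the
  slot, ties broken by the highest overall frequency and then by the
  lexicographically smaller id so the procedure is deterministic. Empty
  slots inherit the previous slot's symbol (no movement assumed); an empty
  head is backfilled from the first observation — the learner has no other
  defensible information about those slots.
* **Typical diary.** The simplest routine template is used: a single home
  location occupying every slot, estimated as the modal symbol of the
  abstract trajectory. Clustering of weekly regularity profiles in large
  mobility datasets shows a dominant single-location cluster, which is what
  makes this simplification serviceable; multi-location typical diaries are
  out of scope here.
* **Counting.** Transition probabilities are empirical frequencies tallied
  at *chain decision points*: every slot spent at the typical location, and
  the last slot of each non-typical stay. Counting every non-typical slot
  instead would put mass on positions where the chain never makes a
  decision and the rows would no longer be stochastic. A stay cut off by
  the end of a trajectory has an unobservable outgoing transition and is
  dropped; a stay of a full period or longer is right-censored into
  `tau_max = N_period - 1`. No smoothing is applied — the model is
  deliberately non-parametric — so states never seen in the data have no
  row. During generation (`md_generate()`) such rows fall back to a
  deterministic return home, and a warning reports how often that fired.
* **Initial state.** Walks start at `(h = 0, R = 1)`: the agent is at home
  at the period start (midnight Monday under the weekly convention). The
  start slot is configurable.

Because the fitted chain is just a transition table, `markov_diary_model()`
also accepts hand-written tables, which is how the test-suite plants known
chains for recovery experiments.

## Baseline diary generators

* `rd_generate()` — perpetual motion: a new location every slot
  (`"0|0|...|0"`). A deliberately unrealistic lower bound on temporal
  structure.
* `wt_generate()` — stay durations drawn i.i.d. from the truncated power
  law `P(dt) ~ dt^(-1-beta) * exp(-dt/tau)` with `beta = 0.8`,
  `tau = 17` hours, the standard waiting-time law measured on mobile-phone
  data. The literature gives only this functional form, so two numerical
  choices are ours: the support is `[one slot, 30 * tau]` (the lower bound
  makes every stay representable; at the upper bound the exponential factor
  is below 1e-13, so the truncation is immaterial), and sampling is by
  inverse-CDF interpolation on a 4096-point logarithmic grid, accurate to
  well below the slot discretization. Durations are floored to whole slots
  with a minimum of one, and the final stay is truncated so the diary has
  exactly the requested length (no re-draw, which would bias the tail).

Neither baseline has routine (`1`) slots: both model agents with no home
concept, which is exactly the deficiency they exist to demonstrate —
several home-dependent comparison measures are undefined for them.

## Location choosers

All three choosers operate on a *weighted spatial tessellation*: discrete
locations with centroid coordinates and a positive `relevance` weight (call
volume, stop counts, or population density). Distances are great-circle
kilometres (haversine, R = 6371 km). Relevance is accepted as any positive
real — integer call counts and fractional population densities are both
admissible — and coincident centroids are rejected at load time rather than
nudged, since a zero distance would give the gravity kernel unbounded
weight.

* **d-EPR** (`depr_choose()`): with probability
  `p_new = rho * N^(-gamma)` (`rho = 0.6`, `gamma = 0.21`, as estimated in
  the exploration/preferential-return literature; `N` = distinct locations
  visited) the agent *explores*, otherwise it *returns* to a previously
  visited location with probability proportional to its visit count.
  Exploration is *preferential*: candidates are the unvisited locations,
  sampled from the gravity row of the current location
  `p_ij ~ r_i r_j / d_ij^2`, renormalized over those candidates. The whole
  OD matrix is normalized jointly (`sum_ij p_ij = 1`) and row-conditioning
  happens at choice time. If the coin lands on a branch with no eligible
  candidate (nothing unvisited, or nothing visited besides the current
  location), the other branch is used. Visit counts are accumulated in
  slots, so a long stay weighs more than a brief one in later returns, and
  the home — visited by construction — accumulates routine slots, which is
  what makes returns gravitate home realistically.
* **SWIM** (`swim_choose()`): candidates are weighted by
  `alpha * 1/(1 + d(home, j))^2 + (1 - alpha) * r_hat(j)` with
  `alpha = 0.75`. The distance term is bounded in (0, 1] but relevance has
  arbitrary scale, so we rescale it to [0, 1] by its maximum over the
  tessellation; without this the mixing weight `alpha` would be
  meaningless. No preferential return.
* **LATP** (`latp_choose()`): candidates weighted by
  `d(current, j)^(-1.5)` — pure short-trip preference, blind to relevance
  and history.

All three exclude the current location, so consecutive stays always differ.
The engine additionally requires a non-routine stay to avoid the slot's
typical location (the home); since SWIM and LATP can propose it, this is
enforced by rejection redraw with a budget of 100 attempts.

## The engine

`run_ditras()` draws each agent's home relevance-proportionally, generates
its diary, and translates it (`diary_to_trajectory()`). Each agent consumes
an RNG substream seeded from `(seed, agent_id)`, making cohorts bit
reproducible and independent of agent execution order. Agents are fully
independent: no social coupling, no shared capacity constraints, and SWIM's
original encounter-based popularity is replaced by the static relevance
weights, keeping all three choosers on the same informational footing.

## The measure suite

`population_measures()` computes nine distributions: trip distance, radius
of gyration, mobility entropy, location frequency by rank, visits per
location, distinct locations per user, trips per hour of day, trips per
day, and stay time. Conventions worth stating:

* A *visit* is one maximal stay (an arrival event), not a slot; `V`,
  `f(L)`, and the visitation frequencies in the radius of gyration and
  entropy all count stays.
* The radius of gyration is
  `r_g = sqrt(sum_i p_i d(l_i, l_cm)^2)` with `p_i = n_i / sum_k n_k`
  (visits at `i` over total visits) and `l_cm` the visit-weighted mean
  point, computed as the weighted mean of latitude and longitude — adequate
  at intra-country scales, increasingly biased for continental spreads.
* Mobility entropy is the normalized Shannon form
  `-sum p_i ln p_i / ln |L_u|`, in [0, 1], defined as 0 for single-location
  agents. Natural logarithms throughout, including the KL divergence.
* Binning is an artifact convention (source datasets never dictate one):
  logarithmic bins with growth factor 1.5 anchored at fixed origins for
  distances, radii, visits and stay times; unit integer bins for counts;
  24 fixed bins for trips per hour (pooled over agents, then normalized);
  20 linear bins on [0, 1] for entropy; rank truncation at 20 for the
  location-frequency curve (mean frequency over the agents possessing each
  rank, then normalized). Anchored bins mean two cohorts produce *nested*
  edge sequences, so `rmse()` and `kl_divergence()` align them by
  zero-padding; comparing distributions built with foreign bins is an
  error, not a silent reinterpretation.
* KL smoothing is additive with `eps = 1e-12`, just enough to keep empty
  synthetic bins finite without visibly distorting the divergence.
* Degenerate cohorts are represented honestly: a stationary cohort has a
  zero-mass trip-distance and trips-per-hour distribution rather than a
  fabricated uniform one.

## Preprocessing raw records

`filter_cdr_users()` applies, in order: drop a user's locations holding at
most 0.5% of their records; drop users left with one location; drop users
whose record rate over the dataset's observation span is below 0.5 per
hour. The span is the interval between the first and last record of the
whole dataset, matching the hours-times-days denominator of the rate
threshold. `segment_gps_trips()` splits a vehicle's ping stream at
silences longer than 20 minutes (configurable; reported analyses are
insensitive between 5 and 40 minutes) and maps each trip's endpoints to a
cell. Polygon cell layers are rarely available offline, so the default
lookup assigns the nearest tessellation centroid; any
`function(lat, lon) -> id` can be injected instead.

## The synthetic study corpus

Real CDR and GPS corpora are proprietary, so the package ships a generator
(`generate_toy_tessellation()`, `generate_synthetic_cdr()`) whose defaults
define the offline study conditions used throughout the tests:

* 50 locations scattered uniformly over a roughly 200 x 200 km box with
  Zipf rank-size relevances (exponent 1) — the heavy-tailed popularity
  landscape of real tessellations;
* 100 users observed for 28 days, hourly slots, time starting on a week
  boundary;
* a week-periodic planted routine: home with probability 0.9 in night
  slots (22:00-06:59), at a fixed work location with probability 0.7 in
  weekday working hours (09:00-17:59), otherwise home with probability 0.5
  or on an excursion with Zipf-tailed length (1-6 slots, exponent 2.5).
  Excursions are clipped at the night boundary and night-time non-home
  slots are single-slot, which keeps night slots conditionally independent
  — that is what makes the planted night continuation probability an
  identifiable target for recovery tests;
* observation by a Poisson call process at 1 call per hour — sparse enough
  to exercise the gap-filling logic, dense enough that the 0.5 calls/hour
  activity filter is typically passed.

The generator emits its ground truth (homes, work places, full latent
occupancy) alongside the records; tests compare against it rather than
re-deriving it. What the corpus does *not* emulate: bursty (non-Poisson)
call inter-event times, tower-geometry noise, multi-location slots, or
population heterogeneity in routine strength. Passing recovery tests on
this corpus therefore demonstrates correctness of the learning machinery
under the planted model, not performance on real data.

## Problem sizes and numerical choices

The validation experiments run at desk scale, chosen as the smallest sizes
at which the targeted effects are comfortably resolvable: the model grid
runs 9 combinations of 100 agents for 336 hourly slots (two weeks) on the
50-location tessellation; chain recovery refits 500 diaries of four weekly
periods sampled from a known sparse circadian chain, where the stochastic
rows accumulate hundreds to thousands of events and the refitted
probabilities land within a few hundredths of the truth; Monte-Carlo
frequency checks use 1e4 draws and three binomial standard errors, or
chi-square goodness of fit at the 1% level. Parameter-free closed forms
(gravity normalization, radius-of-gyration identities, entropy limits,
KL/RMSE identities) are asserted at numerical tolerance.

Known limitations, beyond those noted inline: one population-level chain
(no per-user heterogeneity in the diary model); zero travel time; no
recency effect in preferential return; trips-per-hour pooled across agents
rather than averaged per agent (the per-agent variant is a one-line change
but a different statistic).
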