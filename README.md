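# ditras

Diary-based simulation of spatio-temporal human mobility in R.

`ditras` generates synthetic trajectories for cohorts of agents moving over
a weighted spatial tessellation, for use in epidemiological what-if
analysis, urban simulation, and the evaluation of mobile ad-hoc network
protocols — settings that need realistic movement data but rarely have
access to real call-detail records (CDR) or GPS traces. Its central idea is
to separate *when* people move from *where* they go:

1. A **mobility diary** fixes the temporal skeleton: a string over
   `{1, 0, |}` where `1` is a slot at the agent's typical (home) location,
   `0` a slot elsewhere, and `|` a move. The data-driven diary generator is
   a periodic Markov chain over states `(h, R)` — slot-of-week `h`, routine
   flag `R` — fitted non-parametrically from location records by the
   Mobility Diary Learner (`abstractify()` + `fit_markov()`). It captures
   the circadian tendency to follow a routine and to break it for stays of
   variable length `tau` via transitions
   `(h,1) -> (h+1,1)`, `(h,1) -> (h+tau,0)`, `(h,0) -> (h+1,1)`,
   `(h,0) -> (h+tau,0)`.
2. A **trajectory generator** places each stay on the map. The flagship
   chooser is d-EPR: with probability `p_new = rho * N^(-gamma)`
   (`rho = 0.6`, `gamma = 0.21`; `N` = distinct locations visited) the
   agent explores an unvisited location drawn from a gravity kernel
   `p_ij ∝ r_i r_j / d_ij^2` over location relevances `r` and distances
   `d`; otherwise it returns to a visited location with probability
   proportional to its visit count. SWIM (home-proximity plus popularity,
   `alpha = 0.75`) and LATP (inverse-power distance, exponent 1.5) are
   provided as alternatives.

Baseline diary generators (random-diary RD; waiting-time WT with
`P(dt) ~ dt^(-1.8) exp(-dt/17h)`), CDR/GPS preprocessing filters, a
synthetic-CDR generator with planted ground truth, and a nine-measure
validation suite (trip distance, radius of gyration `r_g`, mobility entropy
`S`, location frequency `f(L)`, visits per location `V`, locations per user
`N_u`, trips per hour `T`, trips per day `D`, stay time `dt`) with RMSE/KL
comparison complete the toolkit. Any diary generator composes with any
chooser, giving a 3 x 3 grid of models to compare.

## Worked example

Learn a weekly diary model from a synthetic CDR corpus, simulate a cohort,
and compare models:

```r
library(ditras)
set.seed(7)

# a 50-location heavy-tailed tessellation and a 100-user, 28-day corpus
tess  <- generate_toy_tessellation(50)
synth <- generate_synthetic_cdr(synth_spec(), tess)

# preprocess, abstract to per-slot symbols, fit the weekly Markov chain
clean <- filter_cdr_users(synth$records)
users <- attr(clean, "users")
trajs <- lapply(users, function(u)
  abstractify(clean[clean$user_id == u, ], 3600, start_time = 0, n_slots = 672))
model <- fit_markov(trajs)
model
#> Markov diary model: 336 states (period 168 slots of 3600s)
#>   observed states: 326 / 336
#>   transitions: 1935

# simulate 100 agents for two weeks with the d-EPR chooser
cfg  <- simulation_config(n_agents = 100, n_slots = 336, diary = "md",
                          traj = "depr", model = model, seed = 42)
traj <- run_ditras(cfg, tess)
head(traj, 4)
#>   agent_id slot location_id      lat      lon
#> 1        1    1     loc0028 43.98095 10.31393
#> 2        1    2     loc0028 43.98095 10.31393
#> 3        1    3     loc0028 43.98095 10.31393
#> 4        1    4     loc0028 43.98095 10.31393

st <- extract_stays_and_trips(traj[traj$agent_id == 1, ])
radius_of_gyration(st$stays, tess)   # 55.79 km
mobility_entropy(st$stays)           # 0.74
```

Agent 1 starts at home (`loc0028`, drawn relevance-proportionally), its
characteristic travel scale is ~56 km on this ~200 km toy region, and its
entropy of 0.74 reflects a routine-dominated but not fully predictable
schedule. Swapping the learned diary for the perpetual-motion baseline and
comparing the nine measures shows where temporal structure matters:

```r
rd <- run_ditras(simulation_config(100, 336, diary = "rd", traj = "depr",
                                   seed = 42), tess)
compare_measures(population_measures(traj, tess),
                 population_measures(rd, tess))
#>               measure       rmse          kl
#> 1       trip_distance 0.02447322  0.06914759
#> 2  radius_of_gyration 0.06333333  4.76367105
#> 3             entropy 0.16495454  3.77772518
#> 4  location_frequency 0.04093045  0.10660484
#> 5 visits_per_location 0.16024980 21.73786374
#> 6  locations_per_user 0.14748227 24.72267648
#> 7      trips_per_hour 0.01897137  0.11522884
#> 8       trips_per_day 0.19942939 25.42695602
#> 9           stay_time 0.23157318 16.70933890
```

Purely spatial measures (trip distance) barely move — both cohorts share
the d-EPR chooser — while temporal and mixed measures (trips per day, stay
time, entropy, locations per user) diverge sharply, which is precisely the
argument for modelling the diary and the geography separately.

A thin command-line front end over the same functions is installed at
`inst/scripts/ditras.R` (subcommands `simulate`, `measure`, `compare`,
`synth-cdr`).

## Vignette

`vignettes/ditras-methods.Rmd` documents the model and its assumptions,
every tunable parameter with units and defaults, the numerical conventions
(binning, smoothing, tie-breaks, censoring), what the synthetic corpus does
and does not emulate, and known limitations.
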