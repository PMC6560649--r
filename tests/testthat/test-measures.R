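toy_traj <- function(locs, agent_id = 1L, tess = NULL) {
  df <- data.frame(agent_id = agent_id, slot = seq_along(locs),
                   location_id = locs, stringsAsFactors = FALSE)
  if (!is.null(tess)) {
    m <- match(locs, tess$location_id)
    df$lat <- tess$lat[m]; df$lon <- tess$lon[m]
  }
  df
}

test_that("stay/trip extraction finds maximal runs and arrival slots", {
  st <- extract_stays_and_trips(toy_traj(c("A", "A", "B", "A")))
  expect_equal(st$stays$location_id, c("A", "B", "A"))
  expect_equal(st$stays$length_slots, c(2L, 1L, 1L))
  expect_equal(st$trips$arrival_slot, c(3L, 4L))
  expect_equal(st$trips$origin, c("A", "B"))
  expect_equal(st$trips$destination, c("B", "A"))

  one <- extract_stays_and_trips(toy_traj(rep("Z", 5)))
  expect_equal(nrow(one$stays), 1L)
  expect_equal(nrow(one$trips), 0L)

  # trips = stays - 1, structurally
  set.seed(61)
  for (i in 1:10) {
    locs <- sample(LETTERS[1:4], 30, replace = TRUE)
    st <- extract_stays_and_trips(toy_traj(locs))
    expect_equal(nrow(st$trips), nrow(st$stays) - 1L)
  }
})

test_that("radius of gyration matches closed forms and brute force", {
  tess <- line_tess(c(0, 10, 4, 30, 18), relevances = rep(1, 5))
  # single location
  st <- extract_stays_and_trips(toy_traj(rep("L1", 4)))$stays
  expect_equal(radius_of_gyration(st, tess), 0)
  # two locations, equal visits, 10 km apart: r_g = d / 2
  st2 <- extract_stays_and_trips(toy_traj(c("L1", "L2", "L1", "L2")))$stays
  expect_equal(radius_of_gyration(st2, tess), 5, tolerance = 1e-6)

  # independent brute-force evaluation on random visit patterns
  set.seed(62)
  for (i in 1:100) {
    locs <- sample(tess$location_id, 20, replace = TRUE)
    st <- extract_stays_and_trips(toy_traj(locs))$stays
    n_i <- table(st$location_id)
    p <- as.numeric(n_i) / sum(n_i)
    m <- match(names(n_i), tess$location_id)
    lat_cm <- sum(p * tess$lat[m]); lon_cm <- sum(p * tess$lon[m])
    brute <- sqrt(sum(p * haversine_km(tess$lat[m], tess$lon[m],
                                       lat_cm, lon_cm)^2))
    expect_equal(radius_of_gyration(st, tess), brute, tolerance = 1e-9)
  }
})

test_that("mobility entropy spans [0, 1] with the normalized Shannon form", {
  one <- extract_stays_and_trips(toy_traj(rep("A", 6)))$stays
  expect_equal(mobility_entropy(one), 0)
  # uniform over k locations
  unif <- extract_stays_and_trips(toy_traj(c("A", "B", "C", "A", "B", "C")))$stays
  expect_equal(mobility_entropy(unif), 1, tolerance = 1e-12)
  # p = (0.5, 0.25, 0.25): -(0.5 ln 0.5 + 0.5 ln 0.25) / ln 3
  mix <- extract_stays_and_trips(
    toy_traj(c("A", "B", "A", "C")))$stays  # visits A:2 B:1 C:1
  expect_equal(mobility_entropy(mix),
               -(0.5 * log(0.5) + 0.5 * log(0.25)) / log(3),
               tolerance = 1e-12)
  expect_equal(round(mobility_entropy(mix), 4), 0.9464)
})

test_that("RMSE matches the direct formula and is symmetric", {
  expect_equal(rmse(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(rmse(c(0, 1), c(1, 1)), sqrt(0.5), tolerance = 1e-12)
  set.seed(63)
  y <- stats::runif(10); z <- stats::runif(10)
  expect_equal(rmse(y, z), rmse(z, y))
})

test_that("KL divergence matches the direct formula and is non-negative", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0, tolerance = 1e-9)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.75, 0.25)),
               0.5 * log(0.5 / 0.75) + 0.5 * log(0.5 / 0.25),
               tolerance = 1e-6)
  set.seed(64)
  for (i in 1:20) {
    p <- stats::runif(8); p <- p / sum(p)
    q <- stats::runif(8); q <- q / sum(q)
    expect_gte(kl_divergence(p, q), 0)
  }
})

test_that("a stationary agent yields a point-mass location count and no trips", {
  tess <- line_tess(c(0, 5, 9), relevances = c(1, 1, 1))
  traj <- toy_traj(rep("L2", 48), tess = tess)
  suite <- population_measures(traj, tess)
  nu <- suite$locations_per_user
  expect_equal(nu$prob, 1)           # point mass at one distinct location
  expect_equal(sum(suite$trips_per_hour$prob), 0)   # no trips at all
  expect_equal(suite$trips_per_day$prob[1L], 1)      # all days have 0 trips
  expect_equal(sum(suite$stay_time$prob), 1)
})

test_that("population measures equal a hand tally on a 3-agent toy cohort", {
  tess <- line_tess(c(0, 1, 3), relevances = c(2, 1, 1))
  # 24 slots = 1 day; hand-designed stay structures
  a1 <- toy_traj(rep(c("L1", "L2"), each = 12), 1L, tess)     # 1 trip, arr slot 13
  a2 <- toy_traj(rep("L1", 24), 2L, tess)                     # stationary
  a3 <- toy_traj(c(rep("L1", 6), rep("L3", 6), rep("L1", 12)), 3L, tess)
  suite <- population_measures(rbind(a1, a2, a3), tess)

  # locations per user: 2, 1, 2 -> P(1)=1/3, P(2)=2/3
  expect_equal(suite$locations_per_user$prob, c(1 / 3, 2 / 3))
  # trips: a1 arrives slot 13 (hour 12), a3 arrives slots 7 and 13 (hours 6, 12)
  expect_equal(suite$trips_per_hour$prob[c(7, 13)], c(1 / 3, 2 / 3))
  expect_equal(sum(suite$trips_per_hour$prob), 1)
  # trips per day over 3 agent-days: 1, 0, 2
  expect_equal(suite$trips_per_day$prob, c(1 / 3, 1 / 3, 1 / 3))
  # stays: a1 (12,12), a2 (24), a3 (6,6,12) -> 6 stays; bins anchored at 1 h
  expect_equal(sum(suite$stay_time$prob), 1)
  # visits per location: L1 visited 4 stays, L2 1, L3 1
  expect_equal(sum(suite$visits_per_location$prob), 1)
  # trip distances: L1->L2 (1 km) x1, L1->L3 (3 km) and back -> 2 trips of 3 km
  td <- suite$trip_distance
  expect_equal(sum(td$prob), 1)
  in_bin <- function(x, d) which(d$edges[-1L] > x & d$edges[-length(d$edges)] <= x + 1e-12)
  expect_equal(sum(td$prob[in_bin(1, td)]), 1 / 3, tolerance = 1e-12)
})

test_that("measures are invariant to agent and row ordering", {
  set.seed(65)
  tess <- generate_toy_tessellation(12)
  tr <- run_ditras(simulation_config(6, 48, diary = "wt", traj = "depr",
                                     seed = 77), tess)
  shuffled <- tr[sample(nrow(tr)), ]
  s1 <- population_measures(tr, tess)
  s2 <- population_measures(shuffled, tess)
  for (nm in names(s1)) expect_equal(s2[[nm]]$prob, s1[[nm]]$prob)
})

test_that("distributions with nested anchored bins align; foreign bins error", {
  d1 <- ditras:::empdist(c(0, 1, 1.5, 2.25), c(0.2, 0.3, 0.5))
  d2 <- ditras:::empdist(c(0, 1, 1.5, 2.25, 3.375), c(0.2, 0.3, 0.4, 0.1))
  expect_equal(rmse(d1, d2), sqrt(mean(c(0, 0, 0.1, 0.1)^2)))
  d3 <- ditras:::empdist(c(0, 2, 4), c(0.5, 0.5))
  expect_error(rmse(d1, d3), "bin mismatch")
})

test_that("measure suites round-trip through JSON and compare cleanly", {
  set.seed(66)
  tess <- generate_toy_tessellation(10)
  tr <- run_ditras(simulation_config(4, 48, diary = "rd", traj = "latp",
                                     seed = 5), tess)
  suite <- population_measures(tr, tess)
  path <- tempfile(fileext = ".json")
  write_measures(suite, path)
  back <- read_measures(path)
  cmp <- compare_measures(suite, back)
  expect_equal(cmp$rmse, rep(0, 9), tolerance = 1e-12)
  expect_equal(cmp$kl, rep(0, 9), tolerance = 1e-9)
  unlink(path)
})
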