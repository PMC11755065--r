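# Dive detection, trip segmentation and behavioural metrics.

test_that("dive detection applies both threshold and duration filters", {
  tt <- 0:599
  flat <- data.frame(time = tt, depth_m = abs(sin(tt / 50)) * 0.3)
  expect_equal(nrow(detect_dives(flat)), 0)

  d <- rep(0, 600)
  d[100:159] <- 20                     # one 60 s excursion to 20 m
  one <- detect_dives(data.frame(time = tt, depth_m = d))
  expect_equal(nrow(one), 1)
  expect_equal(one$max_depth_m, 20)
  expect_equal(one$duration_min, 1)

  d2 <- rep(0, 600); d2[100:101] <- 5  # 2 s spike
  expect_equal(nrow(detect_dives(data.frame(time = tt, depth_m = d2))), 0)

  expect_equal(nrow(detect_dives(data.frame(time = numeric(0),
                                            depth_m = numeric(0)))), 0)
  expect_error(detect_dives(data.frame(time = 1:3, depth_m = c(1, -1, 0))),
               ">= 0")
})

test_that("trip segmentation applies the distance, duration and dive filters", {
  colony <- c(-82, 62.95)
  # three 2 h out-and-back excursions to 15 km
  series <- make_excursion_series(list(
    list(start_h = 1, max_km = 15, bearing_deg = 90),
    list(start_h = 4, max_km = 15, bearing_deg = 90),
    list(start_h = 7, max_km = 15, bearing_deg = 90)), colony)
  dives <- rbind(make_dive(1.3 * 3600, 60, 20),
                 make_dive(4.3 * 3600, 60, 20),
                 make_dive(7.3 * 3600, 60, 20))
  trips <- segment_trips(series, dives, colony)
  expect_equal(nrow(trips), 3)
  # audit: every kept trip satisfies all three predicates
  expect_true(all(trips$max_dist_km > 1))
  expect_true(all(trips$duration_h * 60 > 20))
  expect_true(all(trips$n_dives >= 1))

  # same excursions without dives -> nothing kept
  expect_equal(nrow(segment_trips(series, dives[0, ], colony)), 0)

  # a 15-min excursion fails the duration filter even with a dive
  short <- make_excursion_series(list(
    list(start_h = 1, max_km = 5, bearing_deg = 90)), colony)
  # clip the away-run to 3 steps (15 min)
  away <- which(short$colonydist_km > 1)
  short$colonydist_km[away[-(1:3)]] <- 0.5
  expect_equal(nrow(segment_trips(short, make_dive(1.1 * 3600, 60, 20),
                                  colony)), 0)

  # a track that never leaves the 1-km circle has no trips
  home <- series; home$colonydist_km <- 0.4
  expect_equal(nrow(segment_trips(home, dives, colony)), 0)
})

test_that("trip summaries reproduce constructed geometry", {
  colony <- c(-82, 62.95)
  series <- make_excursion_series(list(
    list(start_h = 1, max_km = 20, bearing_deg = 90)), colony)
  dives <- make_dive(1.4 * 3600, 60, 20)
  trips <- segment_trips(series, dives, colony)
  expect_equal(nrow(trips), 1)
  expect_equal(trips$max_dist_km, 20, tolerance = 0.01)
  expect_equal(trips$path_km, 40, tolerance = 0.05)      # out and back
  expect_equal(trips$azimuth_deg, 90, tolerance = 0.5)   # due east

  # single-step trip: path is the approach plus return leg around that step
  idx <- which(series$colonydist_km > 1)[5]
  one <- trip_summary(idx, series, colony)
  expect_equal(one$path_km, series$step_km[idx] + series$step_km[idx + 1])
})

test_that("path and maximum distance are invariant to time reversal", {
  colony <- c(-82, 62.95)
  series <- make_excursion_series(list(
    list(start_h = 1, max_km = 12, bearing_deg = 45)), colony)
  idx <- which(series$colonydist_km > 1)
  fwd <- trip_summary(idx, series, colony)
  rev_series <- series[rev(seq_len(nrow(series))), ]
  n <- nrow(rev_series)
  pos <- cbind(rev_series$lon, rev_series$lat)
  rev_series$step_km <- c(0, geosphere::distHaversine(
    pos[-n, , drop = FALSE], pos[-1, , drop = FALSE], r = 6371000) / 1000)
  ridx <- sort(n + 1 - idx)
  bwd <- trip_summary(ridx, rev_series, colony)
  expect_equal(bwd$max_dist_km, fwd$max_dist_km, tolerance = 1e-9)
  expect_equal(bwd$path_km, fwd$path_km, tolerance = 1e-6)
  expect_equal(bwd$azimuth_deg, fwd$azimuth_deg, tolerance = 1e-6)
})

test_that("hourly mean depths group and propagate correctly", {
  dives <- rbind(make_dive(0, 60, 10, hour = 3),
                 make_dive(100, 60, 20, hour = 3),
                 make_dive(200, 60, 10, hour = 7))
  h <- hourly_mean_depth(dives)
  expect_equal(unname(h["3"]), 15)
  expect_equal(unname(h["7"]), 10)
  expect_true(is.na(h["12"]))
  expect_error(hourly_mean_depth(dives[0, ]), "no dives")
  # a dive in an hour with no mean is impossible by construction, and the
  # rejection names the hour if forced
  bad <- make_dive(0, 60, 5, hour = 12)
  h2 <- h; h2["12"] <- NA
  expect_error(differential_depth(bad, h2), "12")
})

test_that("differential depth matches a spreadsheet-style manual computation", {
  dives <- rbind(make_dive(0, 60, 12, hour = 2),
                 make_dive(10, 60, 18, hour = 2),
                 make_dive(20, 60, 30, hour = 2),
                 make_dive(30, 60, 8, hour = 9),
                 make_dive(40, 60, 12, hour = 9),
                 make_dive(50, 60, 25, hour = 9))
  h <- hourly_mean_depth(dives)
  # hour 2 mean = (12+18+30)/3 = 20; hour 9 mean = (8+12+25)/3 = 15
  dd <- differential_depth(dives, h)
  expect_equal(dd, c(-8, -2, 10, -7, -3, 10))
  # a dive exactly at its hour's mean has differential 0
  at_mean <- make_dive(60, 60, 20, hour = 2)
  expect_equal(differential_depth(at_mean, h), 0)
  # all-equal depths -> all differentials 0
  eq <- rbind(make_dive(0, 60, 10, hour = 1), make_dive(9, 60, 10, hour = 5))
  expect_equal(differential_depth(eq, hourly_mean_depth(eq)), c(0, 0))
})

test_that("deployment summaries do the arithmetic they claim", {
  colony <- c(-82, 62.95)
  series <- make_excursion_series(list(
    list(start_h = 1, max_km = 15, bearing_deg = 90),
    list(start_h = 5, max_km = 30, bearing_deg = 90)), colony)
  dives <- rbind(make_dive(1.3 * 3600, 60, 20), make_dive(5.6 * 3600, 90, 30))
  trips <- segment_trips(series, dives, colony)
  expect_equal(nrow(trips), 2)
  span_h <- as.numeric(diff(range(series$time))) / 3600
  m <- deployment_summary(trips, dives, span_hours = span_h)
  expect_equal(m$trip_duration_h, mean(trips$duration_h))
  expect_equal(m$daily_dist_km, sum(trips$path_km) / (span_h / 24))
  expect_equal(m$trips_per_day, 2 / (span_h / 24))
  expect_equal(m$total_dist_km, sum(trips$path_km))
  expect_false(m$single_trip)
  # per-trip distances can never exceed the whole-deployment path
  expect_lte(sum(trips$path_km), sum(series$step_km))
  # a two-trip deployment with durations 2 h and 4 h has mean 3 h
  fake <- trips; fake$duration_h <- c(2, 4)
  m2 <- deployment_summary(fake, dives, span_hours = span_h)
  expect_equal(m2$trip_duration_h, 3)
  # single-trip SDs are 0, flagged, not missing
  m1 <- deployment_summary(trips[1, ], dives[1, ], span_hours = span_h)
  expect_equal(m1$sd_trip_duration_h, 0)
  expect_true(m1$single_trip)
  expect_error(deployment_summary(trips[0, ], dives, span_hours = span_h),
               "no kept trips")
  expect_error(deployment_summary(trips, dives, span_hours = 0), "zero")
})

test_that("activity proportions from a decoded path sum to one", {
  spec <- hmm_spec()
  sim <- simulate_hmm_data(spec, 400, seed = 88)
  dec <- decode(sim$series, spec)
  colony <- c(-82, 62.95)
  series <- make_excursion_series(list(
    list(start_h = 1, max_km = 15, bearing_deg = 90)), colony)
  dives <- make_dive(1.3 * 3600, 60, 20)
  trips <- segment_trips(series, dives, colony)
  m <- deployment_summary(trips, dives, states = dec, span_hours = 10)
  expect_equal(m$prop_colony + m$prop_diving + m$prop_flying +
                 m$prop_swimming, 1, tolerance = 1e-6)
})
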