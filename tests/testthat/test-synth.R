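# Synthetic colony generator: declared moments, (dis)assortment construction,
# track/dive structure, fixture round trips.

test_that("config validation names the offending field", {
  expect_error(sim_config(deployment_hours = NA), "deployment_hours")
  expect_error(sim_config(wing_assortment = 2), "wing_assortment")
  expect_error(sim_config(disassortment = c(mean_trip_distance = -2)),
               "disassortment")
  expect_error(sim_config(n_pairs_per_year = c("2022" = 1)),
               "n_pairs_per_year")
})

test_that("generator respects its own declared trait moments", {
  # moments are declared up to the positivity floor, so check them where
  # truncation is negligible: all traits at zero disassortment, and the
  # widened-gap law on trip distance (whose spread stays far from zero)
  cfg <- sim_config(n_pairs_per_year = c("2022" = 1500),
                    disassortment = c(mean_trip_distance = 1.2),
                    seed = 42)
  ph <- draw_phenotypes(cfg)
  tr <- cfg$traits
  for (j in seq_len(nrow(tr))) {
    trait <- tr$trait[j]
    if (trait == "preferred_azimuth") next  # wrapped; checked circularly below
    d <- cfg$disassortment[trait]
    d <- if (is.na(d) || is.null(d)) 0 else unname(d)
    for (sex in c("F", "M")) {
      mu <- if (sex == "F") tr$f_mean[j] else tr$m_mean[j]
      mu_other <- if (sex == "F") tr$m_mean[j] else tr$f_mean[j]
      # declared moment: the disassortment spread widens the sex gap too
      mu_decl <- mu + d * (mu - mu_other) / 2
      x <- ph[ph$sex == sex, trait]
      se <- sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - mu_decl), 3 * se + 1e-9,
                label = paste("mean of", trait, sex))
    }
  }
  # azimuths are wrapped: compare circular means
  for (sex in c("F", "M")) {
    mu <- if (sex == "F") 267 else 242
    a <- ph$preferred_azimuth[ph$sex == sex] * pi / 180
    circ <- (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
    expect_lt(abs(circ - mu), 3)
  }
})

test_that("zero structure makes real-pair differences indistinguishable from random", {
  cfg <- sim_config(n_pairs_per_year = c("2022" = 5000),
                    disassortment = c(mean_trip_distance = 0),
                    wing_assortment = 0, seed = 11)
  ph <- draw_phenotypes(cfg)
  fem <- ph[ph$sex == "F", ]; mal <- ph[ph$sex == "M", ]
  real <- abs(fem$mean_trip_distance - mal$mean_trip_distance)
  set.seed(1)
  rand <- abs(fem$mean_trip_distance -
                mal$mean_trip_distance[sample(nrow(mal))])
  expect_gt(suppressWarnings(ks.test(real, rand)$p.value), 0.01)
  # wings too, with assortment off
  realw <- abs(fem$wing_length - mal$wing_length)
  randw <- abs(fem$wing_length - mal$wing_length[sample(nrow(mal))])
  expect_gt(suppressWarnings(ks.test(realw, randw)$p.value), 0.01)
})

test_that("full wing assortment makes mates' wings identical", {
  cfg <- sim_config(n_pairs_per_year = c("2022" = 50), wing_assortment = 1,
                    seed = 3)
  ph <- draw_phenotypes(cfg)
  fem <- ph[ph$sex == "F", ]; mal <- ph[ph$sex == "M", ]
  expect_equal(fem$wing_length, mal$wing_length, tolerance = 1e-12)
})

test_that("disassortment scales the expected absolute difference by (1 + d)", {
  # Monte-Carlo oracle: expected |difference| of two INDEPENDENT draws from
  # the sex-specific base distributions, at large n
  d <- 0.5
  cfg <- sim_config(n_pairs_per_year = c("2022" = 10000),
                    disassortment = c(mean_trip_distance = d), seed = 9)
  ph <- draw_phenotypes(cfg)
  fem <- ph[ph$sex == "F", ]; mal <- ph[ph$sex == "M", ]
  real <- abs(fem$mean_trip_distance - mal$mean_trip_distance)
  tr <- cfg$traits[cfg$traits$trait == "mean_trip_distance", ]
  set.seed(99)
  indep <- abs(rnorm(2e5, tr$f_mean, tr$f_sd) - rnorm(2e5, tr$m_mean,
                                                      tr$m_sd))
  ratio <- mean(real) / mean(indep)
  se <- sd(real) / sqrt(length(real)) / mean(indep)
  expect_lt(abs(ratio - (1 + d)), 3 * se)
})

test_that("tracks are deterministic under a fixed seed", {
  cfg <- sim_config(n_pairs_per_year = c("2022" = 2), deployment_hours = 6,
                    seed = 5)
  ph <- draw_phenotypes(cfg)
  a <- simulate_track(ph[1, ], cfg, seed = 123)
  b <- simulate_track(ph[1, ], cfg, seed = 123)
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$depths, b$depths)
})

test_that("a bird that never dives yields no trips downstream", {
  cfg <- sim_config(n_pairs_per_year = c("2022" = 2), deployment_hours = 12,
                    seed = 5)
  ph <- draw_phenotypes(cfg)
  ph$dives_per_day[1] <- 0
  dep <- simulate_track(ph[1, ], cfg, seed = 17)
  expect_lt(max(dep$depths$depth_m), 1)
  dives <- detect_dives(dep$depths)
  expect_equal(nrow(dives), 0)
  series <- regularize(dep$fixes, cfg$colony_lonlat)
  trips <- segment_trips(series, dives, cfg$colony_lonlat)
  expect_equal(nrow(trips), 0)
})

test_that("the walk stays bounded near its target trip distance", {
  cfg <- sim_config(n_pairs_per_year = c("2022" = 2), deployment_hours = 24,
                    seed = 5)
  ph <- draw_phenotypes(cfg)
  ph$mean_trip_distance[1] <- 5
  for (s in c(2, 23, 101)) {
    dep <- simulate_track(ph[1, ], cfg, seed = s)
    cd <- gc_dist <- geosphere::distHaversine(
      cbind(dep$fixes$lon, dep$fixes$lat),
      matrix(cfg$colony_lonlat, nrow(dep$fixes), 2, byrow = TRUE),
      r = 6371000) / 1000
    expect_lt(max(cd), 10)
  }
})

test_that("fixture sets have the right shape and reproduce under a seed", {
  cfg <- sim_config(n_pairs_per_year = c("2022" = 2), deployment_hours = 2,
                    seed = 8)
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  m1 <- write_fixture_set(cfg, d1)
  m2 <- write_fixture_set(cfg, d2)
  expect_equal(sum(grepl("^track_", m1$file)), 4)
  expect_equal(sum(grepl("^depth_", m1$file)), 4)
  md <- read.csv(file.path(d1, "metadata.csv"))
  expect_equal(nrow(md), 4)
  expect_identical(m1$md5, m2$md5)   # same seed, same bytes
  # read back round trip
  deps <- read_fixture_set(d1)
  expect_length(deps, 4)
  expect_equal(deps[[1]]$bird_id, md$bird_id[1])
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the default study design enrolls 80 birds across two seasons", {
  ph <- draw_phenotypes(sim_config())
  expect_equal(nrow(ph), 80)
  expect_equal(sum(ph$year == "2022"), 38)
  expect_equal(sum(ph$year == "2023"), 42)
})
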