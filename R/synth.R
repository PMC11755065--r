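# Synthetic colony generator: paired central-place foragers with configurable
# within-pair trait (dis)assortment, biased-correlated-random-walk tracks and
# 1 Hz depth traces carrying V-shaped dives.

# Sex-specific phenotype distributions. Foraging means/SDs follow the field
# scale for a chick-rearing murre colony (trip range tens of km, females
# ranging farther and diving deeper/more often than males); morphometrics are
# common to both sexes in this monomorphic species.
.default_traits <- function() {
  data.frame(
    trait  = c("mean_trip_distance", "dives_per_day", "preferred_azimuth",
               "mean_dive_depth", "wing_length", "head_bill", "body_mass"),
    f_mean = c(41.5, 120, 267, 40, 220, 111, 981),
    f_sd   = c(12.9,  40,  31, 12,   4,   3,  65),
    m_mean = c(31.0,  80, 242, 25, 220, 111, 981),
    m_sd   = c( 9.9,  30,  57, 10,   4,   3,  65),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic colony generator
#'
#' Defines the study conditions emulated by the generator: two field seasons
#' of paired deployments (19 + 21 pairs by default, 80 birds), 72-h
#' deployments with a GPS fix every 3 min and depth sampled at 1 Hz, and a
#' trait model in which breeding partners can be made more dissimilar
#' (disassortative) or more similar (assortative) than random female x male
#' combinations.
#'
#' Disassortment is parameterised per trait: for disassortment `d`, mates are
#' drawn independently from the sex-specific trait distributions and then
#' spread about their midpoint by a factor `(1 + d)`, so the expected absolute
#' within-pair difference is exactly `(1 + d)` times that of two independent
#' draws — for any trait distributions, which is why the spread acts on the
#' whole signed difference. The declared moments under disassortment follow
#' directly: pair midpoints keep their mean `(mu_F + mu_M) / 2`, and each
#' sex's marginal mean moves to `mu + d (mu - mu_other) / 2` (the sex gap,
#' like every other component of the difference, widens by `(1 + d)`).
#' Wing length instead uses a correlation parameter
#' `wing_assortment` in `[0, 1]`: the mates' wing lengths are jointly Gaussian
#' with that correlation (1 with zero noise means identical wings).
#'
#' @param n_pairs_per_year Named integer vector, pairs per season label
#'   (default `c("2022" = 19, "2023" = 21)`).
#' @param deployment_hours Deployment length in hours (default 72).
#' @param gps_interval GPS fix interval in seconds (default 180).
#' @param depth_rate Depth sampling rate in Hz (default 1).
#' @param colony_lonlat Colony (lon, lat) in degrees.
#' @param traits Data frame of per-trait sex-specific means and SDs
#'   (columns `trait, f_mean, f_sd, m_mean, m_sd`).
#' @param disassortment Named numeric vector of per-trait disassortment
#'   parameters (values >= -1; positive means real pairs more different).
#' @param wing_assortment Correlation of mates' wing lengths in `[0, 1]`.
#' @param noise_sd Named numeric vector of per-trait observation noise SDs
#'   used by [simulate_pair_study()]; defaults to 15% of each trait's
#'   between-bird SD.
#' @param mass_loss_mean,mass_loss_sd Mean and SD (g) of body-mass loss
#'   between deployment and retrieval.
#' @param dive_miss_prob Probability that an excursion carries no dive.
#' @param flight_speed_kmh,swim_speed_kmh Commuting and foraging speeds.
#' @param colony_bout_hours Mean colony-attendance bout between trips (h).
#' @param forage_hours Mean duration of the foraging phase of a trip (h).
#' @param tz_offset_hours Colony local time minus UTC, hours (default -5).
#' @param seed Integer seed; every stream the generator uses derives from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_pairs_per_year = c("2022" = 2), deployment_hours = 12)
#' ph <- draw_phenotypes(cfg)
sim_config <- function(n_pairs_per_year = c("2022" = 19, "2023" = 21),
                       deployment_hours = 72,
                       gps_interval = 180,
                       depth_rate = 1,
                       colony_lonlat = c(-82.019, 62.948),
                       traits = .default_traits(),
                       disassortment = c(mean_trip_distance = 1.2,
                                         dives_per_day = 1.8),
                       wing_assortment = 0.4,
                       noise_sd = NULL,
                       mass_loss_mean = 20,
                       mass_loss_sd = 34,
                       dive_miss_prob = 0,
                       flight_speed_kmh = 60,
                       swim_speed_kmh = 2,
                       colony_bout_hours = 3,
                       forage_hours = 2,
                       tz_offset_hours = -5,
                       seed = 1L) {
  stopifnot(is.data.frame(traits),
            all(c("trait", "f_mean", "f_sd", "m_mean", "m_sd") %in%
                  names(traits)))
  if (is.null(names(n_pairs_per_year)))
    names(n_pairs_per_year) <- as.character(seq_along(n_pairs_per_year) + 2021)
  cfg <- list(n_pairs_per_year = n_pairs_per_year,
              years = names(n_pairs_per_year),
              deployment_hours = deployment_hours,
              gps_interval = gps_interval,
              depth_rate = depth_rate,
              colony_lonlat = as.numeric(colony_lonlat),
              traits = traits,
              disassortment = disassortment,
              wing_assortment = wing_assortment,
              noise_sd = noise_sd,
              mass_loss_mean = mass_loss_mean,
              mass_loss_sd = mass_loss_sd,
              dive_miss_prob = dive_miss_prob,
              flight_speed_kmh = flight_speed_kmh,
              swim_speed_kmh = swim_speed_kmh,
              colony_bout_hours = colony_bout_hours,
              forage_hours = forage_hours,
              tz_offset_hours = tz_offset_hours,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  if (is.null(cfg$noise_sd)) {
    ns <- 0.15 * (traits$f_sd + traits$m_sd) / 2
    names(ns) <- traits$trait
    cfg$noise_sd <- ns
  }
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num_fields <- c("deployment_hours", "gps_interval", "depth_rate",
                  "colony_lonlat", "disassortment", "wing_assortment",
                  "mass_loss_mean", "mass_loss_sd", "dive_miss_prob",
                  "flight_speed_kmh", "swim_speed_kmh", "colony_bout_hours",
                  "forage_hours", "tz_offset_hours")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.null(v) && any(!is.finite(v)))
      stop("non-finite value in config field '", f, "'")
  }
  if (any(!is.finite(unlist(cfg$traits[, -1]))))
    stop("non-finite value in config field 'traits'")
  if (any(cfg$n_pairs_per_year < 2))
    stop("n_pairs_per_year must be >= 2 for every year")
  if (cfg$deployment_hours <= 0) stop("deployment_hours must be > 0")
  if (cfg$gps_interval <= 0) stop("gps_interval must be > 0")
  if (any(cfg$traits$f_sd < 0) || any(cfg$traits$m_sd < 0))
    stop("trait SDs must be >= 0")
  if (any(cfg$disassortment < -1))
    stop("disassortment must be >= -1")
  if (cfg$wing_assortment < 0 || cfg$wing_assortment > 1)
    stop("wing_assortment must be in [0, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic colony configuration\n")
  cat("  pairs/year:", paste(names(x$n_pairs_per_year),
                             x$n_pairs_per_year, sep = "=", collapse = ", "),
      "\n")
  cat("  deployment:", x$deployment_hours, "h; GPS every", x$gps_interval,
      "s; depth", x$depth_rate, "Hz\n")
  cat("  colony (lon, lat):", x$colony_lonlat[1], x$colony_lonlat[2], "\n")
  d <- x$disassortment[x$disassortment != 0]
  cat("  disassortment:", if (length(d))
    paste(names(d), d, sep = "=", collapse = ", ") else "none",
    "; wing assortment:", x$wing_assortment, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Deterministic sub-stream seed derived from the global seed (kept < 2^31).
.substream <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Draw phenotypes for every pair in the colony
#'
#' For each pair and trait the two mates are drawn independently from the
#' sex-specific distribution, then spread about their midpoint by
#' `(1 + disassortment)`, making the expected absolute within-pair difference
#' exactly `(1 + d)` times that of two independent draws. Wing lengths are
#' jointly Gaussian with correlation `wing_assortment`. Azimuths are wrapped
#' to `[0, 360)`; all other traits are truncated at a small positive floor.
#'
#' @param config A [sim_config()].
#' @return Data frame, one row per bird: `bird_id, pair_id, year, sex` and one
#'   column per trait.
#' @export
draw_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(.substream(config$seed, 1L))
  tr <- config$traits
  rows <- list()
  for (yr in config$years) {
    n <- config$n_pairs_per_year[[yr]]
    pair_id <- sprintf("%s_P%02d", yr, seq_len(n))
    fem <- matrix(NA_real_, n, nrow(tr), dimnames = list(NULL, tr$trait))
    mal <- fem
    for (j in seq_len(nrow(tr))) {
      trait <- tr$trait[j]
      if (trait == "wing_length") {
        rho <- config$wing_assortment
        z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
        fem[, j] <- tr$f_mean[j] + tr$f_sd[j] * z1
        mal[, j] <- tr$m_mean[j] +
          tr$m_sd[j] * (rho * z1 + sqrt(1 - rho^2) * z2)
      } else {
        f0 <- stats::rnorm(n, tr$f_mean[j], tr$f_sd[j])
        m0 <- stats::rnorm(n, tr$m_mean[j], tr$m_sd[j])
        d <- config$disassortment[trait]
        d <- if (is.na(d) || is.null(d)) 0 else unname(d)
        mid <- (f0 + m0) / 2
        fem[, j] <- mid + (1 + d) * (f0 - mid)
        mal[, j] <- mid + (1 + d) * (m0 - mid)
      }
    }
    fix <- function(mat) {
      az <- mat[, "preferred_azimuth"] %% 360
      mat[, "preferred_azimuth"] <- az
      pos <- setdiff(colnames(mat), "preferred_azimuth")
      mat[, pos] <- pmax(mat[, pos], 0.01)
      mat
    }
    fem <- fix(fem); mal <- fix(mal)
    rows[[yr]] <- rbind(
      data.frame(bird_id = paste0(pair_id, "_F"), pair_id = pair_id,
                 year = yr, sex = "F", fem, stringsAsFactors = FALSE),
      data.frame(bird_id = paste0(pair_id, "_M"), pair_id = pair_id,
                 year = yr, sex = "M", mal, stringsAsFactors = FALSE)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Start of the synthetic deployment window for a season label.
.deploy_origin <- function(year) {
  yr <- suppressWarnings(as.integer(year))
  if (is.na(yr)) yr <- 2022L
  as.POSIXct(sprintf("%d-07-25 12:00:00", yr), tz = "UTC")
}

#' Simulate one bird's GPS track and depth trace
#'
#' The track alternates colony-attendance bouts with out-and-back foraging
#' excursions: a biased correlated random walk flies out toward a target at
#' roughly `mean_trip_distance` along the bird's preferred azimuth, drifts
#' slowly during a foraging phase, then returns. The 1 Hz depth trace is
#' surface noise plus V-shaped dives (descent, short bottom, ascent) placed in
#' foraging phases at the bird's `dives_per_day` rate; every excursion carries
#' at least one dive unless a `dive_miss_prob` coin says otherwise. A
#' per-fix `flight_intensity` scalar (a wing-beat-frequency stand-in derived
#' from the current behavioural phase) travels with the track for use as an
#' HMM emission.
#'
#' @param phenotype One row of [draw_phenotypes()] output (or a list with the
#'   same fields).
#' @param config A [sim_config()].
#' @param seed Integer seed for this bird's streams.
#' @return A `deployment` object: list with `bird_id`, `sex`, `year`,
#'   `pair_id`, `fixes` (data frame `time, lon, lat, flight_intensity`),
#'   `depths` (data frame `time, depth_m`), `morph` (wing, head-bill, pre and
#'   post masses) and `truth` (the phenotype and per-trip targets).
#' @export
simulate_track <- function(phenotype, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  ph <- as.list(phenotype)
  for (f in c("mean_trip_distance", "dives_per_day", "preferred_azimuth",
              "mean_dive_depth"))
    if (is.null(ph[[f]]) || !is.finite(ph[[f]]))
      stop("phenotype is missing field '", f, "'")
  set.seed(as.integer(seed) %% 2147483647L)

  t0 <- .deploy_origin(ph$year %||% config$years[1])
  horizon <- config$deployment_hours * 3600
  dt <- config$gps_interval
  n_fix <- floor(horizon / dt) + 1
  fix_t <- seq(0, by = dt, length.out = n_fix)

  # phase plan: sequence of (phase, duration s, target distance m, azimuth)
  plan <- list()
  tcur <- stats::runif(1, 0, 0.5) * 3600   # first colony bout is short
  plan[[1]] <- list(phase = "colony", start = 0, end = tcur)
  while (tcur < horizon) {
    D <- stats::rnorm(1, ph$mean_trip_distance, 0.12 * ph$mean_trip_distance)
    D <- min(max(D, 0.25 * ph$mean_trip_distance), 1.8 * ph$mean_trip_distance)
    az <- (ph$preferred_azimuth + stats::rnorm(1, 0, 20)) %% 360
    t_out <- D / config$flight_speed_kmh * 3600
    t_forage <- max(1200, stats::rnorm(1, config$forage_hours * 3600,
                                       0.3 * config$forage_hours * 3600))
    plan[[length(plan) + 1]] <- list(phase = "out", start = tcur,
                                     end = tcur + t_out, D = D, az = az)
    tcur <- tcur + t_out
    plan[[length(plan) + 1]] <- list(phase = "forage", start = tcur,
                                     end = tcur + t_forage, D = D, az = az)
    tcur <- tcur + t_forage
    plan[[length(plan) + 1]] <- list(phase = "return", start = tcur,
                                     end = tcur + t_out, D = D, az = az)
    tcur <- tcur + t_out
    bout <- max(900, stats::rnorm(1, config$colony_bout_hours * 3600,
                                  0.3 * config$colony_bout_hours * 3600))
    plan[[length(plan) + 1]] <- list(phase = "colony", start = tcur,
                                     end = tcur + bout)
    tcur <- tcur + bout
  }

  phase_at <- function(t) {
    for (p in plan) if (t >= p$start && t < p$end) return(p)
    plan[[length(plan)]]
  }

  # walk in the local tangent plane (km east/north of the colony)
  xy <- matrix(0, n_fix, 2)
  fi <- numeric(n_fix)
  fi_mean <- c(colony = 0.5, out = 8, forage = 1.2, `return` = 8)
  fi_sd   <- c(colony = 0.3, out = 1, forage = 0.6, `return` = 1)
  for (i in seq_len(n_fix)) {
    p <- phase_at(fix_t[i])
    fi[i] <- stats::rnorm(1, fi_mean[[p$phase]], fi_sd[[p$phase]])
    if (i == 1) next
    prev <- xy[i - 1, ]
    if (p$phase == "colony") {
      xy[i, ] <- stats::rnorm(2, 0, 0.03)
    } else if (p$phase == "out" || p$phase == "return") {
      target <- if (p$phase == "out")
        p$D * c(sin(p$az * pi / 180), cos(p$az * pi / 180)) else c(0, 0)
      dvec <- target - prev
      dist <- sqrt(sum(dvec^2))
      step <- config$flight_speed_kmh * dt / 3600
      if (dist <= step) {
        xy[i, ] <- target + stats::rnorm(2, 0, 0.05)
      } else {
        head <- atan2(dvec[1], dvec[2]) + stats::rnorm(1, 0, 10 * pi / 180)
        xy[i, ] <- prev + step * c(sin(head), cos(head))
      }
    } else { # forage: slow drift around the target
      step <- config$swim_speed_kmh * dt / 3600
      head <- stats::runif(1, 0, 2 * pi)
      xy[i, ] <- prev + step * c(sin(head), cos(head))
    }
  }
  lonlat <- unproject_aeqd(xy * 1000, config$colony_lonlat)

  # depth trace at depth_rate Hz
  dts <- 1 / config$depth_rate
  dep_t <- seq(0, horizon, by = dts)
  depth <- abs(stats::rnorm(length(dep_t), 0, 0.05))
  forage_windows <- Filter(function(p) p$phase == "forage", plan)
  forage_windows <- Filter(function(p) p$start < horizon, forage_windows)
  n_dives_total <- stats::rpois(1, ph$dives_per_day * horizon / 86400)
  dive_starts <- numeric(0)
  if (length(forage_windows) && ph$dives_per_day > 0) {
    durs <- vapply(forage_windows, function(p)
      min(p$end, horizon) - p$start, 0)
    alloc <- if (n_dives_total > 0)
      as.vector(stats::rmultinom(1, n_dives_total, durs / sum(durs)))
    else rep(0L, length(durs))
    for (k in seq_along(forage_windows)) {
      nk <- alloc[k]
      if (nk < 1 && stats::runif(1) > config$dive_miss_prob) nk <- 1L
      if (nk < 1) next
      w <- forage_windows[[k]]
      w1 <- max(w$start + 6, min(w$end, horizon) - 300)
      # evenly spaced slots with jitter: dives rarely overlap unless the
      # rate genuinely saturates the foraging time
      slots <- w$start + 5 + (seq_len(nk) - 0.5) / nk * (w1 - w$start - 5)
      jit <- (w1 - w$start - 5) / nk * 0.3
      dive_starts <- c(dive_starts,
                       sort(slots + stats::runif(nk, -jit, jit)))
    }
  }
  dive_truth <- list()
  for (s in dive_starts) {
    dmax <- stats::rnorm(1, ph$mean_dive_depth, 0.2 * ph$mean_dive_depth)
    dmax <- max(dmax, 1.5)
    rate <- 1.2                      # m/s descent and ascent
    t_leg <- dmax / rate
    t_bottom <- stats::runif(1, 10, 30)
    total <- 2 * t_leg + t_bottom
    idx <- which(dep_t >= s & dep_t <= s + total)
    if (!length(idx)) next
    rel <- dep_t[idx] - s
    prof <- ifelse(rel < t_leg, rel * rate,
                   ifelse(rel < t_leg + t_bottom, dmax,
                          pmax(0, dmax - (rel - t_leg - t_bottom) * rate)))
    depth[idx] <- pmax(depth[idx], prof)
    dive_truth[[length(dive_truth) + 1]] <-
      c(start = s, duration = total, max_depth = dmax)
  }

  wing <- ph$wing_length %||% 220
  hb <- ph$head_bill %||% 111
  mass_pre <- ph$body_mass %||% 981
  mass_post <- mass_pre - stats::rnorm(1, config$mass_loss_mean,
                                       config$mass_loss_sd)
  structure(list(
    bird_id = ph$bird_id %||% "bird",
    sex = ph$sex %||% NA_character_,
    year = as.character(ph$year %||% config$years[1]),
    pair_id = ph$pair_id %||% NA_character_,
    fixes = data.frame(time = t0 + fix_t, lon = lonlat[, "lon"],
                       lat = lonlat[, "lat"], flight_intensity = fi),
    depths = data.frame(time = as.numeric(t0) + dep_t, depth_m = depth),
    morph = list(wing_mm = wing, headbill_mm = hb,
                 mass_pre_g = mass_pre, mass_post_g = mass_post),
    truth = list(phenotype = ph, n_trips_planned =
                   sum(vapply(plan, function(p) p$phase == "out", TRUE)),
                 dives = dive_truth)
  ), class = "deployment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.deployment <- function(x, ...) {
  cat("Deployment", x$bird_id, sprintf("(%s, %s)\n", x$sex, x$year))
  cat(" ", nrow(x$fixes), "GPS fixes;", nrow(x$depths), "depth samples;",
      length(x$truth$dives), "true dives\n")
  invisible(x)
}

#' Simulate a whole colony of paired deployments
#'
#' @param config A [sim_config()].
#' @return List with `phenotypes` (data frame), `deployments` (list of
#'   [simulate_track()] outputs) and `metadata` (one row per bird).
#' @export
simulate_colony <- function(config) {
  ph <- draw_phenotypes(config)
  deps <- vector("list", nrow(ph))
  for (i in seq_len(nrow(ph)))
    deps[[i]] <- simulate_track(ph[i, ], config,
                                seed = .substream(config$seed, 100 + i))
  names(deps) <- ph$bird_id
  md <- do.call(rbind, lapply(deps, function(d)
    data.frame(bird_id = d$bird_id, sex = d$sex, year = d$year,
               pair_id = d$pair_id, wing_mm = d$morph$wing_mm,
               headbill_mm = d$morph$headbill_mm,
               mass_pre_g = d$morph$mass_pre_g,
               mass_post_g = d$morph$mass_post_g,
               stringsAsFactors = FALSE)))
  rownames(md) <- NULL
  list(phenotypes = ph, deployments = deps, metadata = md)
}

#' Fast phenotype-level study simulator
#'
#' Produces the bird-level behavioural metrics a full deployment analysis
#' would estimate, directly from the phenotypes plus observation noise
#' (`config$noise_sd`, defaulting to 15% of each trait's between-bird SD).
#' This is the generator used for replicated parameter-recovery and
#' calibration studies, where re-running the full track -> HMM -> trip chain
#' for every replicate would add nothing: the pair-level inference consumes
#' bird-level metrics, which is exactly what this returns.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return List with `metrics` (one row per bird: identity columns plus one
#'   column per trait, observation noise added) and `phenotypes` (the
#'   noise-free truth).
#' @export
simulate_pair_study <- function(config, seed = config$seed) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  ph <- draw_phenotypes(cfg)
  set.seed(.substream(cfg$seed, 2L))
  met <- ph
  for (trait in cfg$traits$trait) {
    ns <- cfg$noise_sd[[trait]] %||% 0
    met[[trait]] <- met[[trait]] + stats::rnorm(nrow(met), 0, ns)
    if (trait == "preferred_azimuth") met[[trait]] <- met[[trait]] %% 360
    else met[[trait]] <- pmax(met[[trait]], 0.01)
  }
  list(metrics = met, phenotypes = ph)
}

#' Write a synthetic fixture set to disk
#'
#' One track CSV and one depth CSV per bird, a metadata CSV, and a
#' ground-truth JSON holding the phenotypes and configuration.
#'
#' @param config A [sim_config()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, a manifest data frame (`file`, `md5`).
#' @export
write_fixture_set <- function(config, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  col <- simulate_colony(config)
  files <- character(0)
  for (d in col$deployments) {
    tf <- file.path(directory, paste0("track_", d$bird_id, ".csv"))
    track <- data.frame(bird_id = d$bird_id,
                        timestamp_iso8601 = format(d$fixes$time,
                                                   "%Y-%m-%dT%H:%M:%SZ",
                                                   tz = "UTC"),
                        lon = d$fixes$lon, lat = d$fixes$lat,
                        flight_intensity = d$fixes$flight_intensity)
    utils::write.csv(track, tf, row.names = FALSE, quote = FALSE)
    df <- file.path(directory, paste0("depth_", d$bird_id, ".csv"))
    dep <- data.frame(bird_id = d$bird_id,
                      timestamp_iso8601 = format(
                        as.POSIXct(d$depths$time, origin = "1970-01-01",
                                   tz = "UTC"),
                        "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                      depth_m = round(d$depths$depth_m, 1))
    utils::write.csv(dep, df, row.names = FALSE, quote = FALSE)
    files <- c(files, tf, df)
  }
  mf <- file.path(directory, "metadata.csv")
  utils::write.csv(col$metadata, mf, row.names = FALSE, quote = FALSE)
  gt <- file.path(directory, "ground_truth.json")
  jsonlite::write_json(list(config = unclass(config)[
    setdiff(names(config), "traits")],
    traits = config$traits,
    phenotypes = col$phenotypes), gt, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  files <- c(files, mf, gt)
  manifest <- data.frame(file = basename(files),
                         md5 = vapply(files, function(f)
                           as.character(tools::md5sum(f)), ""),
                         stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  invisible(manifest)
}
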