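# Shared test fixtures and independent oracles.

# Simulate observations from a known 4-state HMM spec: returns a step_series
# data frame plus the true state sequence.
simulate_hmm_data <- function(spec, n, seed = 1) {
  set.seed(seed)
  A <- spec$A
  states <- integer(n)
  states[1] <- sample.int(4, 1, prob = spec$pi)
  for (t in 2:n)
    states[t] <- sample.int(4, 1, prob = A[states[t - 1], ])
  step <- rgamma(n, spec$step_shape[states], spec$step_rate[states])
  fi <- rnorm(n, spec$fi_mean[states], spec$fi_sd[states])
  dive <- rbinom(n, 1, spec$dive_p[states]) == 1
  series <- data.frame(time = seq(0, by = 300, length.out = n),
                       lon = 0, lat = 0,
                       step_km = pmax(step, 1e-3),
                       colonydist_km = 10,   # away from the colony override
                       flight_intensity = fi, dive = dive, interp = FALSE)
  class(series) <- c("step_series", "data.frame")
  list(series = series, states = states)
}

# Log emission matrix identical in definition to the package's internal one,
# recomputed here from the public spec fields.
oracle_log_emissions <- function(series, spec) {
  step <- pmax(series$step_km, 1e-3)
  le <- matrix(0, nrow(series), 4)
  for (s in 1:4)
    le[, s] <- dgamma(step, spec$step_shape[s], spec$step_rate[s],
                      log = TRUE) +
      dnorm(series$flight_intensity, spec$fi_mean[s], spec$fi_sd[s],
            log = TRUE) +
      ifelse(series$dive, log(spec$dive_p[s]), log(1 - spec$dive_p[s]))
  pmax(le, -690)
}

# Brute-force total likelihood: sum over all 4^T state paths.
oracle_total_loglik <- function(series, spec) {
  le <- oracle_log_emissions(series, spec)
  n <- nrow(le)
  paths <- as.matrix(expand.grid(rep(list(1:4), n)))
  lp <- apply(paths, 1, function(s) {
    v <- log(spec$pi[s[1]]) + le[1, s[1]]
    if (n > 1)
      for (t in 2:n)
        v <- v + log(spec$A[s[t - 1], s[t]]) + le[t, s[t]]
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# Brute-force Viterbi: the single best path by enumeration.
oracle_best_path <- function(series, spec) {
  le <- oracle_log_emissions(series, spec)
  n <- nrow(le)
  paths <- as.matrix(expand.grid(rep(list(1:4), n)))
  lp <- apply(paths, 1, function(s) {
    v <- log(spec$pi[s[1]]) + le[1, s[1]]
    if (n > 1)
      for (t in 2:n)
        v <- v + log(spec$A[s[t - 1], s[t]]) + le[t, s[t]]
    v
  })
  list(logprob = max(lp), path = paths[which.max(lp), ])
}

# A hand-built step series tracing straight out-and-back excursions along a
# bearing, at `speed_kmh`, with `colony` at the origin of the local plane.
make_excursion_series <- function(excursions, colony = c(-82, 62.95),
                                  interval = 300, speed_kmh = 60) {
  # excursions: list of (start_h, max_km, bearing_deg); colony bouts between
  total_h <- max(vapply(excursions, function(e)
    e$start_h + 2 * e$max_km / speed_kmh + 1, 0)) + 1
  tt <- seq(0, total_h * 3600, by = interval)
  d <- numeric(length(tt))            # distance from colony along bearing
  brg <- rep(0, length(tt))
  for (e in excursions) {
    t_leg <- e$max_km / speed_kmh * 3600
    rel <- tt - e$start_h * 3600
    inside <- rel >= 0 & rel <= 2 * t_leg
    prof <- ifelse(rel < t_leg, rel / 3600 * speed_kmh,
                   pmax(0, e$max_km - (rel - t_leg) / 3600 * speed_kmh))
    d[inside] <- prof[inside]
    brg[inside] <- e$bearing_deg
  }
  dest <- geosphere::destPoint(colony, brg, d * 1000, r = 6371000)
  fixes <- data.frame(time = tt, lon = dest[, 1], lat = dest[, 2],
                      flight_intensity = ifelse(d > 0, 8, 0.5))
  regularize(fixes, colony, interval = interval)
}

# One engineered dive as a data frame row compatible with detect_dives output
make_dive <- function(start_s, duration_s, depth_m, hour = NULL) {
  data.frame(start = start_s, end = start_s + duration_s,
             duration_min = duration_s / 60, max_depth_m = depth_m,
             mean_depth_m = depth_m,
             hour = if (is.null(hour))
               as.integer(floor(((start_s - 5 * 3600) %% 86400) / 3600))
             else as.integer(hour))
}

# Weighted Bernoulli log-likelihood used by the derivative-free cross-check
wll <- function(beta, X, y, w) {
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(w * (y * log(p) + (1 - y) * log(1 - p)))
}
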