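# Track regularization to a 5-min step series and a four-state hidden Markov
# activity classifier (colony, diving, flying, swimming). Forward/backward,
# Baum-Welch and Viterbi are implemented in log space throughout.

HMM_STATES <- c("colony", "diving", "flying", "swimming")

#' Regularize a GPS track onto a fixed time grid
#'
#' Positions are interpolated along the great circle between the bracketing
#' fixes at every grid time (grid anchored at the first fix). Grid points
#' whose bracketing gap exceeds `max_gap` are still filled but flagged
#' `interp = TRUE` so downstream metrics can exclude them. Step length is the
#' great-circle distance between consecutive grid positions; colony distance
#' is the great-circle distance to the colony.
#'
#' @param fixes Data frame with columns `time` (POSIXct or numeric seconds),
#'   `lon`, `lat`, and optionally `flight_intensity`.
#' @param colony Length-2 (lon, lat) of the colony.
#' @param interval Grid spacing in seconds (default 300).
#' @param max_gap Largest fix gap (s) interpolated without flagging
#'   (default 1800).
#' @return A `step_series` data frame: `time, lon, lat, step_km,
#'   colonydist_km, flight_intensity, interp` (plus `dive`, all `FALSE` until
#'   [attach_dives()] fills it).
#' @export
regularize <- function(fixes, colony, interval = 300, max_gap = 1800) {
  if (is.null(fixes) || nrow(fixes) < 2) {
    out <- data.frame(time = numeric(0), lon = numeric(0), lat = numeric(0),
                      step_km = numeric(0), colonydist_km = numeric(0),
                      flight_intensity = numeric(0), dive = logical(0),
                      interp = logical(0))
    class(out) <- c("step_series", "data.frame")
    return(out)
  }
  tt <- as.numeric(fixes$time)
  if (any(diff(tt) <= 0)) stop("fix timestamps must be strictly increasing")
  grid <- seq(tt[1], tt[length(tt)], by = interval)
  n <- length(grid)
  lon <- numeric(n); lat <- numeric(n); interp_flag <- logical(n)
  fi_in <- fixes$flight_intensity
  fi <- numeric(n)
  for (i in seq_len(n)) {
    g <- grid[i]
    j <- findInterval(g, tt)
    if (tt[j] == g) {            # exactly on a fix
      lon[i] <- fixes$lon[j]; lat[i] <- fixes$lat[j]
      if (!is.null(fi_in)) fi[i] <- fi_in[j]
      next
    }
    gap <- tt[j + 1] - tt[j]
    f <- (g - tt[j]) / gap
    p <- gc_interpolate(c(fixes$lon[j], fixes$lat[j]),
                        c(fixes$lon[j + 1], fixes$lat[j + 1]), f)
    lon[i] <- p[1, "lon"]; lat[i] <- p[1, "lat"]
    if (!is.null(fi_in)) fi[i] <- (1 - f) * fi_in[j] + f * fi_in[j + 1]
    if (gap > max_gap) interp_flag[i] <- TRUE
  }
  pos <- cbind(lon, lat)
  step <- c(0, gc_dist_km(pos[-n, , drop = FALSE], pos[-1, , drop = FALSE]))
  cdist <- gc_dist_km(matrix(colony, n, 2, byrow = TRUE), pos)
  t_out <- if (inherits(fixes$time, "POSIXct"))
    as.POSIXct(grid, origin = "1970-01-01", tz = "UTC") else grid
  out <- data.frame(time = t_out, lon = lon, lat = lat, step_km = step,
                    colonydist_km = cdist, flight_intensity = fi,
                    dive = FALSE, interp = interp_flag)
  class(out) <- c("step_series", "data.frame")
  out
}

#' Mark steps during which a dive occurred
#'
#' @param series A [regularize()] output.
#' @param dives A [detect_dives()] output.
#' @param interval Step width in seconds.
#' @return The series with its `dive` column filled.
#' @export
attach_dives <- function(series, dives, interval = 300) {
  if (is.null(dives) || nrow(dives) == 0) return(series)
  tt <- as.numeric(series$time)
  for (k in seq_len(nrow(dives))) {
    s <- as.numeric(dives$start[k]); e <- as.numeric(dives$end[k])
    series$dive <- series$dive | (tt + interval > s & tt <= e)
  }
  series
}

#' Construct (or default) the four-state HMM specification
#'
#' States are ordered colony, diving, flying, swimming. Emissions per state:
#' step length ~ Gamma, flight intensity ~ Normal, dive indicator ~
#' Bernoulli. The default starting values encode the obvious physical
#' separation (near-zero steps at the colony, ~4 km five-minute steps in
#' flight, high wing-beat intensity in flight, dive probability 0.95 in the
#' diving state and <= 0.05 elsewhere); they are starting values for
#' [fit_hmm()], not constants.
#'
#' @param pi0 Initial state distribution (length 4, sums to 1).
#' @param A 4x4 row-stochastic transition matrix.
#' @param step_mean,step_sd Per-state mean and SD of step length (km).
#' @param fi_mean,fi_sd Per-state Normal parameters of flight intensity.
#' @param dive_p Per-state Bernoulli probability of a dive in the step.
#' @return Object of class `hmm_spec`.
#' @export
hmm_spec <- function(pi0 = c(0.7, 0.05, 0.15, 0.1),
                     A = NULL,
                     step_mean = c(0.02, 0.3, 4.0, 0.2),
                     step_sd = c(0.02, 0.2, 1.5, 0.15),
                     fi_mean = c(0.5, 2.0, 8.0, 1.2),
                     fi_sd = c(0.3, 1.0, 1.0, 0.6),
                     dive_p = c(0.01, 0.95, 0.02, 0.05)) {
  if (is.null(A)) {
    A <- matrix(0.04, 4, 4)
    diag(A) <- 0.88
  }
  shape <- (step_mean / step_sd)^2
  rate <- shape / step_mean
  spec <- list(states = HMM_STATES, pi = pi0 / sum(pi0),
               A = A / rowSums(A),
               step_shape = shape, step_rate = rate,
               fi_mean = fi_mean, fi_sd = fi_sd, dive_p = dive_p)
  validate_hmm_spec(spec)
  structure(spec, class = "hmm_spec")
}

validate_hmm_spec <- function(spec) {
  stopifnot(length(spec$pi) == 4, nrow(spec$A) == 4, ncol(spec$A) == 4)
  if (abs(sum(spec$pi) - 1) > 1e-10) stop("pi must sum to 1")
  if (any(abs(rowSums(spec$A) - 1) > 1e-10))
    stop("transition matrix rows must sum to 1")
  if (any(spec$step_shape <= 0) || any(spec$step_rate <= 0))
    stop("Gamma parameters must be > 0")
  if (any(spec$dive_p < 0) || any(spec$dive_p > 1))
    stop("Bernoulli p must be in [0, 1]")
  invisible(spec)
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat("4-state activity HMM (colony, diving, flying, swimming)\n")
  cat("Transition matrix:\n")
  print(round(x$A, 3))
  em <- data.frame(state = x$states,
                   step_mean_km = round(x$step_shape / x$step_rate, 3),
                   fi_mean = x$fi_mean, dive_p = x$dive_p)
  print(em, row.names = FALSE)
  invisible(x)
}

# Per-step log emission density matrix (T x 4). Step lengths are floored at
# 1 m to keep the Gamma density finite at stationary fixes; densities are
# floored at exp(-690) so no observation has zero likelihood under all states.
.log_emissions <- function(series, spec) {
  step <- pmax(series$step_km, 1e-3)
  fi <- series$flight_intensity
  dv <- as.numeric(series$dive)
  n <- nrow(series)
  le <- matrix(0, n, 4)
  for (s in 1:4) {
    le[, s] <- stats::dgamma(step, spec$step_shape[s], spec$step_rate[s],
                             log = TRUE) +
      stats::dnorm(fi, spec$fi_mean[s], spec$fi_sd[s], log = TRUE) +
      dv * log(max(spec$dive_p[s], 1e-12)) +
      (1 - dv) * log(max(1 - spec$dive_p[s], 1e-12))
  }
  pmax(le, -690)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Log-space forward pass (per-step max shift keeps it exact under long
# sequences). Returns list(logalpha, loglik).
.forward <- function(le, logpi, logA) {
  n <- nrow(le)
  A <- exp(logA)
  la <- matrix(-Inf, n, 4)
  la[1, ] <- logpi + le[1, ]
  for (t in seq_len(n)[-1]) {
    v <- la[t - 1, ]
    m <- max(v)
    la[t, ] <- m + log(as.vector(crossprod(exp(v - m), A))) + le[t, ]
  }
  list(logalpha = la, loglik = .logsumexp(la[n, ]))
}

.backward <- function(le, logA) {
  n <- nrow(le)
  A <- exp(logA)
  lb <- matrix(0, n, 4)
  for (t in rev(seq_len(n - 1))) {
    v <- le[t + 1, ] + lb[t + 1, ]
    m <- max(v)
    lb[t, ] <- m + log(as.vector(A %*% exp(v - m)))
  }
  lb
}

# Weighted Gamma MLE via Newton iterations on the shape parameter.
.gamma_wmle <- function(x, w) {
  w <- w / sum(w)
  mx <- sum(w * x)
  mlx <- sum(w * log(x))
  s <- log(mx) - mlx
  if (s < 1e-10) s <- 1e-10
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in 1:25) {
    g <- log(shape) - digamma(shape) - s
    h <- 1 / shape - trigamma(shape)
    delta <- g / h
    shape_new <- shape - delta
    if (shape_new <= 0) shape_new <- shape / 2
    if (abs(shape_new - shape) < 1e-10 * shape) { shape <- shape_new; break }
    shape <- shape_new
  }
  shape <- min(max(shape, 1e-3), 1e6)
  c(shape = shape, rate = shape / mx)
}

#' Fit the activity HMM by Baum-Welch EM
#'
#' Multiple step series are treated as independent sequences sharing one
#' parameter set. The expected complete-data log-likelihood is maximized
#' exactly in each M step (closed forms for the Normal and Bernoulli
#' emissions and the transition matrix; Newton iterations for the Gamma
#' shape), so the observed log-likelihood is non-decreasing across
#' iterations. A state whose total posterior responsibility falls below 1e-6
#' keeps its current parameters (degenerate one-state data then converge
#' with a near-absorbing row instead of dividing by zero); if the
#' log-likelihood itself degenerates the fit restarts from a jittered
#' initialization, at most five times, then fails loudly.
#'
#' @param series_list A `step_series` or list of them.
#' @param spec0 Starting [hmm_spec()] (default [hmm_spec()]).
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Relative log-likelihood change declaring convergence
#'   (default 1e-6).
#' @return Object of class `hmm_fit`: the fitted `spec`, the log-likelihood
#'   trace `ll_trace`, `converged`, `iterations`, `restarts`.
#' @export
fit_hmm <- function(series_list, spec0 = hmm_spec(), max_iter = 100,
                    tol = 1e-6) {
  if (inherits(series_list, "data.frame")) series_list <- list(series_list)
  series_list <- Filter(function(s) nrow(s) > 1, series_list)
  if (!length(series_list)) stop("no usable step series")
  validate_hmm_spec(spec0)

  run_em <- function(spec) {
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (iter in seq_len(max_iter)) {
      logpi <- log(spec$pi); logA <- log(spec$A)
      # accumulators
      pi_acc <- numeric(4)
      xi_acc <- matrix(0, 4, 4)
      g_list <- list()
      ll <- 0
      for (q in seq_along(series_list)) {
        le <- .log_emissions(series_list[[q]], spec)
        fw <- .forward(le, logpi, logA)
        lb <- .backward(le, logA)
        lg <- fw$logalpha + lb - fw$loglik
        gamma <- exp(lg)
        n <- nrow(le)
        pi_acc <- pi_acc + gamma[1, ]
        A <- exp(logA)
        for (t in seq_len(n - 1)) {
          u <- fw$logalpha[t, ]; v <- le[t + 1, ] + lb[t + 1, ]
          mu <- max(u); mv <- max(v)
          xi_acc <- xi_acc + A * outer(exp(u - mu), exp(v - mv)) *
            exp(mu + mv - fw$loglik)
        }
        g_list[[q]] <- gamma
        ll <- ll + fw$loglik
      }
      ll_trace <- c(ll_trace, ll)
      if (!is.finite(ll))
        return(list(starved = TRUE, ll_trace = ll_trace, spec = spec))
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * max(1, abs(ll_old))) {
        return(list(starved = FALSE, spec = spec, ll_trace = ll_trace,
                    converged = TRUE, iterations = iter))
      }
      ll_old <- ll
      # M step; a state with negligible responsibility ("starved") keeps its
      # current parameters and transition row so degenerate one-state data
      # still converge instead of producing 0/0
      spec$pi <- pi_acc / sum(pi_acc)
      rs <- rowSums(xi_acc)
      for (s in 1:4)
        if (rs[s] > 1e-12) spec$A[s, ] <- xi_acc[s, ] / rs[s]
      allg <- do.call(rbind, g_list)
      step <- pmax(unlist(lapply(series_list, `[[`, "step_km")), 1e-3)
      fi <- unlist(lapply(series_list, `[[`, "flight_intensity"))
      dv <- as.numeric(unlist(lapply(series_list, `[[`, "dive")))
      for (s in 1:4) {
        w <- allg[, s]
        if (sum(w) < 1e-6) next
        gp <- .gamma_wmle(step, w)
        spec$step_shape[s] <- gp["shape"]
        spec$step_rate[s] <- gp["rate"]
        mu <- sum(w * fi) / sum(w)
        sd <- sqrt(sum(w * (fi - mu)^2) / sum(w))
        spec$fi_mean[s] <- mu
        spec$fi_sd[s] <- max(sd, 1e-3)
        spec$dive_p[s] <- min(max(sum(w * dv) / sum(w), 1e-6), 1 - 1e-6)
      }
    }
    list(starved = FALSE, spec = spec, ll_trace = ll_trace,
         converged = FALSE, iterations = max_iter)
  }

  spec <- spec0
  for (attempt in 0:5) {
    res <- run_em(spec)
    if (!res$starved) {
      return(structure(list(spec = structure(res$spec, class = "hmm_spec"),
                            ll_trace = res$ll_trace,
                            loglik = res$ll_trace[length(res$ll_trace)],
                            converged = res$converged,
                            iterations = res$iterations,
                            restarts = attempt), class = "hmm_fit"))
    }
    if (attempt == 5) stop("EM degenerate: a state starved in all restarts")
    # jitter the starting values and try again
    spec <- spec0
    spec$step_shape <- spec$step_shape * exp(stats::rnorm(4, 0, 0.2))
    spec$step_rate <- spec$step_rate * exp(stats::rnorm(4, 0, 0.2))
    spec$fi_mean <- spec$fi_mean + stats::rnorm(4, 0, 0.3)
  }
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Baum-Welch fit:", x$iterations, "iterations;",
      if (x$converged) "converged" else "max_iter reached",
      sprintf("(logLik %.2f, %d restart(s))\n", x$loglik, x$restarts))
  print(x$spec)
  invisible(x)
}

#' Decode a step series under a fitted HMM
#'
#' Computes the Viterbi path (global MAP state sequence; ties broken toward
#' the lower state index) and forward-backward posterior state
#' probabilities.
#'
#' @param series A `step_series`.
#' @param spec A fitted [hmm_spec()] (or the `spec` element of an `hmm_fit`).
#' @return Object of class `state_path`: `states` (factor of labels),
#'   `posterior` (T x 4 matrix), `loglik`, `viterbi_logprob`.
#' @export
decode <- function(series, spec) {
  if (inherits(spec, "hmm_fit")) spec <- spec$spec
  validate_hmm_spec(spec)
  le <- .log_emissions(series, spec)
  n <- nrow(le)
  logpi <- log(spec$pi); logA <- log(spec$A)
  # Viterbi
  delta <- matrix(-Inf, n, 4)
  psi <- matrix(1L, n, 4)
  delta[1, ] <- logpi + le[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (s in 1:4) {
        cand <- delta[t - 1, ] + logA[, s]
        psi[t, s] <- which.max(cand)   # first max = lowest index on ties
        delta[t, s] <- cand[psi[t, s]] + le[t, s]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  # forward-backward
  fw <- .forward(le, logpi, logA)
  lb <- .backward(le, logA)
  post <- exp(fw$logalpha + lb - fw$loglik)
  post <- post / rowSums(post)
  structure(list(states = factor(HMM_STATES[path], levels = HMM_STATES),
                 state_index = path,
                 posterior = post,
                 loglik = fw$loglik,
                 viterbi_logprob = max(delta[n, ])), class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat("Decoded state path,", length(x$states), "steps; logLik",
      sprintf("%.2f\n", x$loglik))
  print(table(x$states))
  invisible(x)
}

#' Classify a deployment's activities
#'
#' Regularizes, attaches dives, decodes under the spec, then applies the
#' colony override: steps within 1 km of the colony with no dive are forced
#' to the colony state (the splashdown filter, applied after decoding).
#'
#' @param series A `step_series` with its `dive` column filled.
#' @param spec An [hmm_spec()] or `hmm_fit`.
#' @param colony_radius_km Radius of the colony override (default 1).
#' @return A `state_path` whose `states` include the override.
#' @export
classify_steps <- function(series, spec, colony_radius_km = 1) {
  sp <- decode(series, spec)
  force_colony <- series$colonydist_km < colony_radius_km & !series$dive
  sp$states[force_colony] <- "colony"
  sp$state_index[force_colony] <- 1L
  sp
}
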