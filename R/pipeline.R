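# Configuration, file readers/writers and the end-to-end pipeline:
# regularize -> classify -> dives/trips -> metrics -> UD/overlap ->
# pair table -> model selection -> permutation inference.

#' Pipeline configuration
#'
#' Collects every stage parameter with the standard defaults: 1 km colony
#' filter, 20 min minimum trip duration, 5 min step interval, 200 m grid,
#' 2720 m smoothing bandwidth, collinearity threshold 0.8 and a log(1 + x)
#' overlap transform.
#'
#' @param colony_lonlat Colony (lon, lat) degrees.
#' @param step_interval_s HMM step interval in seconds (default 300).
#' @param max_gap_s Interpolation flagging threshold (default 1800).
#' @param dive_min_depth_m,dive_min_duration_s Dive detection knobs.
#' @param trip_min_dist_km,trip_min_duration_min Trip filter knobs.
#' @param ud_bandwidth_m Common kernel bandwidth; `NULL` means the mean of
#'   per-bird reference bandwidths (default 2720).
#' @param ud_cell_m Grid cell size in metres (default 200).
#' @param ba_level Contour level for the overlap (default 0.5).
#' @param collinearity_threshold Absolute correlation cut (default 0.8).
#' @param traits Trait columns differenced into the pair table; `NULL` uses
#'   the full deployment metric set.
#' @param standardize Traits z-scored after differencing.
#' @param weight_real Pair-table weighting rule (see [build_pair_table()]).
#' @param n_perm Permutations for the matching test (default 999).
#' @param fit_hmm_first Refit the HMM by EM before decoding (default TRUE);
#'   otherwise decode under the starting spec.
#' @param hmm_max_iter EM iteration cap (default 30).
#' @param tz_offset_hours Colony local time minus UTC (default -5).
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Optional directory for stage CSV artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(colony_lonlat = c(-82.019, 62.948),
                            step_interval_s = 300,
                            max_gap_s = 1800,
                            dive_min_depth_m = 1.0,
                            dive_min_duration_s = 3,
                            trip_min_dist_km = 1,
                            trip_min_duration_min = 20,
                            ud_bandwidth_m = 2720,
                            ud_cell_m = 200,
                            ba_level = 0.5,
                            collinearity_threshold = 0.8,
                            traits = NULL,
                            standardize = c("max_dist_km", "total_dist_km",
                                            "mean_trip_dist_km", "wing_mm"),
                            weight_real = "balanced",
                            n_perm = 999,
                            fit_hmm_first = TRUE,
                            hmm_max_iter = 30,
                            tz_offset_hours = -5,
                            seed = 1L) {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, TRUE)
  if (any(vapply(cfg[num], function(v) any(!is.finite(v)), TRUE)))
    stop("non-finite numeric value in pipeline configuration")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  trip filter: > %g km, > %g min, >= 1 dive\n",
              x$trip_min_dist_km, x$trip_min_duration_min))
  cat(sprintf("  steps %gs; dive threshold %g m / %g s\n",
              x$step_interval_s, x$dive_min_depth_m, x$dive_min_duration_s))
  cat(sprintf("  UD: h = %s m, cells %g m, overlap level %g\n",
              if (is.null(x$ud_bandwidth_m)) "href mean" else
                x$ud_bandwidth_m, x$ud_cell_m, x$ba_level))
  cat(sprintf("  n_perm = %d, seed = %d\n", x$n_perm, x$seed))
  invisible(x)
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the reconstructed `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[names(raw) %in%
                                 names(formals(pipeline_config))])
}

#' Read a fixture set written by [write_fixture_set()]
#'
#' @param directory Directory holding `track_*.csv`, `depth_*.csv` and
#'   `metadata.csv`.
#' @return List of `deployment` objects.
#' @export
read_fixture_set <- function(directory) {
  md <- utils::read.csv(file.path(directory, "metadata.csv"),
                        stringsAsFactors = FALSE)
  deps <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    b <- md$bird_id[i]
    tr <- utils::read.csv(file.path(directory, paste0("track_", b, ".csv")),
                          stringsAsFactors = FALSE)
    dp <- utils::read.csv(file.path(directory, paste0("depth_", b, ".csv")),
                          stringsAsFactors = FALSE)
    fixes <- data.frame(
      time = as.POSIXct(tr$timestamp_iso8601, format = "%Y-%m-%dT%H:%M:%OSZ",
                        tz = "UTC"),
      lon = tr$lon, lat = tr$lat)
    fixes$flight_intensity <- if ("flight_intensity" %in% names(tr))
      tr$flight_intensity else 0
    deps[[i]] <- structure(list(
      bird_id = b, sex = md$sex[i], year = as.character(md$year[i]),
      pair_id = md$pair_id[i],
      fixes = fixes,
      depths = data.frame(
        time = as.numeric(as.POSIXct(dp$timestamp_iso8601,
                                     format = "%Y-%m-%dT%H:%M:%OSZ",
                                     tz = "UTC")),
        depth_m = dp$depth_m),
      morph = list(wing_mm = md$wing_mm[i], headbill_mm = md$headbill_mm[i],
                   mass_pre_g = md$mass_pre_g[i],
                   mass_post_g = md$mass_post_g[i]),
      truth = NULL), class = "deployment")
  }
  names(deps) <- md$bird_id
  deps
}

#' Process one deployment through the track stages
#'
#' Regularize, detect dives, attach them to the step series, decode
#' activities and segment trips.
#'
#' @param dep A `deployment`.
#' @param config A [pipeline_config()].
#' @param spec A fitted or starting [hmm_spec()].
#' @return List: `series`, `dives`, `states`, `trips`.
#' @export
process_deployment <- function(dep, config, spec = hmm_spec()) {
  series <- regularize(dep$fixes, config$colony_lonlat,
                       interval = config$step_interval_s,
                       max_gap = config$max_gap_s)
  dives <- detect_dives(dep$depths, config$dive_min_depth_m,
                        config$dive_min_duration_s,
                        config$tz_offset_hours)
  series <- attach_dives(series, dives, config$step_interval_s)
  states <- classify_steps(series, spec, config$trip_min_dist_km)
  trips <- segment_trips(series, dives, config$colony_lonlat,
                         config$trip_min_dist_km,
                         config$trip_min_duration_min,
                         config$step_interval_s)
  list(series = series, dives = dives, states = states, trips = trips)
}

#' Run the full analysis on a set of deployments
#'
#' Stages, in order: regularization of every track; one HMM fit pooled over
#' all birds (optional) and decoding with the colony override; dive
#' detection and trip segmentation; per-bird deployment metrics with
#' year-level hourly depth means; per-bird kernel UDs on trip fixes with a
#' common bandwidth and pairwise core-area overlap; the cross-pair table;
#' AICc model selection over single-covariate weighted logistic models,
#' grouped into foraging, diving, morphometric and overlap candidates; and
#' matching-permutation tests for the headline traits.
#'
#' @param deployments List of `deployment` objects ([simulate_colony()]
#'   output element, or [read_fixture_set()]).
#' @param config A [pipeline_config()].
#' @param stages Character vector of stage names to run (a prefix of
#'   `c("classify", "trips", "metrics", "spaceuse", "pairs", "models")`).
#' @return List of stage results (named as the stages), plus `metrics`,
#'   `pair_table` and `hmm`.
#' @export
analyze_colony <- function(deployments, config = pipeline_config(),
                           stages = c("classify", "trips", "metrics",
                                      "spaceuse", "pairs", "models")) {
  set.seed(config$seed)
  res <- list(config = config)
  # classify
  series_list <- lapply(deployments, function(d)
    regularize(d$fixes, config$colony_lonlat, config$step_interval_s,
               config$max_gap_s))
  dives_list <- lapply(deployments, function(d)
    detect_dives(d$depths, config$dive_min_depth_m,
                 config$dive_min_duration_s, config$tz_offset_hours))
  series_list <- Map(attach_dives, series_list, dives_list,
                     MoreArgs = list(interval = config$step_interval_s))
  spec <- hmm_spec()
  if (config$fit_hmm_first) {
    fit <- fit_hmm(series_list, spec, max_iter = config$hmm_max_iter)
    spec <- fit$spec
    res$hmm <- fit
  } else res$hmm <- spec
  states_list <- lapply(series_list, classify_steps, spec = spec,
                        colony_radius_km = config$trip_min_dist_km)
  res$classify <- list(series = series_list, states = states_list)
  if (!"trips" %in% stages) return(res)

  trips_list <- lapply(seq_along(deployments), function(i)
    segment_trips(series_list[[i]], dives_list[[i]], config$colony_lonlat,
                  config$trip_min_dist_km, config$trip_min_duration_min,
                  config$step_interval_s))
  names(trips_list) <- names(deployments)
  res$trips <- trips_list
  res$dives <- dives_list
  if (!"metrics" %in% stages) return(res)

  # year-level hourly depth means (population-wide within year)
  years <- vapply(deployments, function(d) d$year, "")
  hourly_by_year <- lapply(split(dives_list, years), function(dl) {
    all <- do.call(rbind, dl)
    if (nrow(all)) hourly_mean_depth(all) else rep(NA_real_, 24)
  })
  met_rows <- list()
  excluded <- character(0)
  for (i in seq_along(deployments)) {
    d <- deployments[[i]]
    if (nrow(trips_list[[i]]) == 0) { excluded <- c(excluded, d$bird_id); next }
    span_h <- diff(range(as.numeric(d$fixes$time))) / 3600
    m <- deployment_summary(trips_list[[i]], dives_list[[i]],
                            states_list[[i]], span_h,
                            hourly = hourly_by_year[[d$year]])
    met_rows[[length(met_rows) + 1]] <-
      cbind(data.frame(bird_id = d$bird_id, sex = d$sex, year = d$year,
                       pair_id = d$pair_id, wing_mm = d$morph$wing_mm,
                       headbill_mm = d$morph$headbill_mm,
                       mass_pre_g = d$morph$mass_pre_g,
                       mass_post_g = d$morph$mass_post_g,
                       stringsAsFactors = FALSE), m)
  }
  if (length(excluded))
    message("excluded (no kept trips): ", paste(excluded, collapse = ", "))
  metrics <- do.call(rbind, met_rows)
  rownames(metrics) <- NULL
  res$metrics <- metrics
  if (!"spaceuse" %in% stages) return(res)

  # per-bird UD on trip fixes, common bandwidth, core-area overlap
  uds <- list(); hrefs <- numeric(0)
  for (i in seq_along(deployments)) {
    tr <- trips_list[[i]]
    if (nrow(tr) == 0) next
    idx <- unlist(lapply(seq_len(nrow(tr)), function(k)
      tr$first_idx[k]:tr$last_idx[k]))
    s <- series_list[[i]]
    xy <- project_aeqd(cbind(s$lon[idx], s$lat[idx]), config$colony_lonlat)
    uds[[deployments[[i]]$bird_id]] <- xy
    if (nrow(xy) >= 5 && (stats::sd(xy[, 1]) + stats::sd(xy[, 2])) > 0)
      hrefs <- c(hrefs, href_bandwidth(xy))
  }
  h <- if (!is.null(config$ud_bandwidth_m)) config$ud_bandwidth_m
  else mean(hrefs)
  ud_grids <- lapply(uds, kernel_ud, h = h, cell_size = config$ud_cell_m)
  ba_rows <- list()
  if (!is.null(metrics)) {
    for (yr in unique(metrics$year)) {
      fem <- metrics$bird_id[metrics$year == yr & metrics$sex == "F"]
      mal <- metrics$bird_id[metrics$year == yr & metrics$sex == "M"]
      for (f in intersect(fem, names(ud_grids)))
        for (m in intersect(mal, names(ud_grids)))
          ba_rows[[length(ba_rows) + 1]] <-
            data.frame(female_id = f, male_id = m,
                       ba = bhattacharyya_overlap(ud_grids[[f]],
                                                  ud_grids[[m]],
                                                  level = config$ba_level))
    }
  }
  ba <- if (length(ba_rows)) do.call(rbind, ba_rows) else NULL
  res$spaceuse <- list(h = h, hrefs = hrefs, ud = ud_grids, ba = ba)
  if (!"pairs" %in% stages) return(res)

  traits <- config$traits
  if (is.null(traits))
    traits <- c("max_dist_km", "total_dist_km", "mean_trip_dist_km",
                "trip_duration_h", "azimuth_mean_deg", "daily_dist_km",
                "trips_per_day", "dives_per_day", "mean_dive_depth_m",
                "mean_dive_duration_min", "mean_diff_depth_m",
                "total_dive_duration_h", "wing_mm", "headbill_mm",
                "mass_pre_g")
  traits <- intersect(traits, names(metrics))
  pt <- build_pair_table(metrics, traits,
                         standardize = intersect(config$standardize, traits),
                         ba = ba, weight_real = config$weight_real)
  res$pair_table <- pt
  if (!"models" %in% stages) return(res)

  res$models <- fit_pair_models(pt, traits, config)
  res
}

#' Model selection and permutation inference on a pair table
#'
#' Fits, per candidate group (foraging, diving, morphometrics and — when an
#' overlap column is present — overlap), a null intercept-only weighted
#' logistic model and one single-covariate model per retained trait, ranks
#' them by AICc, and runs the matching-permutation test on each group's best
#' non-null trait.
#'
#' @param pair_table A [build_pair_table()] output.
#' @param traits Trait names present in the table.
#' @param config A [pipeline_config()].
#' @return List with `selection` (per-group AICc tables), `fits`,
#'   `collinearity`, `permutation`.
#' @export
fit_pair_models <- function(pair_table, traits, config = pipeline_config()) {
  dcols <- paste0("d_", intersect(traits, sub("^d_", "",
                                              names(pair_table))))
  dcols <- intersect(dcols, names(pair_table))
  cf <- collinearity_filter(pair_table[, dcols, drop = FALSE],
                            config$collinearity_threshold)
  retained <- sub("^d_", "", cf$retained)
  groups <- list(
    foraging = intersect(retained, c("max_dist_km", "total_dist_km",
                                     "mean_trip_dist_km", "trip_duration_h",
                                     "azimuth_mean_deg", "daily_dist_km",
                                     "trips_per_day", "mean_trip_distance",
                                     "preferred_azimuth")),
    diving = intersect(retained, c("dives_per_day", "mean_dive_depth_m",
                                   "mean_dive_duration_min",
                                   "mean_diff_depth_m",
                                   "total_dive_duration_h",
                                   "mean_dive_depth")),
    morphometrics = intersect(retained, c("wing_mm", "headbill_mm",
                                          "mass_pre_g", "wing_length",
                                          "head_bill", "body_mass")))
  if ("log1p_BA" %in% names(pair_table)) groups$overlap <- "log1p_BA"
  y <- pair_table$is_real
  w <- pair_table$weight
  sel <- list(); fits <- list(); perms <- list()
  for (g in names(groups)) {
    cand <- list()
    cand[["null"]] <- fit_weighted_logistic(
      matrix(1, nrow(pair_table), 1, dimnames = list(NULL, "(Intercept)")),
      y, w)
    for (tr in groups[[g]]) {
      cn <- if (tr == "log1p_BA") tr else paste0("d_", tr)
      X <- cbind("(Intercept)" = 1, pair_table[[cn]])
      colnames(X)[2] <- cn
      cand[[tr]] <- tryCatch(fit_weighted_logistic(X, y, w),
                             error = function(e) NULL)
    }
    cand <- Filter(Negate(is.null), cand)
    sel[[g]] <- aicc_rank(cand)
    fits[[g]] <- cand
    best <- sel[[g]]$model[sel[[g]]$model != "null"][1]
    if (!is.na(best) && best != "log1p_BA")
      perms[[g]] <- tryCatch(
        c(list(trait = best),
          matching_permutation_test(pair_table, best,
                                    n_perm = config$n_perm,
                                    seed = config$seed)),
        error = function(e) {
          message("permutation test skipped for ", g, ": ",
                  conditionMessage(e))
          list(trait = best, statistic = NA_real_, p_value = NA_real_,
               skipped = conditionMessage(e))
        })
  }
  list(selection = sel, fits = fits, collinearity = cf, permutation = perms)
}

#' Run the pipeline end to end and write stage artifacts
#'
#' Simulates a colony when `deployments` is `NULL` (using `sim`), analyzes
#' it, and — if `config$out_dir` is set — writes per-stage CSVs (step
#' series, trips, dives, bird metrics, pair table, model-selection tables)
#' plus a JSON results bundle. Deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @param deployments Optional list of `deployment` objects.
#' @param sim A [sim_config()] used when simulating (default scaled-down
#'   demo colony).
#' @param out_dir Optional output directory (overrides `config$out_dir`).
#' @return The [analyze_colony()] results list.
#' @export
run_pipeline <- function(config = pipeline_config(), deployments = NULL,
                         sim = NULL, out_dir = NULL) {
  if (is.null(deployments)) {
    if (is.null(sim))
      sim <- sim_config(n_pairs_per_year = c("2022" = 3, "2023" = 3),
                        deployment_hours = 24, seed = config$seed)
    colony <- simulate_colony(sim)
    deployments <- colony$deployments
  }
  res <- analyze_colony(deployments, config)
  out_dir <- out_dir %||% config$out_dir
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                            row.names = FALSE)
    if (!is.null(res$metrics)) wcsv(res$metrics, "bird_metrics.csv")
    if (!is.null(res$pair_table)) wcsv(as.data.frame(res$pair_table),
                                       "pair_table.csv")
    if (!is.null(res$trips))
      wcsv(do.call(rbind, Map(cbind, bird_id = names(res$trips),
                              res$trips)), "trips.csv")
    if (!is.null(res$dives))
      wcsv(do.call(rbind, Map(function(b, d)
        if (nrow(d)) cbind(bird_id = b, d) else NULL,
        names(res$dives), res$dives)), "dives.csv")
    if (!is.null(res$models))
      for (g in names(res$models$selection))
        wcsv(res$models$selection[[g]], paste0("model_selection_", g,
                                               ".csv"))
    bundle <- list(
      seed = config$seed,
      n_birds = length(deployments),
      pair_rows = if (!is.null(res$pair_table)) nrow(res$pair_table) else 0,
      selection = res$models$selection,
      permutation = lapply(res$models$permutation, function(p)
        p[c("trait", "statistic", "p_value", "n_perm")]))
    jsonlite::write_json(bundle, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  res
}
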