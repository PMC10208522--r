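#' Default run configuration
#'
#' All parameter blocks of a simulation experiment — track, speed profile,
#' speed noise, input features, network, analysis settings and batch settings
#' — with the model's reference values. The returned list serializes
#' losslessly to YAML via [save_config()].
#'
#' @param master_seed Master seed; per-run and per-stream seeds are derived
#'   from it deterministically.
#' @param n_runs Number of independent simulation runs pooled by the
#'   analyses.
#' @param n_laps Laps per run (30 default; 45 for the instantaneous-speed
#'   analysis).
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(master_seed = 1, n_runs = 10, n_laps = 30) {
  structure(list(
    track = list(length = 200, bin_size_features = 1, n_laps = n_laps,
                 dt = 0.001),
    profile = list(v_end = 15, v_mid = 80),
    noise = list(kernel_std = 2, lo = 0.5, hi = 1.5, center = 1),
    features = list(n_features = 128, std_min = 2, std_max = 20),
    network = unclass(network_params()),
    theta_freq = 8,
    analysis = list(warmup = 80, map_bin = 2, smoothing_sd = 3,
                    phase_bin = 20, peak_min = 0.2, density_window = 10,
                    density_stride = 2, speed_quantile = 0.2,
                    act_min = 0.1, do_decode = TRUE, do_ratios = FALSE),
    master_seed = master_seed,
    n_runs = n_runs
  ), class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' @param config A [default_config()]-style list.
#' @param path File path.
#' @return `save_config` returns `path` invisibly; `load_config` returns the
#'   configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

config_objects <- function(config) {
  list(
    track = track_spec(config$track$length, config$track$bin_size_features,
                       config$track$n_laps, config$track$dt),
    profile = speed_profile(config$profile$v_end, config$profile$v_mid),
    noise = speed_noise_spec(config$noise$kernel_std, config$noise$lo,
                             config$noise$hi, config$noise$center),
    params = do.call(network_params, config$network)
  )
}

#' Simulate and analyze a single run
#'
#' Generates the trajectory and feature bank from run-specific seeds,
#' integrates the network, and computes the full analysis suite: measured and
#' true activation maps, place fields, field shifts, phase-precession
#' slopes, field density, and (optionally) population decoding with
#' per-theta-cycle sweep metrics and instantaneous-speed invariance ratios.
#'
#' @param config A [default_config()]-style configuration.
#' @param run_seed Integer seed for this run (features and speed noise use
#'   independent streams derived from it).
#' @param keep_run If `TRUE`, the (large) `network_run` object is included in
#'   the result.
#' @return A list of tidy tables: `fields`, `true_fields`, `shifts`,
#'   `slopes`, `density`, and when enabled `sweeps`, `ratios`; plus `n_steps`
#'   and `duration_s`.
#' @export
analyze_run <- function(config, run_seed, keep_run = FALSE) {
  obj <- config_objects(config)
  an <- config$analysis
  traj <- simulate_trajectory(obj$track, obj$profile, obj$noise,
                              config$theta_freq,
                              seed = derive_seed(run_seed, 1))
  bank <- generate_features(obj$track, config$features$n_features,
                            c(config$features$std_min, config$features$std_max),
                            seed = derive_seed(run_seed, 2))
  run <- run_simulation(traj, bank, obj$params)

  amap <- activation_map(run, "measured", an$map_bin, an$smoothing_sd,
                         an$warmup)
  tmap <- activation_map(run, "true", an$map_bin, an$smoothing_sd, an$warmup)
  fields <- extract_fields(amap, an$peak_min)
  true_fields <- extract_fields(tmap, 0)
  true_fields <- true_fields[true_fields$unit %in% fields$unit, ]
  shifts <- field_shifts(fields, true_fields, traj, an$warmup)
  pmap <- phase_map(run, an$map_bin, an$phase_bin, an$warmup)
  slopes <- phase_precession_slopes(pmap, fields)
  cf <- fields[fields$complete, ]
  cf$mean_speed <- field_mean_speeds(cf, traj, an$warmup)
  slopes <- merge(slopes, cf[, c("unit", "size", "mean_speed")], by = "unit")
  density <- field_density(fields, obj$profile, obj$track,
                           an$density_window, an$density_stride)
  out <- list(fields = cf, true_fields = true_fields, shifts = shifts,
              slopes = slopes, density = density,
              n_steps = nrow(traj), duration_s = max(traj$t))
  if (isTRUE(an$do_decode)) {
    dec <- decode_positions(run, amap, an$act_min, an$warmup)
    sweeps <- sweep_metrics(dec)
    out$sweeps <- sweep_speeds(sweeps, obj$profile, obj$track)
  }
  if (isTRUE(an$do_ratios)) {
    out$ratios <- instantaneous_speed_ratios(run, an$speed_quantile,
                                             an$warmup, an$map_bin,
                                             an$smoothing_sd, an$map_bin,
                                             an$phase_bin)
  }
  if (keep_run) out$run <- run
  out
}

#' Run a multi-run experiment and write its artifacts
#'
#' Runs `config$n_runs` independent simulations (per-run seeds derived from
#' the master seed), writes per-run and pooled analysis tables as CSV to
#' `outdir`, plus a JSON manifest with the configuration and per-run summary.
#' Pooled figures in the accompanying analyses are computed from the pooled
#' tables.
#'
#' @param config A [default_config()]-style configuration.
#' @param outdir Output directory (created if missing). `NULL` skips writing
#'   and returns the tables only.
#' @param verbose Print per-run progress.
#' @return Invisibly, a list with `pooled` (named list of pooled tables,
#'   each with a `run` column) and `per_run` summaries.
#' @export
run_experiment <- function(config = default_config(), outdir = NULL,
                           verbose = interactive()) {
  n_runs <- config$n_runs
  table_names <- c("fields", "true_fields", "shifts", "slopes", "density",
                   "sweeps", "ratios")
  pooled <- stats::setNames(vector("list", length(table_names)), table_names)
  per_run <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    seed_k <- derive_seed(config$master_seed, k)
    res <- tryCatch(analyze_run(config, seed_k), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("run %d failed: %s", k, conditionMessage(res)))
      per_run[[k]] <- list(run = k, seed = seed_k, failed = TRUE,
                           message = conditionMessage(res))
      next
    }
    for (nm in table_names) {
      if (!is.null(res[[nm]]) && nrow(res[[nm]]) > 0) {
        pooled[[nm]] <- rbind(pooled[[nm]], cbind(run = k, res[[nm]]))
      }
    }
    per_run[[k]] <- list(run = k, seed = seed_k, failed = FALSE,
                         n_steps = res$n_steps, duration_s = res$duration_s,
                         n_fields = nrow(res$fields),
                         n_shifts = nrow(res$shifts))
    if (verbose) {
      message(sprintf("run %d/%d: %.1f s simulated, %d complete fields",
                      k, n_runs, res$duration_s, nrow(res$fields)))
    }
  }
  pooled <- pooled[!vapply(pooled, is.null, logical(1))]
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(pooled)) {
      utils::write.csv(pooled[[nm]], file.path(outdir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    manifest <- list(package_version = as.character(utils::packageVersion("thetasweeps")),
                     r_version = as.character(getRversion()),
                     config = unclass(config), per_run = per_run)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    save_config(config, file.path(outdir, "config.yaml"))
  }
  invisible(list(pooled = pooled, per_run = per_run))
}

# slope/correlation of y on x via ordinary regression; helper for summaries
trend <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(list(slope = NA_real_, r = NA_real_))
  co <- stats::coef(stats::lm(y[ok] ~ x[ok]))
  list(slope = unname(co[2]), r = stats::cor(x[ok], y[ok]))
}

# mean of y in equal-width bins of x, then the trend across bin means;
# matches the binned-average curves used in the sweep analyses
binned_trend <- function(x, y, breaks) {
  b <- cut(x, breaks, include.lowest = TRUE)
  mx <- tapply(x, b, mean)
  my <- tapply(y, b, mean)
  trend(as.numeric(mx), as.numeric(my))
}

#' Summarize a pooled experiment into a machine-readable report
#'
#' Computes the headline statistics of the pooled tables: the mean backward
#' shift between measured and true place fields (ms), the mean temporal
#' look-ahead at field onset (ms), the speed dependence of field size,
#' inverse phase-precession slope and field density, the sweep metrics'
#' speed trends, the shift-vs-look-behind comparison and, when present, the
#' instantaneous-speed ratio means.
#'
#' @param pooled The `pooled` element of a [run_experiment()] result (or a
#'   directory containing the CSV tables it writes).
#' @param track A [track_spec()] matching the experiment (only its length is
#'   used).
#' @return A named list of scalar statistics.
#' @export
summarize_experiment <- function(pooled, track = track_spec()) {
  if (is.character(pooled)) {
    files <- list.files(pooled, pattern = "\\.csv$", full.names = TRUE)
    nm <- sub("\\.csv$", "", basename(files))
    pooled <- stats::setNames(lapply(files, utils::read.csv), nm)
  }
  rep <- list()
  if (!is.null(pooled$shifts)) {
    sh <- pooled$shifts
    rep$n_shift_fields <- nrow(sh)
    rep$mean_backward_shift_ms <- mean(sh$shift_time_ms)
    rep$mean_onset_lookahead_ms <- mean(sh$onset_lookahead_ms)
    rep$shift_vs_speed_r <- trend(sh$mean_speed, -sh$shift)$r
  }
  if (!is.null(pooled$fields)) {
    tsz <- trend(pooled$fields$mean_speed, pooled$fields$size)
    rep$size_vs_speed_slope <- tsz$slope
    rep$size_vs_speed_r <- tsz$r
  }
  if (!is.null(pooled$slopes)) {
    tis <- trend(pooled$slopes$mean_speed, pooled$slopes$inv_slope_mag)
    rep$inv_slope_vs_speed_slope <- tis$slope
    rep$inv_slope_vs_speed_r <- tis$r
  }
  if (!is.null(pooled$density)) {
    d <- stats::aggregate(count ~ window_center + mean_speed, pooled$density,
                          mean)
    lin <- stats::lm(count ~ mean_speed, d)
    hyp <- stats::lm(count ~ I(1 / mean_speed), d)
    rep$density_vs_speed_slope <- unname(stats::coef(lin)[2])
    rep$density_r2_linear <- summary(lin)$r.squared
    rep$density_r2_hyperbolic <- summary(hyp)$r.squared
  }
  if (!is.null(pooled$sweeps)) {
    sw <- pooled$sweeps[!pooled$sweeps$excluded, ]
    breaks <- seq(0, max(sw$mean_speed_at_pos) + 5, by = 5)
    rep$n_sweeps <- nrow(sw)
    rep$lookbehind_vs_speed_slope <-
      binned_trend(sw$mean_speed_at_pos, sw$look_behind, breaks)$slope
    rep$lookahead_vs_speed_slope <-
      binned_trend(sw$mean_speed_at_pos, sw$look_ahead, breaks)$slope
    rep$length_vs_speed_slope <-
      binned_trend(sw$mean_speed_at_pos, sw$length, breaks)$slope
    if (!is.null(pooled$shifts)) {
      cmp <- shift_vs_lookbehind(pooled$shifts, sw, track)
      rep$lookbehind_vs_shift_slope <- cmp$fit$slope
      rep$lookbehind_vs_shift_r <- cmp$fit$r
    }
  }
  if (!is.null(pooled$ratios)) {
    rep$size_ratio_mean <- mean(pooled$ratios$size_ratio)
    rep$inv_slope_ratio_mean <- mean(pooled$ratios$inv_slope_ratio)
  }
  rep
}
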