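#' Decode represented position by template correlation
#'
#' For each time step, Pearson-correlates the instantaneous population
#' activation vector with the template population vector of every spatial bin
#' (a column of the measured activation map) and takes the best-matching bin.
#' Steps where no unit exceeds `act_min` — the inhibited troughs between
#' theta cycles — or where the population vector has zero variance are marked
#' invalid. Correlation ties go to the lowest-index bin.
#'
#' @param run A [run_simulation()] result.
#' @param templates An [activation_map()] (measured source) from the same
#'   run.
#' @param act_min Minimum single-unit activation for a step to be decodable.
#' @param warmup Seconds discarded from the start.
#' @param steps Optional explicit step indices (defaults to all post-warmup
#'   steps).
#' @param chunk Steps per block in the blocked correlation computation.
#' @return A `data.frame` of class `decoded_trajectory`: `step`, `t`, `x`
#'   (real position), `theta_phase`, `lap_id`, `decoded_bin`, `decoded_pos`
#'   (cm; NA when invalid), `best_corr`, `valid`.
#' @export
decode_positions <- function(run, templates, act_min = 0.1, warmup = 80,
                             steps = NULL, chunk = 20000L) {
  traj <- run$trajectory
  if (is.null(steps)) steps <- which(traj$t >= warmup)
  tv <- templates$values # units x bins
  n <- nrow(tv)
  tc <- sweep(tv, 2, colMeans(tv))
  tnorm <- sqrt(colSums(tc^2))
  usable <- tnorm > 0
  tz <- sweep(tc[, usable, drop = FALSE], 2, tnorm[usable], "/")
  n_steps <- length(steps)
  decoded_bin <- rep(NA_integer_, n_steps)
  best_corr <- rep(NA_real_, n_steps)
  valid <- logical(n_steps)
  bin_ids <- which(usable)
  for (st in seq(1, n_steps, by = chunk)) {
    en <- min(st + chunk - 1L, n_steps)
    pop <- run$sigma[, steps[st:en], drop = FALSE]
    vmax <- apply(pop, 2, max)
    pc <- sweep(pop, 2, colMeans(pop))
    pnorm <- sqrt(colSums(pc^2))
    ok <- vmax > act_min & pnorm > 0
    if (any(ok)) {
      pz <- sweep(pc[, ok, drop = FALSE], 2, pnorm[ok], "/")
      cc <- crossprod(pz, tz) # steps x usable-bins
      pick <- max.col(cc, ties.method = "first")
      rows <- which(ok)
      decoded_bin[st:en][rows] <- bin_ids[pick]
      best_corr[st:en][rows] <- cc[cbind(seq_len(nrow(cc)), pick)]
      valid[st:en][rows] <- TRUE
    }
  }
  out <- data.frame(step = steps, t = traj$t[steps], x = traj$x[steps],
                    theta_phase = traj$theta_phase[steps],
                    lap_id = traj$lap_id[steps],
                    decoded_bin = decoded_bin,
                    decoded_pos = templates$centers[decoded_bin],
                    best_corr = best_corr, valid = valid)
  attr(out, "n_bins") <- ncol(tv)
  class(out) <- c("decoded_trajectory", "data.frame")
  out
}

#' Segment a trajectory into theta cycles
#'
#' Cycle boundaries are placed at theta = 0 (the inhibition peak), so each
#' cycle contains one contiguous active epoch. A cycle is `complete` when it
#' is bounded by phase wraps on both sides and does not straddle a lap
#' teleport.
#'
#' @param traj A trajectory (or any data.frame with `theta_phase` and
#'   `lap_id`).
#' @param steps Optional step indices to segment (default: all).
#' @return A `data.frame`: `cycle_id`, `start`, `end` (step indices,
#'   inclusive), `complete`.
#' @export
segment_cycles <- function(traj, steps = NULL) {
  if (is.null(steps)) steps <- seq_len(nrow(traj))
  ph <- traj$theta_phase[steps]
  n <- length(ph)
  wraps <- which(diff(ph) < 0) + 1L # first step of each new cycle
  starts <- c(1L, wraps)
  ends <- c(wraps - 1L, n)
  complete <- logical(length(starts))
  complete[] <- TRUE
  complete[1] <- FALSE
  complete[length(complete)] <- FALSE
  lap <- traj$lap_id[steps]
  lap_change <- vapply(seq_along(starts), function(i) {
    any(lap[starts[i]:ends[i]] != lap[starts[i]])
  }, logical(1))
  data.frame(cycle_id = seq_along(starts),
             start = steps[starts], end = steps[ends],
             complete = complete & !lap_change)
}

#' Per-theta-cycle sweep metrics
#'
#' Splits each complete theta cycle into ten 36-degree phase bins anchored at
#' theta = 0 and finds the first and last bin containing at least one validly
#' decoded step (the start and end of the theta sweep). The look-behind is
#' the mean real position minus the mean decoded position in the first bin;
#' the look-ahead is the mean decoded position minus the mean real position
#' in the last bin; the sweep length is the difference between the mean
#' decoded positions of the two bins. Cycles in which the first or last
#' spatial bin of the track wins the correlation at any step are excluded
#' (boundary artifacts), as are cycles with no valid steps.
#'
#' @param decoded A [decode_positions()] result.
#' @param n_phase_bins Number of phase bins per cycle (10).
#' @return A `data.frame` of class `sweep_records`, one row per complete
#'   cycle: `cycle_id`, `look_behind`, `look_ahead`, `length` (cm),
#'   `mean_real_pos` (cm), `excluded`, `reason`. Use [sweep_speeds()] to
#'   attach the local target speed.
#' @export
sweep_metrics <- function(decoded, n_phase_bins = 10) {
  cycles <- segment_cycles(decoded)
  cycles <- cycles[cycles$complete, ]
  n_bins <- attr(decoded, "n_bins")
  res <- vector("list", nrow(cycles))
  for (i in seq_len(nrow(cycles))) {
    # segment_cycles() on the decoded table returns row ranges
    d <- decoded[cycles$start[i]:cycles$end[i], ]
    mean_real <- mean(d$x)
    rec <- data.frame(cycle_id = cycles$cycle_id[i], look_behind = NA_real_,
                      look_ahead = NA_real_, length = NA_real_,
                      mean_real_pos = mean_real,
                      excluded = TRUE, reason = "")
    val <- d[d$valid, ]
    if (nrow(val) == 0) {
      rec$reason <- "no_valid_steps"
      res[[i]] <- rec
      next
    }
    if (any(val$decoded_bin == 1L | val$decoded_bin == n_bins)) {
      rec$reason <- "track_edge_decoded"
      res[[i]] <- rec
      next
    }
    pb <- pmin(floor(val$theta_phase / (2 * pi) * n_phase_bins) + 1L,
               n_phase_bins)
    first_bin <- min(pb)
    last_bin <- max(pb)
    fb <- val[pb == first_bin, ]
    lb <- val[pb == last_bin, ]
    rec$look_behind <- mean(fb$x) - mean(fb$decoded_pos)
    rec$look_ahead <- mean(lb$decoded_pos) - mean(lb$x)
    rec$length <- mean(lb$decoded_pos) - mean(fb$decoded_pos)
    rec$excluded <- FALSE
    res[[i]] <- rec
  }
  out <- do.call(rbind, res)
  class(out) <- c("sweep_records", "data.frame")
  out
}

#' Attach the local target speed to sweep records
#'
#' @param sweeps A [sweep_metrics()] table.
#' @param profile A [speed_profile()].
#' @param track A [track_spec()].
#' @return The table with a `mean_speed_at_pos` column.
#' @export
sweep_speeds <- function(sweeps, profile, track) {
  sweeps$mean_speed_at_pos <- target_speed(sweeps$mean_real_pos, profile, track)
  sweeps
}

#' Compare look-behind distances with place-field shifts by location
#'
#' Bins both quantities by track position (the sweep's mean real position;
#' the field's measured peak position) and returns the paired bin means plus
#' an ordinary regression of binned look-behind on binned backward shift,
#' whose slope near 1 indicates that the decoding look-behind is explained by
#' the measured-vs-true field shift.
#'
#' @param shifts A [field_shifts()] table (possibly pooled over runs).
#' @param sweeps A [sweep_metrics()] table (possibly pooled; excluded rows
#'   are dropped).
#' @param track A [track_spec()].
#' @param bin_width Position bin width, cm.
#' @return A list with `bins` (a `data.frame`: `bin_center`, `mean_shift`,
#'   `mean_look_behind`, both cm) and `fit` (`slope`, `intercept`, `r`).
#' @export
shift_vs_lookbehind <- function(shifts, sweeps, track, bin_width = 20) {
  sweeps <- sweeps[!sweeps$excluded, ]
  breaks <- seq(0, track$length, by = bin_width)
  centers <- breaks[-1] - bin_width / 2
  sh_bin <- cut(shifts$measured_peak, breaks, include.lowest = TRUE)
  sw_bin <- cut(sweeps$mean_real_pos, breaks, include.lowest = TRUE)
  # backward shift as a positive distance: true peak - measured peak
  mean_shift <- tapply(-shifts$shift, sh_bin, mean)
  mean_lb <- tapply(sweeps$look_behind, sw_bin, mean)
  bins <- data.frame(bin_center = centers,
                     mean_shift = as.numeric(mean_shift),
                     mean_look_behind = as.numeric(mean_lb))
  ok <- stats::complete.cases(bins)
  fit <- if (sum(ok) >= 3) {
    co <- stats::coef(stats::lm(mean_look_behind ~ mean_shift, data = bins[ok, ]))
    r <- if (stats::sd(bins$mean_shift[ok]) > 0 &&
             stats::sd(bins$mean_look_behind[ok]) > 0) {
      stats::cor(bins$mean_shift[ok], bins$mean_look_behind[ok])
    } else {
      NA_real_
    }
    list(slope = unname(co[2]), intercept = unname(co[1]), r = r)
  } else {
    list(slope = NA_real_, intercept = NA_real_, r = NA_real_)
  }
  list(bins = bins, fit = fit)
}
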