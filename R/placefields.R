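#' Spatial activation map
#'
#' Mean per-unit signal in 2 cm occupancy bins of the track, lightly smoothed
#' with a Gaussian kernel along space. The `"measured"` source averages the
#' unit activations `sigma_r(r)`; the `"true"` source averages the spatial
#' input `i_ext` driving each unit, giving the input-defined (true) place
#' fields. The first `warmup` seconds of the session are discarded (place
#' fields are still unstable while the input weights are being learned).
#'
#' @param run A [run_simulation()] result.
#' @param source `"measured"` (`sigma_r(r)`) or `"true"` (`i_ext`).
#' @param bin_size Spatial bin size, cm.
#' @param smoothing_sd Gaussian smoothing standard deviation, cm (0 disables).
#' @param warmup Seconds discarded from the start of the session.
#' @param steps Optional explicit step indices to use instead of all
#'   post-warmup steps (e.g. a speed-conditioned subset).
#' @return An object of class `activation_map`: list with `values` (units x
#'   bins), `centers` (bin centers, cm), `bin_size`, `occupancy` (steps per
#'   bin), `empty_bins`, `source`.
#' @export
activation_map <- function(run, source = c("measured", "true"), bin_size = 2,
                           smoothing_sd = 3, warmup = 80, steps = NULL) {
  source <- match.arg(source)
  traj <- run$trajectory
  track <- attr(traj, "track")
  traces <- if (source == "measured") run$sigma else run$i_ext
  if (is.null(steps)) steps <- which(traj$t >= warmup)
  if (length(steps) == 0) stop("no steps left after warm-up exclusion")
  n_bins <- as.integer(ceiling(track$length / bin_size))
  bins <- pmin(floor(traj$x[steps] / bin_size) + 1L, n_bins)
  by_bin <- split(steps, factor(bins, levels = seq_len(n_bins)))
  occupancy <- lengths(by_bin)
  n_units <- nrow(traces)
  values <- matrix(NA_real_, n_units, n_bins)
  for (b in seq_len(n_bins)) {
    idx <- by_bin[[b]]
    if (length(idx) > 0) {
      values[, b] <- rowMeans(traces[, idx, drop = FALSE])
    }
  }
  centers <- (seq_len(n_bins) - 0.5) * bin_size
  empty <- which(occupancy == 0)
  if (length(empty) > 0) {
    # interpolate across unvisited bins so smoothing has full support
    filled <- which(occupancy > 0)
    for (u in seq_len(n_units)) {
      values[u, empty] <- stats::approx(centers[filled], values[u, filled],
                                        xout = centers[empty], rule = 2)$y
    }
  }
  if (smoothing_sd > 0) {
    sd_bins <- smoothing_sd / bin_size
    values <- t(apply(values, 1, gaussian_smooth, sd = sd_bins))
  }
  structure(list(values = values, centers = centers, bin_size = bin_size,
                 occupancy = as.integer(occupancy), empty_bins = empty,
                 source = source, smoothing_sd = smoothing_sd),
            class = "activation_map")
}

# interpolated crossing of `thr` adjacent to the peak; side = -1 (left), +1
# (right). Returns NA if the map never falls below thr on that side.
crossing_pos <- function(v, centers, pk, thr, side) {
  idx <- if (side < 0) rev(seq_len(pk)) else pk:length(v)
  below <- which(v[idx] < thr)
  if (length(below) == 0) return(NA_real_)
  j <- idx[below[1]]            # first bin below threshold moving outwards
  k <- j - side                 # neighbouring bin (>= thr) towards the peak
  if (v[k] == v[j]) return(centers[j])
  centers[k] + (centers[j] - centers[k]) * (v[k] - thr) / (v[k] - v[j])
}

# sub-bin peak refinement: 3-point parabola around the argmax
refine_peak <- function(v, centers, pk, bin_size) {
  if (pk == 1 || pk == length(v)) return(centers[pk])
  denom <- v[pk - 1] - 2 * v[pk] + v[pk + 1]
  if (denom >= 0) return(centers[pk])
  off <- 0.5 * (v[pk - 1] - v[pk + 1]) / denom
  centers[pk] + max(-0.5, min(0.5, off)) * bin_size
}

#' Extract place fields from an activation map
#'
#' Per unit: the field peak is the global maximum of its (smoothed) map row.
#' Units with a peak below `peak_min` are discarded, as are units whose
#' activation does not fall below 50% of the peak on both sides before the
#' track ends (fields substantially cut off by the track boundaries). Field
#' size is the extent above 10% of the peak; if that threshold is reached on
#' only one side, size is twice the peak-to-crossing distance and the field
#' is marked incomplete. Threshold crossings are linearly interpolated
#' between bin centers and the peak position is refined with a 3-point
#' parabola.
#'
#' @param map An [activation_map()].
#' @param peak_min Absolute peak threshold for retaining a unit (0.2 for
#'   measured maps; use 0 for input-defined maps, whose scale is bounded by
#'   the theta gate rather than the unit nonlinearity).
#' @return A `data.frame` with one row per retained unit: `unit`, `peak_pos`,
#'   `peak_val`, `start_pos`, `end_pos`, `size`, `complete`.
#' @export
extract_fields <- function(map, peak_min = 0.2) {
  n_units <- nrow(map$values)
  rows <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    v <- map$values[u, ]
    pk <- which.max(v)
    peak <- v[pk]
    if (peak < peak_min) next
    # cut-off filter: must drop below 50% of peak on both sides
    if (!(any(v[seq_len(pk)] < 0.5 * peak) && any(v[pk:length(v)] < 0.5 * peak))) next
    thr <- 0.1 * peak
    left <- crossing_pos(v, map$centers, pk, thr, -1)
    right <- crossing_pos(v, map$centers, pk, thr, +1)
    peak_pos <- refine_peak(v, map$centers, pk, map$bin_size)
    complete <- !is.na(left) && !is.na(right)
    if (complete) {
      size <- right - left
    } else if (!is.na(left)) {
      size <- 2 * (peak_pos - left)
    } else if (!is.na(right)) {
      size <- 2 * (right - peak_pos)
    } else {
      next # no 10% crossing on either side: no measurable extent
    }
    rows[[u]] <- data.frame(unit = u, peak_pos = peak_pos, peak_val = peak,
                            start_pos = if (is.na(left)) NA_real_ else left,
                            end_pos = if (is.na(right)) NA_real_ else right,
                            size = size, complete = complete)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(unit = integer(), peak_pos = numeric(),
                      peak_val = numeric(), start_pos = numeric(),
                      end_pos = numeric(), size = numeric(),
                      complete = logical())
  }
  rownames(out) <- NULL
  out
}

#' Occupancy-weighted mean running speed through each field
#'
#' Mean of the target speed profile over the post-warmup trajectory steps
#' spent between `start_pos` and `end_pos` of each field.
#'
#' @param fields A field table from [extract_fields()].
#' @param traj The run's trajectory.
#' @param warmup Seconds discarded from the start.
#' @return Numeric vector, cm/s, one entry per field row (NA for incomplete
#'   fields).
#' @export
field_mean_speeds <- function(fields, traj, warmup = 80) {
  track <- attr(traj, "track")
  profile <- attr(traj, "profile")
  keep <- traj$t >= warmup
  x <- traj$x[keep]
  vbar <- target_speed(x, profile, track)
  vapply(seq_len(nrow(fields)), function(i) {
    a <- fields$start_pos[i]
    b <- fields$end_pos[i]
    if (is.na(a) || is.na(b)) return(NA_real_)
    inside <- x >= a & x <= b
    if (!any(inside)) return(NA_real_)
    mean(vbar[inside])
  }, numeric(1))
}

#' Measured-versus-true place-field shifts
#'
#' Pairs each unit's measured field (from the `sigma_r(r)` map) with its true
#' field (from the `i_ext` map) and computes the spatial shift between their
#' peaks, the equivalent temporal shift at the mean running speed through the
#' measured field, and the temporal look-ahead from the measured field onset
#' to the true-field peak. Only units with complete fields in both maps are
#' kept.
#'
#' @param measured,true Field tables from [extract_fields()] on the measured
#'   and true maps of the same run.
#' @param traj The run's trajectory.
#' @param warmup Seconds discarded from the start.
#' @return A `data.frame`: `unit`, `measured_peak`, `true_peak`,
#'   `measured_start`, `shift` (cm, measured - true; negative means the
#'   measured field sits behind the true field), `mean_speed` (cm/s),
#'   `shift_time_ms` (backward shift as a positive duration),
#'   `onset_lookahead_ms`.
#' @export
field_shifts <- function(measured, true, traj, warmup = 80) {
  m <- measured[measured$complete, ]
  tr <- true[true$complete, ]
  common <- intersect(m$unit, tr$unit)
  m <- m[match(common, m$unit), ]
  tr <- tr[match(common, tr$unit), ]
  speed <- field_mean_speeds(m, traj, warmup)
  data.frame(
    unit = common,
    measured_peak = m$peak_pos,
    true_peak = tr$peak_pos,
    measured_start = m$start_pos,
    shift = m$peak_pos - tr$peak_pos,
    mean_speed = speed,
    shift_time_ms = (tr$peak_pos - m$peak_pos) / speed * 1000,
    onset_lookahead_ms = (tr$peak_pos - m$start_pos) / speed * 1000
  )
}

#' Position-by-phase activation map
#'
#' Mean unit activation in position x theta-phase bins (2 cm and 20 degrees
#' by default), the basis of the phase-precession analysis.
#'
#' @inheritParams activation_map
#' @param pos_bin Position bin size, cm.
#' @param phase_bin Phase bin size, degrees (must divide 360).
#' @return An object of class `phase_map`: list with `values` (3-D array
#'   units x position bins x phase bins), `pos_centers` (cm) and
#'   `phase_centers` (degrees).
#' @export
phase_map <- function(run, pos_bin = 2, phase_bin = 20, warmup = 80,
                      steps = NULL) {
  traj <- run$trajectory
  track <- attr(traj, "track")
  if (is.null(steps)) steps <- which(traj$t >= warmup)
  n_pos <- as.integer(ceiling(track$length / pos_bin))
  n_ph <- as.integer(round(360 / phase_bin))
  stopifnot(n_ph * phase_bin == 360)
  pb <- pmin(floor(traj$x[steps] / pos_bin) + 1L, n_pos)
  hb <- pmin(floor(traj$theta_phase[steps] / (2 * pi) * n_ph) + 1L, n_ph)
  grp <- (hb - 1L) * n_pos + pb
  by_grp <- split(steps, factor(grp, levels = seq_len(n_pos * n_ph)))
  n_units <- nrow(run$sigma)
  values <- array(0, c(n_units, n_pos, n_ph))
  for (g in seq_along(by_grp)) {
    idx <- by_grp[[g]]
    if (length(idx) == 0) next
    b <- (g - 1L) %% n_pos + 1L
    h <- (g - 1L) %/% n_pos + 1L
    values[, b, h] <- rowMeans(run$sigma[, idx, drop = FALSE])
  }
  structure(list(values = values,
                 pos_centers = (seq_len(n_pos) - 0.5) * pos_bin,
                 phase_centers = (seq_len(n_ph) - 0.5) * phase_bin,
                 pos_bin = pos_bin, phase_bin = phase_bin),
            class = "phase_map")
}

# weighted orthogonal fit of a phase-precession cloud with branch search:
# phases live on a circle, so every 360-degree relabeling cut is tried and
# the branch with the smallest orthogonal residual wins
fit_precession_cloud <- function(pos, phase_deg, w, phase_bin) {
  cuts <- seq(0, 360 - phase_bin, by = phase_bin)
  best <- NULL
  for (cut in cuts) {
    ph <- phase_deg + 360 * (phase_deg < cut)
    fit <- tls_line(pos, ph, w)
    if (is.null(best) || fit$ossr < best$ossr) best <- fit
  }
  best
}

#' Phase-precession slopes by orthogonal distance regression
#'
#' For each complete field, collects the position x phase bins within the
#' field extent whose activation exceeds 10% of the unit's in-field
#' phase-map maximum, and fits a line to the (position, phase) bin centers
#' by activation-weighted total least squares (orthogonal distances). Because
#' phase is circular, the fit is repeated for every 360-degree relabeling cut
#' (one per phase bin) and the branch with the smallest orthogonal residual
#' is kept. Orthogonal fitting recovers the steep clouds at the track ends
#' that ordinary regression would flatten.
#'
#' @param pmap A [phase_map()].
#' @param fields Field table from [extract_fields()] (complete fields used).
#' @param thresh_frac Activation threshold as a fraction of the in-field
#'   phase-map maximum.
#' @param min_bins Minimum number of contributing bins; units with fewer are
#'   skipped.
#' @return A `data.frame`: `unit`, `slope` (degrees/cm, negative for phase
#'   precession), `inv_slope` (cm/degree), `inv_slope_mag`, `n_points`.
#' @export
phase_precession_slopes <- function(pmap, fields, thresh_frac = 0.1,
                                    min_bins = 3) {
  fields <- fields[fields$complete, ]
  rows <- vector("list", nrow(fields))
  for (i in seq_len(nrow(fields))) {
    u <- fields$unit[i]
    in_field <- pmap$pos_centers >= fields$start_pos[i] &
      pmap$pos_centers <= fields$end_pos[i]
    if (!any(in_field)) next
    sub <- pmap$values[u, in_field, , drop = TRUE]
    if (is.null(dim(sub))) sub <- matrix(sub, nrow = 1)
    keep <- sub >= thresh_frac * max(sub)
    if (sum(keep) < min_bins) next
    ij <- which(keep, arr.ind = TRUE)
    pos <- pmap$pos_centers[in_field][ij[, 1]]
    ph <- pmap$phase_centers[ij[, 2]]
    w <- sub[keep]
    fit <- fit_precession_cloud(pos, ph, w, pmap$phase_bin)
    slope <- fit$slope
    rows[[i]] <- data.frame(unit = u, slope = slope,
                            inv_slope = 1 / slope,
                            inv_slope_mag = abs(1 / slope),
                            n_points = sum(keep))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(unit = integer(), slope = numeric(),
                      inv_slope = numeric(), inv_slope_mag = numeric(),
                      n_points = integer())
  }
  rownames(out) <- NULL
  out
}

#' Instantaneous-speed invariance ratios
#'
#' Recomputes field sizes and phase-precession slopes twice per unit: once
#' from only the time steps whose instantaneous speed is in the top 20% of
#' the speeds observed in that spatial bin, and once from the bottom 20%.
#' Returns per-unit top/bottom ratios for field size and inverse-slope
#' magnitude; units without a complete field (or a defined slope) in both
#' conditions are excluded. Behavior-dependent (rather than
#' instantaneous-speed-dependent) coding predicts ratios close to 1.
#'
#' @param run A [run_simulation()] result (use a longer, e.g. 45-lap,
#'   session so both speed conditions sample every bin).
#' @param quantile Fraction defining the top/bottom speed groups per bin.
#' @param warmup,bin_size,smoothing_sd,pos_bin,phase_bin As in
#'   [activation_map()] / [phase_map()].
#' @return A `data.frame`: `unit`, `size_ratio`, `inv_slope_ratio`.
#' @export
instantaneous_speed_ratios <- function(run, quantile = 0.2, warmup = 80,
                                       bin_size = 2, smoothing_sd = 3,
                                       pos_bin = 2, phase_bin = 20) {
  traj <- run$trajectory
  track <- attr(traj, "track")
  steps <- which(traj$t >= warmup)
  n_bins <- as.integer(ceiling(track$length / bin_size))
  bins <- pmin(floor(traj$x[steps] / bin_size) + 1L, n_bins)
  v <- traj$v[steps]
  q_lo <- tapply(v, bins, stats::quantile, probs = quantile)
  q_hi <- tapply(v, bins, stats::quantile, probs = 1 - quantile)
  bchar <- as.character(bins)
  bot <- steps[v <= q_lo[bchar]]
  top <- steps[v >= q_hi[bchar]]
  one_condition <- function(idx) {
    amap <- activation_map(run, "measured", bin_size, smoothing_sd,
                           warmup, steps = idx)
    flds <- extract_fields(amap)
    pm <- phase_map(run, pos_bin, phase_bin, warmup, steps = idx)
    slopes <- phase_precession_slopes(pm, flds)
    merge(flds[flds$complete, c("unit", "size")],
          slopes[, c("unit", "inv_slope_mag")], by = "unit")
  }
  ttab <- one_condition(top)
  btab <- one_condition(bot)
  both <- merge(ttab, btab, by = "unit", suffixes = c("_top", "_bottom"))
  ok <- is.finite(both$inv_slope_mag_top) & is.finite(both$inv_slope_mag_bottom) &
    both$inv_slope_mag_bottom > 0 & both$size_bottom > 0
  both <- both[ok, ]
  data.frame(unit = both$unit,
             size_ratio = both$size_top / both$size_bottom,
             inv_slope_ratio = both$inv_slope_mag_top / both$inv_slope_mag_bottom)
}

#' Place-field density along the track
#'
#' Counts place-field peaks (one per retained unit) in overlapping windows
#' and pairs each window with its mean target running speed.
#'
#' @param fields Field table from [extract_fields()].
#' @param profile A [speed_profile()].
#' @param track A [track_spec()].
#' @param window Window width, cm.
#' @param stride Window stride, cm.
#' @return A `data.frame`: `window_start`, `window_center`, `count`,
#'   `mean_speed` (cm/s).
#' @export
field_density <- function(fields, profile, track, window = 10, stride = 2) {
  starts <- seq(0, track$length - window, by = stride)
  grid <- seq(0.05, window - 0.05, by = 0.1)
  data.frame(
    window_start = starts,
    window_center = starts + window / 2,
    count = vapply(starts, function(s) {
      sum(fields$peak_pos >= s & fields$peak_pos < s + window)
    }, numeric(1)),
    mean_speed = vapply(starts, function(s) {
      mean(target_speed(s + grid, profile, track))
    }, numeric(1))
  )
}
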