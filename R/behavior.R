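#' Linear-track specification
#'
#' Geometry and discretization of the simulated linear track.
#'
#' @param length Track length in cm.
#' @param bin_size_features Spatial bin size (cm) on which the weakly tuned
#'   input features are defined.
#' @param n_laps Number of laps to simulate. The default run uses 30; the
#'   instantaneous-speed invariance analysis uses 45.
#' @param dt Integration time step in seconds (1 ms).
#' @return An object of class `track_spec`.
#' @export
track_spec <- function(length = 200, bin_size_features = 1, n_laps = 30,
                       dt = 0.001) {
  stopifnot(length > 0, bin_size_features > 0, n_laps >= 1, dt > 0)
  structure(list(length = length, bin_size_features = bin_size_features,
                 n_laps = as.integer(n_laps), dt = dt),
            class = "track_spec")
}

#' Triangular target mean-speed profile
#'
#' The typical running speed of the simulated rat at each position: slow at
#' both ends of the track and fast in the middle, interpolated linearly.
#'
#' @param v_end Target speed at both ends of the track (cm/s).
#' @param v_mid Target speed at the middle of the track (cm/s).
#' @return An object of class `speed_profile`.
#' @export
speed_profile <- function(v_end = 15, v_mid = 80) {
  stopifnot(v_end > 0, v_mid >= v_end)
  structure(list(v_end = v_end, v_mid = v_mid, shape = "triangular"),
            class = "speed_profile")
}

#' Smooth multiplicative speed-noise specification
#'
#' Lap-to-lap speed variability is generated by multiplying the target speed
#' with a smooth noise factor: white Gaussian noise per time step convolved
#' with a Gaussian kernel (`kernel_std` seconds wide), then rescaled
#' affinely so the session-wide factor ranges between `lo` and `hi`,
#' centered at `center`.
#'
#' @param kernel_std Smoothing kernel standard deviation in seconds.
#' @param lo,hi Range of the rescaled factor.
#' @param center Value the degenerate (zero-variance) series maps to; must
#'   equal the range midpoint.
#' @return An object of class `speed_noise_spec`.
#' @export
speed_noise_spec <- function(kernel_std = 2, lo = 0.5, hi = 1.5, center = 1) {
  stopifnot(kernel_std > 0, lo < center, center < hi)
  structure(list(kernel_std = kernel_std, lo = lo, hi = hi, center = center),
            class = "speed_noise_spec")
}

#' Target mean running speed at a position
#'
#' Piecewise-linear interpolation between (0, `v_end`), (length/2, `v_mid`)
#' and (length, `v_end`).
#'
#' @param x Position(s) in cm; must lie within the track.
#' @param profile A [speed_profile()].
#' @param track A [track_spec()].
#' @return Target speed(s) in cm/s.
#' @export
target_speed <- function(x, profile, track) {
  if (any(x < 0 | x > track$length)) {
    stop("position outside the track")
  }
  half <- track$length / 2
  d <- abs(x - half)
  profile$v_mid + (profile$v_end - profile$v_mid) * d / half
}

#' Smooth multiplicative speed-noise factor series
#'
#' Draws independent standard Gaussian noise at every time step, convolves it
#' with a Gaussian kernel of standard deviation `spec$kernel_std` seconds
#' (truncated at 4 sd, reflective boundaries), and rescales the result
#' affinely so that over the whole series min = `spec$lo` and max =
#' `spec$hi`. A degenerate zero-variance series maps to the constant
#' `spec$center`.
#'
#' @param n_steps Number of time steps.
#' @param spec A [speed_noise_spec()].
#' @param dt Time step in seconds.
#' @param seed Integer seed for the noise stream.
#' @param raw Optional pre-drawn raw noise (for testing degenerate inputs);
#'   overrides the seed.
#' @return Numeric vector of length `n_steps`.
#' @export
speed_noise_factor <- function(n_steps, spec, dt = 0.001, seed = NULL,
                               raw = NULL) {
  sd_steps <- spec$kernel_std / dt
  if (n_steps < 2 * sd_steps) {
    stop("series shorter than the smoothing kernel support; cannot scale meaningfully")
  }
  if (is.null(raw)) {
    if (!is.null(seed)) set.seed(seed)
    raw <- stats::rnorm(n_steps)
  } else {
    stopifnot(length(raw) == n_steps)
  }
  smooth <- gaussian_smooth(raw, sd_steps)
  rescale_range(smooth, spec$lo, spec$hi)
}

# expected lap duration (s) at the target profile, used to size the noise
# series before the actual (noise-dependent) duration is known
expected_lap_time <- function(profile, track) {
  half <- track$length / 2
  if (profile$v_mid == profile$v_end) return(track$length / profile$v_end)
  2 * half / (profile$v_mid - profile$v_end) * log(profile$v_mid / profile$v_end)
}

#' Simulate the rat's trajectory on the linear track
#'
#' Forward-Euler motion at `track$dt`: each step the position advances by
#' `v * dt`, where the instantaneous speed `v` is the target mean speed at
#' the current position multiplied by the smooth noise factor. On reaching
#' the end of the track the rat is teleported back to 0 and the lap counter
#' increments; time (and hence theta phase) keeps running freely across
#' laps.
#'
#' The session-wide affine scaling of the noise factor (min to `noise$lo`,
#' max to `noise$hi`) is applied to exactly the steps the session uses; since
#' the session duration itself depends on the scaled noise, the scaling
#' window is found by fixed-point iteration (it converges in a few rounds
#' because the duration is insensitive to the tail of the window).
#'
#' @param track A [track_spec()].
#' @param profile A [speed_profile()].
#' @param noise A [speed_noise_spec()], or `NULL` for noise-free motion
#'   (factor identically 1).
#' @param theta_freq Theta frequency in Hz (8 by default).
#' @param seed Integer seed for the speed-noise stream.
#' @return A `data.frame` of class `trajectory` with columns `t` (s), `x`
#'   (cm), `v` (cm/s), `lap_id`, `theta_phase` (radians in \[0, 2pi)), and
#'   attributes `track`, `profile`, `theta_freq`.
#' @export
simulate_trajectory <- function(track, profile, noise = speed_noise_spec(),
                                theta_freq = 8, seed = 1) {
  stopifnot(theta_freq > 0)
  # hard upper bound on session length: slowest possible speed everywhere
  v_floor <- profile$v_end * if (is.null(noise)) 1 else noise$lo
  n_max <- ceiling(track$n_laps * track$length / v_floor / track$dt) + 10L
  if (is.null(noise)) {
    factors_raw <- rep(1, n_max)
    scale_fun <- function(n) factors_raw
  } else {
    sd_steps <- noise$kernel_std / track$dt
    set.seed(seed)
    factors_raw <- gaussian_smooth(stats::rnorm(n_max), sd_steps)
    scale_fun <- function(n) {
      pre <- factors_raw[seq_len(n)]
      rng <- range(pre)
      if (diff(rng) <= .Machine$double.eps) {
        return(rep(noise$center, n_max))
      }
      (factors_raw - rng[1]) / (rng[2] - rng[1]) * (noise$hi - noise$lo) + noise$lo
    }
  }
  n_est <- min(n_max, ceiling(1.05 * track$n_laps *
                                expected_lap_time(profile, track) / track$dt))
  sim <- NULL
  for (iter in 1:12) {
    fac <- scale_fun(n_est)
    sim <- simulate_motion_cpp(fac, track$length, profile$v_end,
                               profile$v_mid, track$dt, track$n_laps)
    n_act <- length(sim$x)
    if (n_act == n_est) break
    n_est <- n_act
  }
  n <- length(sim$x)
  t <- (seq_len(n) - 1) * track$dt
  traj <- data.frame(
    t = t,
    x = sim$x,
    v = sim$v,
    lap_id = sim$lap_id,
    theta_phase = (2 * pi * theta_freq * t) %% (2 * pi)
  )
  attr(traj, "track") <- track
  attr(traj, "profile") <- profile
  attr(traj, "theta_freq") <- theta_freq
  attr(traj, "noise_factor") <- sim$factor
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Write / read a trajectory as CSV
#'
#' @param traj A trajectory from [simulate_trajectory()].
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a plain `data.frame` with the trajectory columns.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path)
}
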