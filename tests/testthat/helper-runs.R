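# shared fixtures, computed once per test session and cached

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# small full-parameter network run used by the dynamics property tests:
# default 250-unit network, default track, shortened session
std_run <- function() {
  memo("std_run", {
    tr <- track_spec(n_laps = 24)
    traj <- simulate_trajectory(tr, speed_profile(), speed_noise_spec(),
                                seed = 101)
    bank <- generate_features(tr, seed = 102)
    run_simulation(traj, bank)
  })
}

# tiny network run (reduced track and units) for cheap structural tests
tiny_run <- function(store_stp = FALSE) {
  memo(paste0("tiny_run_", store_stp), {
    tr <- track_spec(length = 80, n_laps = 3)
    traj <- simulate_trajectory(tr, speed_profile(30, 60),
                                speed_noise_spec(kernel_std = 0.5),
                                seed = 7)
    bank <- generate_features(tr, n_features = 32, seed = 8)
    run_simulation(traj, bank, network_params(n_units = 80),
                   store_stp = store_stp)
  })
}

# a synthetic "run" whose activation is a pure deterministic function of
# position: unit u has a Gaussian spatial tuning curve. Useful as ground
# truth for map/field/decoding tests.
synthetic_run <- function(n_units = 12, track_len = 100, n_steps = 40000,
                          width = 6, theta_freq = 8, dt = 0.001,
                          speed = 25) {
  track <- track_spec(length = track_len, n_laps = 1, dt = dt)
  t <- (seq_len(n_steps) - 1) * dt
  x <- (speed * t) %% track_len
  lap_id <- floor(speed * t / track_len) + 1L
  traj <- data.frame(t = t, x = x, v = rep(speed, n_steps),
                     lap_id = lap_id,
                     theta_phase = (2 * pi * theta_freq * t) %% (2 * pi))
  attr(traj, "track") <- track
  attr(traj, "profile") <- speed_profile(speed, speed)
  attr(traj, "theta_freq") <- theta_freq
  class(traj) <- c("trajectory", "data.frame")
  centers <- seq(track_len / (n_units + 1), track_len * n_units / (n_units + 1),
                 length.out = n_units)
  sigma <- vapply(seq_len(n_steps), function(i) {
    exp(-(x[i] - centers)^2 / (2 * width^2))
  }, numeric(n_units))
  list(trajectory = traj, sigma = sigma, i_ext = sigma,
       params = network_params(n_units = n_units), theta_freq = theta_freq,
       centers = centers)
}

# brute-force orthogonal-distance line fit: scan over line angle and offset
# via closed-form projection; independent oracle for the TLS fitter
brute_odr <- function(x, y, w = rep(1, length(x)), n_angle = 20000) {
  best <- list(ossr = Inf)
  for (ang in seq(0, pi, length.out = n_angle)) {
    # unit normal of the line
    nx <- -sin(ang); ny <- cos(ang)
    c0 <- sum(w * (nx * x + ny * y)) / sum(w) # optimal offset
    ossr <- sum(w * (nx * x + ny * y - c0)^2)
    if (ossr < best$ossr) {
      best <- list(ossr = ossr, slope = tan(ang))
    }
  }
  best
}
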