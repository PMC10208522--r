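#' Network parameters
#'
#' All parameters of the 250-unit recurrent rate network, its theta drive,
#' short-term synaptic facilitation/depression, gated spatial input and
#' Hebbian input plasticity. Defaults are the model's reference values.
#'
#' @param n_units Number of units.
#' @param tau_r Activation time constant (s).
#' @param kappa_theta Concentration of the rhythmic drive waveform.
#' @param i_theta_max,i_theta_min Peak excitation / inhibition of the theta
#'   drive.
#' @param delta Asymmetry offset (in unit indices) of the recurrent kernel;
#'   sets the direction and pace of bump propagation.
#' @param sigma_rec Width (unit indices) of the recurrent Gaussian kernel.
#' @param w_rec_max,w_rec_min Peak and baseline recurrent weight.
#' @param alpha_r,x_r Gain and threshold of the somatic logistic nonlinearity
#'   `sigma_r`.
#' @param tau_f,tau_d Facilitation and depression time constants (s).
#' @param f0 Baseline facilitation.
#' @param kappa_s Concentration of the theta gate `beta_theta` on spatial
#'   input and plasticity.
#' @param beta_max Maximal spatial input amplitude.
#' @param alpha_s,x_s Gain and threshold of the dendritic logistic
#'   nonlinearity `sigma_s`.
#' @param tau_w Plasticity time constant (s).
#' @param n_init_units Number of units receiving the lap-initialization
#'   current.
#' @return An object of class `network_params`.
#' @export
network_params <- function(n_units = 250, tau_r = 0.005, kappa_theta = 12,
                           i_theta_max = 1.6, i_theta_min = -1, delta = 0.6,
                           sigma_rec = 5, w_rec_max = 0.5, w_rec_min = -2.8,
                           alpha_r = 6, x_r = 0.5, tau_f = 0.32, tau_d = 0.06,
                           f0 = 0.14, kappa_s = 2, beta_max = 0.4,
                           alpha_s = 12, x_s = 0.7, tau_w = 20,
                           n_init_units = 5) {
  p <- list(n_units = as.integer(n_units), tau_r = tau_r,
            kappa_theta = kappa_theta, i_theta_max = i_theta_max,
            i_theta_min = i_theta_min, delta = delta, sigma_rec = sigma_rec,
            w_rec_max = w_rec_max, w_rec_min = w_rec_min, alpha_r = alpha_r,
            x_r = x_r, tau_f = tau_f, tau_d = tau_d, f0 = f0,
            kappa_s = kappa_s, beta_max = beta_max, alpha_s = alpha_s,
            x_s = x_s, tau_w = tau_w, n_init_units = as.integer(n_init_units))
  stopifnot(p$tau_r > 0, p$tau_f > 0, p$tau_d > 0, p$tau_w > 0,
            p$i_theta_min < p$i_theta_max, p$w_rec_min < p$w_rec_max,
            p$f0 > 0, p$f0 < 1)
  structure(p, class = "network_params")
}

#' Rhythmic theta drive
#'
#' Common excitation/inhibition to all units as a function of theta phase:
#' maximal inhibition (`i_theta_min`) at theta = 0, near-maximal excitation
#' (close to `i_theta_max`) around theta = pi.
#'
#' @param theta Theta phase (radians); vectorized.
#' @param p A [network_params()].
#' @return Drive value(s).
#' @export
theta_drive <- function(theta, p) {
  -(p$i_theta_max - p$i_theta_min) *
    exp(p$kappa_theta * cos(theta)) / exp(p$kappa_theta) + p$i_theta_max
}

#' Theta gate on spatial input and plasticity
#'
#' A bump of the theta cycle peaking at theta = pi/2 (value 1), defining the
#' window early in each cycle in which spatial inputs arrive and input
#' synapses are effectively plastic.
#'
#' @inheritParams theta_drive
#' @return Gate value(s) in (0, 1].
#' @export
theta_gate <- function(theta, p) {
  exp(p$kappa_s * sin(theta)) / exp(p$kappa_s)
}

#' Logistic activation function
#'
#' @param x Input(s).
#' @param alpha Gain.
#' @param x0 Threshold (midpoint).
#' @return Value(s) in (0, 1).
#' @export
logistic <- function(x, alpha, x0) {
  1 / (1 + exp(-alpha * (x - x0)))
}

#' Asymmetric recurrent weight matrix
#'
#' Gaussian connectivity kernel over unit-index distance, its peak shifted by
#' `delta` towards higher-index postsynaptic units, on a global inhibitory
#' baseline `w_rec_min`. The asymmetry makes activity bumps travel towards
#' increasing unit indices.
#'
#' @param p A [network_params()].
#' @return An `n_units` x `n_units` matrix; entry `[i, j]` is the weight from
#'   unit `j` to unit `i`.
#' @export
recurrent_weights <- function(p) {
  idx <- seq_len(p$n_units)
  diffs <- outer(idx, idx, "-") # i - j
  (p$w_rec_max - p$w_rec_min) *
    exp(-(diffs - p$delta)^2 / (2 * p$sigma_rec^2)) + p$w_rec_min
}

#' One Euler step of short-term facilitation and depression
#'
#' Facilitation builds slowly with presynaptic activity towards
#' `(s + f0)/(1 + s)` and depression tracks activity quickly towards `s`,
#' where `s = sigma_r(r)` is the unit's activation.
#'
#' @param f,d Facilitation and depression vectors.
#' @param sigma_r_of_r Activation `sigma_r(r)` per unit.
#' @param p A [network_params()].
#' @param dt Time step (s).
#' @return List with updated `f` and `d`.
#' @export
stp_step <- function(f, d, sigma_r_of_r, p, dt) {
  list(f = f + dt / p$tau_f * (-f + (1 - f) * sigma_r_of_r + p$f0),
       d = d + dt / p$tau_d * (-d + sigma_r_of_r))
}

#' Gated spatial input
#'
#' `i_ext = beta_max * beta_theta * sigma_s(W_s s)`: the plastic input
#' weights read out the feature vector at the rat's position, pass through
#' the dendritic nonlinearity, and are gated by the theta window.
#'
#' @param s Feature vector at the current position.
#' @param W_s Unit x feature weight matrix.
#' @param theta Theta phase (radians).
#' @param p A [network_params()].
#' @return Per-unit non-negative input vector.
#' @export
external_input <- function(s, W_s, theta, p) {
  if (ncol(W_s) != length(s)) stop("feature/weight shape mismatch")
  p$beta_max * theta_gate(theta, p) *
    logistic(drop(W_s %*% s), p$alpha_s, p$x_s)
}

#' Lap-initialization current
#'
#' At the beginning of each lap the first `n_init_units` units receive
#' `beta_theta` for the duration of one theta cycle (measured as lap-elapsed
#' time), seeding the activity bump at the start of the unit sequence.
#'
#' @param theta Theta phase (radians).
#' @param step_in_lap Zero-based step index within the current lap.
#' @param p A [network_params()].
#' @param theta_freq Theta frequency (Hz).
#' @param dt Time step (s).
#' @return Per-unit input vector.
#' @export
init_current <- function(theta, step_in_lap, p, theta_freq = 8, dt = 0.001) {
  out <- numeric(p$n_units)
  if (step_in_lap * dt < 1 / theta_freq) {
    out[seq_len(p$n_init_units)] <- theta_gate(theta, p)
  }
  out
}

#' One Euler step of the network activation and its short-term plasticity
#'
#' Updates the activation `r` using the pre-update facilitation, depression
#' and activation, then advances facilitation and depression with the
#' pre-update activation.
#'
#' @param state List with `r`, `f`, `d`.
#' @param drive List with scalars/vectors `i_theta`, `i_init`, `i_ext`.
#' @param W_rec Recurrent weight matrix.
#' @param p A [network_params()].
#' @param dt Time step (s).
#' @return Updated state list (plus `sigma_r_pre`, the activation used for
#'   the update).
#' @export
network_step <- function(state, drive, W_rec, p, dt) {
  if (any(!is.finite(state$r))) stop("network state is non-finite")
  srr <- logistic(state$r, p$alpha_r, p$x_r)
  syn <- drop(W_rec %*% ((1 - state$d) * state$f * srr))
  r_new <- state$r + dt / p$tau_r *
    (-state$r + drive$i_theta + syn + drive$i_init + drive$i_ext)
  fd <- stp_step(state$f, state$d, srr, p, dt)
  list(r = r_new, f = fd$f, d = fd$d, sigma_r_pre = srr)
}

#' One Euler step of the gated Hebbian input-weight update
#'
#' `tau_w dW_s/dt = beta_theta * (sigma_r(r) - i_ext) (x) s`, oriented
#' unit x feature. The subtraction of `i_ext` limits weight growth to the
#' level needed to match the bounded unit activity.
#'
#' @param W_s Unit x feature weight matrix.
#' @param s Feature vector.
#' @param sigma_r_of_r Post-update activation per unit.
#' @param i_ext Per-unit spatial input of the current step.
#' @param beta_theta Theta gate value.
#' @param p A [network_params()].
#' @param dt Time step (s).
#' @return Updated weight matrix.
#' @export
plasticity_step <- function(W_s, s, sigma_r_of_r, i_ext, beta_theta, p, dt) {
  W_s + (dt / p$tau_w) * beta_theta * tcrossprod(sigma_r_of_r - i_ext, s)
}

# pure-R reference integration loop, assembled from the exported step
# primitives; used to validate the compiled loop on short runs
simulate_network_r <- function(traj, bank, p, theta_freq = 8,
                               store_stp = FALSE) {
  n <- p$n_units
  T_ <- nrow(traj)
  dt <- attr(traj, "track")$dt
  W_rec <- recurrent_weights(p)
  W_s <- matrix(0, n, nrow(bank$values))
  state <- list(r = numeric(n), f = rep(p$f0, n), d = numeric(n))
  sigma <- matrix(0, n, T_)
  iext <- matrix(0, n, T_)
  ftr <- if (store_stp) matrix(0, n, T_)
  dtr <- if (store_stp) matrix(0, n, T_)
  cur_lap <- -1L
  lap_start <- 1L
  for (t in seq_len(T_)) {
    if (traj$lap_id[t] != cur_lap) {
      cur_lap <- traj$lap_id[t]
      lap_start <- t
      state <- list(r = numeric(n), f = rep(p$f0, n), d = numeric(n))
    }
    th <- traj$theta_phase[t]
    s <- features_at(bank, traj$x[t])
    i_ext <- external_input(s, W_s, th, p)
    drive <- list(i_theta = theta_drive(th, p),
                  i_init = init_current(th, t - lap_start, p, theta_freq, dt),
                  i_ext = i_ext)
    state <- network_step(state, drive, W_rec, p, dt)
    srr_new <- logistic(state$r, p$alpha_r, p$x_r)
    W_s <- plasticity_step(W_s, s, srr_new, i_ext, theta_gate(th, p), p, dt)
    sigma[, t] <- srr_new
    iext[, t] <- i_ext
    if (store_stp) {
      ftr[, t] <- state$f
      dtr[, t] <- state$d
    }
  }
  out <- list(sigma = sigma, i_ext = iext, W_s = W_s)
  if (store_stp) {
    out$f <- ftr
    out$d <- dtr
  }
  out
}

#' Run the full closed-loop network simulation
#'
#' Integrates the network along a pre-generated trajectory. At the beginning
#' of each lap `r` and `d` are reset to 0 and `f` to `f0`, and the first
#' `n_init_units` units receive the initialization current for one theta
#' cycle; the plastic input weights `W_s` start at 0 and persist across laps.
#'
#' @param traj A trajectory from [simulate_trajectory()].
#' @param bank A feature bank from [generate_features()].
#' @param p A [network_params()].
#' @param engine `"cpp"` (compiled loop, default) or `"r"` (reference loop
#'   assembled from the exported step primitives; slow, for validation).
#' @param store_stp If `TRUE`, also store per-step facilitation and
#'   depression traces (memory-heavy).
#' @return An object of class `network_run`: list with `trajectory`, `sigma`
#'   (units x steps activation `sigma_r(r)`), `i_ext` (units x steps spatial
#'   input), `W_s` (final input weights), `params`, `theta_freq`, and
#'   optionally `f`, `d`.
#' @export
run_simulation <- function(traj, bank, p = network_params(),
                           engine = c("cpp", "r"), store_stp = FALSE) {
  engine <- match.arg(engine)
  theta_freq <- attr(traj, "theta_freq")
  track <- attr(traj, "track")
  stopifnot(!is.null(theta_freq), !is.null(track))
  if (engine == "cpp") {
    out <- simulate_network_cpp(traj$x, traj$theta_phase, traj$lap_id,
                                bank$values, bank$bin_size,
                                recurrent_weights(p), unclass(p), track$dt,
                                theta_freq, store_stp)
  } else {
    out <- simulate_network_r(traj, bank, p, theta_freq, store_stp)
  }
  out$trajectory <- traj
  out$params <- p
  out$theta_freq <- theta_freq
  class(out) <- "network_run"
  out
}

#' @export
print.network_run <- function(x, ...) {
  cat(sprintf("network_run: %d units, %d steps (%.1f s), %d laps\n",
              nrow(x$sigma), ncol(x$sigma),
              ncol(x$sigma) * attr(x$trajectory, "track")$dt,
              max(x$trajectory$lap_id)))
  invisible(x)
}
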