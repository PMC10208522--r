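p <- network_params()

test_that("theta drive has the analytic extrema and waveform", {
  expect_equal(theta_drive(0, p), -1)                     # maximal inhibition
  expect_equal(theta_drive(pi, p), 1.6 - 2.6 * exp(-24))  # ~ peak excitation
  expect_equal(theta_drive(pi / 2, p), 1.6 - 2.6 * exp(-12))
  th <- seq(0, 2 * pi, length.out = 1000)
  expect_true(all(theta_drive(th, p) >= -1 - 1e-12))
  expect_true(all(theta_drive(th, p) <= 1.6 + 1e-12))
})

test_that("theta gate peaks at pi/2 with the analytic off-peak values", {
  expect_equal(theta_gate(pi / 2, p), 1)
  expect_equal(theta_gate(0, p), exp(-2))
  expect_equal(theta_gate(3 * pi / 2, p), exp(-4))
})

test_that("logistic nonlinearities hit their midpoints and gains", {
  expect_equal(logistic(0.5, p$alpha_r, p$x_r), 0.5)
  expect_equal(logistic(1, p$alpha_r, p$x_r), 1 / (1 + exp(-3)))
  expect_equal(logistic(0.7, p$alpha_s, p$x_s), 0.5)
})

test_that("recurrent weights are asymmetric with the printed values", {
  W <- recurrent_weights(p)
  expect_equal(dim(W), c(250, 250))
  # weight from j to i at offset i - j
  expect_equal(W[2, 1], 3.3 * exp(-0.16 / 50) - 2.8, tolerance = 1e-12)
  expect_equal(W[1, 1], 3.3 * exp(-0.36 / 50) - 2.8, tolerance = 1e-12)
  expect_gt(W[2, 1], W[1, 1]) # forward asymmetry
  expect_equal(W[1, 21], -2.8, tolerance = 1e-3) # far tail ~ w_rec_min
})

test_that("short-term plasticity has the analytic fixed points and Euler step", {
  # fixed points: f* = (s + f0)/(1 + s), d* = s
  for (s in c(0, 0.5, 1)) {
    fstar <- (s + p$f0) / (1 + s)
    upd <- stp_step(fstar, s, s, p, dt = 0.001)
    expect_equal(upd$f, fstar, tolerance = 1e-12)
    expect_equal(upd$d, s, tolerance = 1e-12)
  }
  # hand-computed single Euler step from baseline with full drive
  upd <- stp_step(0.14, 0, 1, p, dt = 0.001)
  expect_equal(upd$f, 0.14 + 0.001 / 0.32 * (-0.14 + 0.86 + 0.14))
  expect_equal(upd$d, 0.001 / 0.06)
})

test_that("external input is gated, bounded and shape-checked", {
  s <- rep(1, 8)
  W0 <- matrix(0, 4, 8)
  i0 <- external_input(s, W0, pi / 2, p)
  expect_equal(i0, rep(0.4 * 1 / (1 + exp(8.4)), 4))
  # saturated dendritic drive at the gate peak reaches beta_max
  Wbig <- matrix(10, 4, 8)
  expect_equal(external_input(s, Wbig, pi / 2, p), rep(0.4, 4),
               tolerance = 1e-6)
  th <- runif(20, 0, 2 * pi)
  for (t1 in th) expect_true(all(external_input(s, W0, t1, p) >= 0))
  expect_error(external_input(rep(1, 5), W0, 0, p), "mismatch")
})

test_that("initialization current targets the first five units for one cycle", {
  i1 <- init_current(pi / 2, step_in_lap = 50, p, theta_freq = 8, dt = 0.001)
  expect_equal(i1[1:5], rep(1, 5)) # beta_theta(pi/2) = 1
  expect_equal(i1[6:250], rep(0, 245))
  i2 <- init_current(pi / 2, step_in_lap = 200, p, theta_freq = 8, dt = 0.001)
  expect_equal(i2, rep(0, 250)) # 200 ms > one 125 ms cycle
})

test_that("plasticity update has the Hebbian structure and fixed points", {
  W <- matrix(0.1, 3, 4)
  s <- c(1, 0, -1, 0.5)
  # postsynaptic factor zero -> no change
  expect_equal(plasticity_step(W, s, rep(0.3, 3), rep(0.3, 3), 1, p, 0.001), W)
  # gate zero -> no change
  expect_equal(plasticity_step(W, s, rep(1, 3), rep(0, 3), 0, p, 0.001), W)
  # hand value: single unit/feature increment dt/tau_w
  W1 <- plasticity_step(matrix(0, 1, 1), 1, 1, 0, 1, p, 0.001)
  expect_equal(W1[1, 1], 0.001 / 20)
})

test_that("sustained inhibition shuts down network activity within 50 ms", {
  pp <- network_params(n_units = 50)
  W <- recurrent_weights(pp)
  state <- list(r = runif(50, 0, 1.5), f = rep(0.5, 50), d = rep(0.2, 50))
  drive <- list(i_theta = theta_drive(0, pp), i_init = 0, i_ext = 0)
  for (i in 1:50) state <- network_step(state, drive, W, pp, 0.001)
  expect_true(all(logistic(state$r, pp$alpha_r, pp$x_r) < 0.02))
})

test_that("network_step aborts on non-finite state", {
  pp <- network_params(n_units = 4)
  W <- recurrent_weights(pp)
  state <- list(r = c(NaN, 0, 0, 0), f = rep(0.14, 4), d = rep(0, 4))
  drive <- list(i_theta = 0, i_init = 0, i_ext = 0)
  expect_error(network_step(state, drive, W, pp, 0.001), "non-finite")
})

test_that("compiled and reference integration loops agree", {
  tr <- track_spec(length = 60, n_laps = 2)
  traj <- simulate_trajectory(tr, speed_profile(40, 60),
                              speed_noise_spec(kernel_std = 0.5), seed = 3)
  bank <- generate_features(tr, n_features = 16, seed = 4)
  pp <- network_params(n_units = 40)
  a <- run_simulation(traj, bank, pp, engine = "cpp", store_stp = TRUE)
  b <- run_simulation(traj, bank, pp, engine = "r", store_stp = TRUE)
  expect_equal(a$sigma, b$sigma, tolerance = 1e-10)
  expect_equal(a$i_ext, b$i_ext, tolerance = 1e-10)
  expect_equal(a$W_s, b$W_s, tolerance = 1e-10)
  expect_equal(a$f, b$f, tolerance = 1e-10)
  expect_equal(a$d, b$d, tolerance = 1e-10)
})

test_that("facilitation and depression stay within their physical bounds", {
  run <- tiny_run(store_stp = TRUE)
  expect_true(all(run$f >= 0 & run$f < 1))
  expect_true(all(run$d >= 0 & run$d <= 1))
  expect_true(all(run$sigma > 0 & run$sigma < 1))
  expect_true(all(is.finite(run$W_s)))
})

test_that("step halving changes cycle-integrated activations by < 1%, at first order", {
  sim_one_cycle <- function(dt) {
    tr <- track_spec(length = 80, n_laps = 1, dt = dt)
    traj <- simulate_trajectory(tr, speed_profile(30, 60), noise = NULL)
    keep <- traj$t <= 0.125 + 1e-12
    sub <- traj[keep, ]
    attr(sub, "track") <- tr
    attr(sub, "profile") <- attr(traj, "profile")
    attr(sub, "theta_freq") <- attr(traj, "theta_freq")
    class(sub) <- class(traj)
    bank <- generate_features(track_spec(length = 80, n_laps = 1),
                              n_features = 32, seed = 8)
    run_simulation(sub, bank, network_params(n_units = 80))
  }
  a <- sim_one_cycle(0.001)
  b <- sim_one_cycle(0.0005)
  c4 <- sim_one_cycle(0.00025)
  # integration accuracy is assessed on each unit's activation integrated
  # over the cycle: pointwise traces are intrinsically sensitive to bump
  # timing in a marginally stable attractor, the integral is not
  intg <- function(run, dt) rowSums(run$sigma) * dt
  e1 <- sqrt(sum((intg(a, 1e-3) - intg(b, 5e-4))^2)) /
    sqrt(sum(intg(b, 5e-4)^2))
  e2 <- sqrt(sum((intg(b, 5e-4) - intg(c4, 2.5e-4))^2)) /
    sqrt(sum(intg(c4, 2.5e-4)^2))
  expect_lt(e1, 0.01)
  # Richardson check: the error halves again with the next halving (O(dt))
  expect_gt(e1 / e2, 1.5)
  expect_lt(e1 / e2, 3)
})

test_that("population activity is theta-rhythmic at 8 Hz after warm-up", {
  run <- std_run()
  traj <- run$trajectory
  idx <- which(traj$t >= 60 & traj$t < 80)
  pop <- colSums(run$sigma[, idx])
  sp <- stats::spec.pgram(stats::ts(pop, frequency = 1000), plot = FALSE,
                          taper = 0, detrend = TRUE)
  peak_freq <- sp$freq[which.max(sp$spec)]
  expect_equal(peak_freq, 8, tolerance = 0.05)
})

test_that("activity bumps propagate forward within and across theta cycles", {
  run <- tiny_run()
  traj <- run$trajectory
  wraps <- c(1, which(diff(traj$theta_phase) < 0) + 1)
  lap2 <- wraps[traj$lap_id[wraps] == 2]
  com <- function(i) {
    s <- run$sigma[, i]
    if (max(s) > 0.3) sum(seq_along(s) * s) / sum(s) else NA_real_
  }
  # within-cycle: center of mass non-decreasing up to one-unit jitter
  viol <- 0; tot <- 0
  starts <- numeric(0)
  for (c0 in lap2[2:9]) {
    cms <- vapply(c0 + seq(0, 124, by = 5), com, numeric(1))
    cms <- cms[!is.na(cms)]
    if (length(cms) > 3) {
      viol <- viol + sum(diff(cms) < -1)
      tot <- tot + length(cms) - 1
      starts <- c(starts, cms[1])
    }
  }
  expect_lt(viol / tot, 0.05)
  # across-cycle: bump start index increases over successive cycles
  expect_gt(mean(diff(starts) > 0), 0.8)
})

test_that("early laps show time-cell behavior; late maps are spatially stable", {
  run <- std_run()
  traj <- run$trajectory
  # early laps (little learning): reach in the network grows with lap time
  early <- 1:4
  lap_dur <- tapply(traj$t, traj$lap_id, function(t) diff(range(t)))[early]
  reach <- vapply(early, function(l) {
    idx <- which(traj$lap_id == l)
    max(which(apply(run$sigma[, idx] > 0.5, 1, any)))
  }, numeric(1))
  expect_gt(cor(as.numeric(lap_dur), reach), 0)
  # late laps: per-unit activation maps correlate across successive two-lap
  # blocks (a single lap undersamples the 2 cm bins)
  lap_map <- function(l) {
    activation_map(run, "measured", steps = which(traj$lap_id %in% l))$values
  }
  n_laps <- max(traj$lap_id)
  m1 <- lap_map(n_laps - 3:2)
  m2 <- lap_map(n_laps - 1:0)
  active <- apply(m1, 1, max) > 0.2 & apply(m2, 1, max) > 0.2
  cors <- vapply(which(active), function(u) cor(m1[u, ], m2[u, ]), numeric(1))
  expect_gt(median(cors), 0.9)
})

test_that("bump advance across cycles scales with relative running speed", {
  run <- std_run()
  traj <- run$trajectory
  track <- attr(traj, "track")
  profile <- attr(traj, "profile")
  wraps <- c(1, which(diff(traj$theta_phase) < 0) + 1)
  late <- wraps[traj$t[wraps] > 80]
  # cycle-averaged bump center of mass and relative speed v / vbar
  st <- do.call(rbind, lapply(seq_len(length(late) - 1), function(i) {
    idx <- late[i]:(late[i + 1] - 1)
    s <- run$sigma[, idx]
    use <- apply(s, 2, max) > 0.3
    if (sum(use) < 20) return(NULL)
    cm <- sum(t(s[, use]) %*% seq_len(nrow(s))) / sum(s[, use])
    vrel <- mean(traj$v[idx] / target_speed(traj$x[idx], profile, track))
    data.frame(cm = cm, vrel = vrel, lap = traj$lap_id[idx[1]])
  }))
  adv <- diff(st$cm)
  ok <- diff(st$lap) == 0 & adv > -3 & adv < 12 # drop lap-reset jumps
  x <- st$vrel[-1][ok]
  y <- adv[ok]
  # average out per-cycle measurement jitter in deciles of relative speed
  qb <- cut(x, stats::quantile(x, seq(0, 1, 0.1)), include.lowest = TRUE)
  fit <- lm(tapply(y, qb, mean) ~ tapply(x, qb, mean))
  expect_gt(coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.5)
})
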