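# helper: wrap a units x bins matrix as an activation_map for field tests
as_map <- function(values, bin_size = 2, source = "measured") {
  n_bins <- ncol(values)
  structure(list(values = values, centers = (seq_len(n_bins) - 0.5) * bin_size,
                 bin_size = bin_size, occupancy = rep(1L, n_bins),
                 empty_bins = integer(), source = source, smoothing_sd = 0),
            class = "activation_map")
}

test_that("activation maps average the source signal per occupancy bin", {
  run <- synthetic_run(n_units = 3, track_len = 100, n_steps = 50000)
  # constant signal: every bin equals the constant, smoothing-invariant
  run_const <- run
  run_const$sigma <- matrix(0.5, nrow(run$sigma), ncol(run$sigma))
  m <- activation_map(run_const, "measured", warmup = 0)
  expect_equal(unname(m$values), matrix(0.5, 3, 50), tolerance = 1e-9)
  # localized signal: active only in [60, 70) -> spread limited by kernel
  run_loc <- run
  run_loc$sigma <- matrix(0, 1, ncol(run$sigma))
  run_loc$sigma[1, run$trajectory$x >= 60 & run$trajectory$x < 70] <- 1
  m2 <- activation_map(run_loc, "measured", warmup = 0)
  # meaningful spread is limited to ~4 bins beyond the active region
  nz <- which(m2$values[1, ] > 0.01)
  expect_true(all(m2$centers[nz] > 60 - 4 * 2 & m2$centers[nz] < 70 + 4 * 2))
  # the region center stays near 1 after smoothing (3 cm kernel)
  inside <- m2$centers > 64 & m2$centers < 66
  expect_true(all(m2$values[1, inside] > 0.85))
})

test_that("warm-up steps contribute nothing to the maps", {
  run <- synthetic_run(n_units = 2, track_len = 100, n_steps = 60000)
  run2 <- run
  pre <- run$trajectory$t < 30
  run2$sigma[, pre] <- 5 # corrupt the warm-up period
  m1 <- activation_map(run, "measured", warmup = 30)
  m2 <- activation_map(run2, "measured", warmup = 30)
  expect_identical(m1$values, m2$values)
})

test_that("spatial smoothing conserves total activation to < 1%", {
  run <- synthetic_run(n_units = 6, track_len = 100, n_steps = 60000)
  raw <- activation_map(run, "measured", smoothing_sd = 0, warmup = 0)
  sm <- activation_map(run, "measured", smoothing_sd = 3, warmup = 0)
  expect_equal(sum(sm$values), sum(raw$values), tolerance = 0.01)
})

test_that("field extraction recovers the analytic 10%-width of a Gaussian", {
  centers <- (1:100 - 0.5) * 2
  v <- 0.8 * exp(-(centers - 100)^2 / (2 * 25))
  f <- extract_fields(as_map(rbind(v)))
  expect_equal(nrow(f), 1)
  expect_true(f$complete)
  expect_equal(f$peak_pos, 100, tolerance = 0.5)
  expect_equal(f$size, 2 * 5 * sqrt(2 * log(10)), tolerance = 0.3)
})

test_that("field filters discard weak and cut-off fields", {
  centers <- (1:100 - 0.5) * 2
  weak <- 0.15 * exp(-(centers - 100)^2 / 50)
  expect_equal(nrow(extract_fields(as_map(rbind(weak)))), 0)
  # monotone rising profile: never drops below 50% on the right side
  cutoff <- 0.9 * plogis((centers - 150) / 10)
  expect_equal(nrow(extract_fields(as_map(rbind(cutoff)))), 0)
})

test_that("one-sided 10% crossings give doubled half-widths, incomplete", {
  centers <- (1:100 - 0.5) * 2
  # drops below 50% on both sides but below 10% only on the left
  v <- 0.8 * exp(-(centers - 150)^2 / (2 * 100))
  v[centers > 150] <- pmax(v[centers > 150], 0.2)
  f <- extract_fields(as_map(rbind(v)))
  expect_equal(nrow(f), 1)
  expect_false(f$complete)
  expect_true(is.na(f$end_pos))
  expect_equal(f$size, 2 * (f$peak_pos - f$start_pos))
})

test_that("identically-scaled true fields give zero shift", {
  run <- synthetic_run(n_units = 8, track_len = 100, n_steps = 60000)
  run$i_ext <- 0.3 * run$sigma
  m <- activation_map(run, "measured", warmup = 0)
  tm <- activation_map(run, "true", warmup = 0)
  mf <- extract_fields(m, 0.2)
  tf <- extract_fields(tm, 0)
  sh <- field_shifts(mf, tf, run$trajectory, warmup = 0)
  expect_gt(nrow(sh), 3)
  expect_equal(sh$shift, rep(0, nrow(sh)), tolerance = 1e-6)
})

test_that("orthogonal regression matches a brute-force oracle on steep clouds", {
  # noiseless line is recovered exactly
  x <- seq(10, 20, by = 0.5)
  y <- 360 - 10 * (x - 10)
  f <- odr_slope(x, y)
  expect_equal(f$slope, -10, tolerance = 1e-6)
  # near-vertical cloud: phase spans 300 degrees over 0.5 cm
  set.seed(42)
  xv <- 15 + runif(30, 0, 0.5)
  yv <- 600 * (xv - 15) + rnorm(30, 0, 5)
  fv <- odr_slope(xv, yv)
  oracle <- brute_odr(xv, yv)
  expect_equal(abs(fv$slope), abs(oracle$slope), tolerance = 0.05)
  expect_lte(fv$ossr, oracle$ossr * (1 + 1e-6))
  expect_gt(abs(fv$slope), 400) # OLS would flatten this to ~ a few deg/cm
  # independent cross-check against an established ODR implementation
  # (unweighted case; the in-package fitter additionally supports weights)
  ref <- pracma::odregress(cbind(xv), yv)
  expect_equal(fv$slope, ref$coeff[1], tolerance = 1e-6)
  # weighted fit agrees with the weighted oracle
  w <- runif(30, 0.1, 1)
  fw <- odr_slope(xv, yv, weights = w)
  ow <- brute_odr(xv, yv, w)
  expect_lte(fw$ossr, ow$ossr * (1 + 1e-6))
})

test_that("phase precession fitting recovers a synthetic precessing unit", {
  # build a phase map with activation along phase = 340 - 8 * (pos - x0)
  pos_centers <- (1:50 - 0.5) * 2
  ph_centers <- (1:18 - 0.5) * 20
  x0 <- 40
  vals <- array(0, c(1, 50, 18))
  for (b in which(pos_centers >= x0 & pos_centers <= x0 + 40)) {
    target <- 340 - 8 * (pos_centers[b] - x0)
    ph_idx <- which.min(abs(ph_centers - (target %% 360)))
    vals[1, b, ph_idx] <- 1
  }
  pmap <- structure(list(values = vals, pos_centers = pos_centers,
                         phase_centers = ph_centers, pos_bin = 2,
                         phase_bin = 20), class = "phase_map")
  fields <- data.frame(unit = 1, peak_pos = x0 + 20, peak_val = 1,
                       start_pos = x0, end_pos = x0 + 40, size = 40,
                       complete = TRUE)
  sl <- phase_precession_slopes(pmap, fields)
  expect_equal(nrow(sl), 1)
  expect_equal(sl$slope, -8, tolerance = 0.8)
  expect_lt(sl$slope, 0)
})

test_that("speed-conditioned ratios are exactly 1 for speed-invariant activity", {
  run <- synthetic_run(n_units = 10, track_len = 100, n_steps = 80000,
                       width = 5)
  # impose speed variability uncorrelated with the activation (which is a
  # pure function of position)
  set.seed(3)
  n <- nrow(run$trajectory)
  run$trajectory$v <- 25 * (1 + 0.4 * sin(seq_len(n) / 3000) + 0.1)
  rat <- instantaneous_speed_ratios(run, warmup = 0)
  expect_gt(nrow(rat), 2)
  expect_equal(rat$size_ratio, rep(1, nrow(rat)), tolerance = 0.05)
})

test_that("field density counts peaks in sliding windows", {
  tr <- track_spec(length = 30)
  pf <- speed_profile(10, 20)
  fields <- data.frame(unit = 1:3, peak_pos = c(3, 5, 9), peak_val = 1,
                       start_pos = 1, end_pos = 10, size = 9,
                       complete = TRUE)
  d <- field_density(fields, pf, tr, window = 10, stride = 2)
  expect_equal(d$count[d$window_start == 0], 3)
  expect_equal(d$count[d$window_start == 10], 0)
  expect_equal(nrow(d), length(seq(0, 20, by = 2)))
  # mean speed of the first window on the rising leg of the profile
  expect_equal(d$mean_speed[1], mean(target_speed(seq(0.05, 9.95, 0.1), pf, tr)),
               tolerance = 1e-9)
})
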