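# hand-built trace: perturbation at t = 0 (index 1), 20 s at 50 Hz
make_trace <- function(x, y = x, fs = 50) {
  n <- length(x)
  balance_trace((seq_len(n) - 1) / fs, x, y, fs = fs, pert_index = 1L)
}

test_that("threshold is zero for a flat tail and equals a pure sine amplitude", {
  n <- 20 * 50 + 1
  flat <- make_trace(rep(3.7, n))  # constant (offset) trace
  expect_equal(compute_threshold(flat), 0)
  t <- (seq_len(n) - 1) / 50
  a <- 0.8; c0 <- 5
  sine <- make_trace(c0 + a * sin(2 * pi * t))  # 1 Hz: whole cycles in the 7 s window
  thr <- compute_threshold(sine)
  # oracle: direct max over the window samples
  iw <- t >= 13 & t <= 20
  xw <- c0 + a * sin(2 * pi * t[iw])
  expect_equal(thr, max(abs(xw - mean(xw))))
  expect_equal(thr, a, tolerance = 0.01)
})

test_that("all four metrics are invariant to a constant channel offset", {
  tr <- generate_balance_trace(balance_sim_params(noise_sd = 0.02, seed = 9))
  sh <- tr
  sh$x <- sh$x + 12.3
  sh$y <- sh$y - 4.5
  m1 <- balance_metrics(tr); m2 <- balance_metrics(sh)
  for (v in c("threshold", "time", "distance_x", "distance_y",
              "area_x", "area_y")) {
    expect_equal(m2[[v]], m1[[v]], tolerance = 1e-9)
  }
})

test_that("a too-short trace raises a window error", {
  tr <- generate_balance_trace(balance_sim_params(post_duration_s = 10))
  expect_error(compute_threshold(tr), "post-perturbation window")
})

test_that("settling time matches the log-envelope prediction on clean decay", {
  A <- 10; lam <- 0.4; f <- 1.5
  tr <- generate_balance_trace(balance_sim_params(amplitude = A, damping = lam,
                                                  freq = f, noise_sd = 0))
  thr <- compute_threshold(tr)
  tm <- compute_time(tr, thr)
  expect_true(attr(tm, "settled"))
  expect_equal(as.numeric(tm), log(A / thr) / lam, tolerance = 1 / f)
})

test_that("time is non-increasing in the threshold and handles the extremes", {
  tr <- generate_balance_trace(balance_sim_params(noise_sd = 0, seed = 2))
  thr <- compute_threshold(tr)
  ts <- vapply(c(0.5, 1, 2, 4) * max(thr, 0.01),
               function(th) as.numeric(compute_time(tr, th)), numeric(1))
  expect_true(all(diff(ts) <= 1e-9))
  # a trace that never exceeds the threshold settles immediately at its peak
  n <- 20 * 50 + 1
  quiet <- make_trace(rep(0, n))
  expect_equal(as.numeric(compute_time(quiet, 1)), 0)
  # a threshold below the final excursion never settles: flagged, time = 20 s
  ramp <- make_trace(seq(0, 20, length.out = n))
  tm <- compute_time(ramp, 1)
  expect_false(attr(tm, "settled"))
  expect_equal(as.numeric(tm), 20)
})

test_that("first-crossing mode reaches the threshold on the rising flank", {
  tr <- generate_balance_trace(balance_sim_params(amplitude = 10, noise_sd = 0))
  thr <- compute_threshold(tr)
  t_first <- as.numeric(compute_time(tr, thr, mode = "first-crossing"))
  t_settle <- as.numeric(compute_time(tr, thr, mode = "settling"))
  expect_lt(t_first, 0.5)
  expect_gt(t_settle, t_first)
})

test_that("distance is exact total variation", {
  n <- 20 * 50 + 1
  ramp <- make_trace(c(seq(0, 5, length.out = 200), rep(5, n - 200)))
  expect_equal(compute_distance(ramp, n, "x"), 5)
  # one full sine cycle of amplitude a: distance = 4a within discretization
  t <- (seq_len(n) - 1) / 50
  a <- 2
  x <- ifelse(t <= 1, a * sin(2 * pi * t), 0)
  sine <- make_trace(x)
  expect_equal(compute_distance(sine, n, "x"), 4 * a, tolerance = 0.01 * 4 * a)
  # triangle inequality against the endpoint difference
  tr <- generate_balance_trace(balance_sim_params(noise_sd = 0.05, seed = 4))
  si <- nrow(tr)
  expect_gte(compute_distance(tr, si, "x"),
             abs(tr$x[si] - tr$x[attr(tr, "pert_index")]))
  expect_error(compute_distance(ramp, 1, "x"), "after the perturbation")
})

test_that("area is exact for a rectangular pulse and zero for flat signal", {
  n <- 20 * 50 + 1
  flat <- make_trace(rep(0, n))
  expect_equal(compute_area(flat, n, "x"), 0)
  h <- 3; w <- 2  # pulse height and width in seconds
  t <- (seq_len(n) - 1) / 50
  pulse <- make_trace(ifelse(t >= 1 & t < 1 + w, h, 0))
  expect_equal(compute_area(pulse, n, "x"), h * w, tolerance = h / 50)
  # signed variant cancels a symmetric oscillation
  x <- ifelse(t <= 2, sin(2 * pi * t), 0)
  osc <- make_trace(x)
  expect_lt(abs(compute_area(osc, n, "x", signed = TRUE)), 0.02)
  expect_equal(compute_area(osc, n, "x"), 4 / pi, tolerance = 0.01)
})

test_that("distance and area are stable under doubling the sampling rate", {
  for (fs in c(50, 100)) {
    p <- balance_sim_params(fs = fs, amplitude = 10, damping = 0.5,
                            freq = 1.5, noise_sd = 0)
    tr <- generate_balance_trace(p)
    m <- balance_metrics(tr)
    if (fs == 50) m50 <- m else m100 <- m
  }
  expect_equal(m100$distance_x, m50$distance_x, tolerance = 0.01)
  expect_equal(m100$area_x, m50$area_x, tolerance = 0.01)
})

test_that("aggregation averages trials per leg then legs per subject", {
  one <- balance_metrics(generate_balance_trace(balance_sim_params(seed = 1)))
  trials <- do.call(rbind, lapply(1:4, function(i) one))
  trials$leg <- c("left", "left", "right", "right")
  trials$direction <- c("medial", "lateral", "medial", "lateral")
  agg <- aggregate_trials(trials)
  expect_equal(agg$subject$threshold, one$threshold)
  # hand-set leg means (2, 4) average to 3
  trials$time <- c(2, 2, 4, 4)
  expect_equal(aggregate_trials(trials)$subject$time, 3)
  # permuting trial order never changes the aggregate
  perm <- trials[c(3, 1, 4, 2), ]
  expect_equal(aggregate_trials(perm)$subject, aggregate_trials(trials)$subject)
  # a missing (leg, direction) pair is reported by name
  expect_error(aggregate_trials(trials[-2, ]), "left, lateral")
})
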