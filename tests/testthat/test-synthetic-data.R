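test_that("thinning sampler matches Poisson expectations and honours its contract", {
  expect_identical(sample_inhomogeneous_poisson(function(t) 0 * t, 0, 10, 0),
                   numeric())
  expect_error(
    sample_inhomogeneous_poisson(function(t) 50 + 0 * t, 0, 1, 10),
    "thinning bound")

  set.seed(101)
  counts <- replicate(2000, length(
    sample_inhomogeneous_poisson(function(t) 20 + 0 * t, 0, 1, 25)))
  # closed-form Poisson mean 20, SE of the mean over 2000 draws = sqrt(20/2000)
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 2000))
  # variance should match the mean for a Poisson count
  expect_lt(abs(var(counts) - 20), 4 * sqrt(2 * 20^2 / 2000) + 2)
})

test_that("refractory deletion matches the sequential reference rule", {
  set.seed(7)
  for (i in 1:20) {
    spikes <- sort(runif(300, 0, 1))
    got <- sample_inhomogeneous_poisson(function(t) 200 + 0 * t, 0, 1, 200,
                                        refractory_ms = 5)
    expect_true(all(diff(got) >= 0.005))
    # cross-check the deletion rule itself on an arbitrary train
    expect_identical(icdyn:::apply_refractory(spikes, 0.004),
                     brute_refractory(spikes, 0.004))
  }
})

test_that("simulated choices follow the psychometric law", {
  d <- oddball_design()
  # degenerate limits
  b_sharp <- behavior_model(psy_a = 1.3, psy_b = 1e-9)
  set.seed(1)
  ch <- replicate(10, simulate_choice(b_sharp, 4, d)$choice)  # r = 2.0 >> a
  expect_true(all(ch == "press"))
  b_nolapse <- behavior_model(lapse_press_control = 0)
  ch0 <- replicate(10, simulate_choice(b_nolapse, 0, d)$choice)
  expect_true(all(ch0 == "no_press"))

  # press fraction at level 4 matches the closed-form normal CDF value
  b <- behavior_model(psy_a = 1.3, psy_b = 0.15)
  set.seed(2)
  f <- mean(replicate(1e4, simulate_choice(b, 4, d)$choice == "press"))
  expect_lt(abs(f - psychometric_eval(1.3, 0.15, d$lambda^4)), 0.02)

  # press times stay inside the response window
  set.seed(3)
  rts <- replicate(200, simulate_choice(b_sharp, 4, d)$rt_s)
  expect_true(all(rts > 0 & rts < 0.6))
})

test_that("sessions are reproducible from their seed", {
  s1 <- tiny_oddball(seed = 21)
  s2 <- tiny_oddball(seed = 21)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_session(s1, p1); write_session(s2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  s3 <- tiny_oddball(seed = 22)
  expect_false(identical(s1$spike_times, s3$spike_times))

  r1 <- suppressWarnings(simulate_reward_session(seed = 21))
  r2 <- suppressWarnings(simulate_reward_session(seed = 21))
  expect_identical(r1$spike_times, r2$spike_times)
})

test_that("windowed spike counts match the generating rate integral", {
  # the module's master oracle: empirical counts against quadrature of the
  # exact rate function rebuilt from stored ground truth
  s <- tiny_oddball(seed = 31, n_blocks_per_level = 4)
  fn <- session_rate_fn(s)
  total <- oddball_total_count(s)
  expect_lt(abs(length(s$spike_times) - total) / sqrt(total), 4)

  # per-sound late windows, pooled: deviants carry the climbing ramp
  ev <- s$events[s$events$role == "deviant", ]
  off <- ev$onset_s + ev$duration_ms / 1000
  obs <- sum(vapply(off, function(t) count_in(s$spike_times, t - 0.1, t), 0))
  exp_ <- sum(vapply(off, function(t) expected_count(fn, t - 0.1, t), 0))
  expect_lt(abs(obs - exp_) / sqrt(exp_), 4)

  r <- suppressWarnings(simulate_reward_session(seed = 31))
  fnr <- session_rate_fn(r)
  rw <- r$trials$reward_time_s[!is.na(r$trials$reward_time_s)]
  obs_r <- sum(vapply(rw, function(t) count_in(r$spike_times, t, t + 0.2), 0))
  exp_r <- sum(vapply(rw, function(t) expected_count(fnr, t, t + 0.2), 0))
  expect_lt(abs(obs_r - exp_r) / sqrt(exp_r), 4)
})

test_that("climb slope profile is zero at order 1, nondecreasing, saturated", {
  rm <- rate_model(climb_slope_max_hz_per_s = 40, climb_saturation_order = 4)
  sl <- climb_slope(rm, 1:7)
  expect_identical(sl[1], 0)
  expect_true(all(diff(sl) >= 0))
  expect_true(all(sl[4:7] == 40))
})

test_that("reward surprise multiplier handles its limits and decay structure", {
  r <- suppressWarnings(simulate_reward_session(
    surprise_decay_trials = Inf, seed = 9))
  fn <- session_rate_fn(r)
  rw <- r$trials$reward_time_s[!is.na(r$trials$reward_time_s)]
  peaks <- fn(rw + 1e-6) - fn(rw - 1e-6)  # transient jump at delivery
  expect_equal(max(peaks) - min(peaks), 0, tolerance = 1e-9)

  r0 <- suppressWarnings(simulate_reward_session(
    surprise_decay_trials = 0, seed = 9))
  fn0 <- session_rate_fn(r0)
  peaks0 <- fn0(rw + 1e-6) - fn0(rw - 1e-6)
  expect_gt(peaks0[1], peaks0[2] * 1.5)       # gain confined to first reward
  expect_equal(max(peaks0[-1]) - min(peaks0[-1]), 0, tolerance = 1e-9)

  r5 <- suppressWarnings(simulate_reward_session(
    surprise_decay_trials = 5, seed = 9))
  fn5 <- session_rate_fn(r5)
  peaks5 <- fn5(rw + 1e-6) - fn5(rw - 1e-6)
  expect_true(all(diff(peaks5) < 0))          # strictly decaying surprise
})

test_that("a silent rate model yields baseline-only reward-window rates", {
  rm <- rate_model(onset_peak_hz = 0, sustained_hz = 0,
                   climb_slope_max_hz_per_s = 0, reward_peak_hz = 0)
  r <- suppressWarnings(simulate_reward_session(rate = rm, seed = 13))
  rw <- r$trials$reward_time_s[!is.na(r$trials$reward_time_s)]
  rate <- mean(windowed_rate(r$spike_times, rw, window_preset("reward_post_100")))
  se <- sqrt(10 / (length(rw) * 0.1))
  expect_lt(abs(rate - 10), 3 * se)
})

test_that("every simulated session passes validation", {
  for (seed in 1:3) {
    expect_s3_class(suppressWarnings(validate_session(
      tiny_oddball(seed = seed))), "icdyn_session")
    expect_s3_class(suppressWarnings(validate_session(
      simulate_reward_session(seed = seed))), "icdyn_session")
  }
})
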