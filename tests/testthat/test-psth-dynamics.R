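test_that("psth bins single-trial spikes exactly and validates its grid", {
  w <- analysis_window("sound_onset", 0, 100)
  p <- compute_psth(c(0.01), anchor_times_s = 0, window = w, bin_ms = 20,
                    smoothing_sigma_ms = 0)
  expect_equal(p$rate_hz, c(50, 0, 0, 0, 0))
  expect_equal(nrow(p), 5)
  expect_error(compute_psth(0.01, 0, w, bin_ms = 30), "does not divide")
})

test_that("psth of a homogeneous train is flat at the true rate", {
  set.seed(5)
  train <- sample_inhomogeneous_poisson(function(t) 20 + 0 * t, 0, 600, 25)
  anchors <- seq(0.5, 598, by = 1.2)[1:450]
  w <- analysis_window("sound_onset", 0, 200)
  p <- compute_psth(train, anchors, w, bin_ms = 20, smoothing_sigma_ms = 0)
  se <- sqrt(20 / (length(anchors) * 0.02))
  expect_true(all(abs(p$rate_hz - 20) < 3.5 * se))
})

test_that("gaussian smoothing preserves the rate integral", {
  set.seed(8)
  train <- sort(runif(400, 0, 2))
  w <- analysis_window("sound_onset", -100, 400)
  raw <- compute_psth(train, c(0.5, 1.0, 1.5), w, bin_ms = 10,
                      smoothing_sigma_ms = 0)
  sm <- compute_psth(train, c(0.5, 1.0, 1.5), w, bin_ms = 10,
                     smoothing_sigma_ms = 15)
  expect_equal(sum(sm$rate_hz), sum(raw$rate_hz), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(sm$rate_hz, raw$rate_hz)))
})

test_that("RDI reproduces its defining arithmetic and conventions", {
  # 600 ms sound at onset 0: 1 spike in [100,200) ms, 3 in [500,600) ms
  r <- compute_rdi(c(0.15, 0.52, 0.55, 0.58), onset_s = 0, duration_ms = 600)
  expect_equal(r$fir_after_peak_hz, 10)
  expect_equal(r$fir_late_hz, 30)
  expect_equal(r$rdi, 0.5)
  # equal rates -> 0; empty train -> 0 by convention
  expect_equal(compute_rdi(c(0.15, 0.55), 0, 600)$rdi, 0)
  expect_equal(compute_rdi(numeric(), 0, 600)$rdi, 0)
  expect_error(compute_rdi(0.1, 0, 250), "overlap")
})

test_that("RDI is scale-invariant and bounded in [-1, 1]", {
  set.seed(12)
  for (i in 1:25) {
    train <- sort(runif(rpois(1, 40), 0, 0.7))
    r1 <- compute_rdi(train, 0, 600)
    # tripling every spike scales both window rates by 3
    r3 <- compute_rdi(sort(rep(train, 3)), 0, 600)
    expect_equal(r3$rdi, r1$rdi)
    expect_lte(abs(r1$rdi), 1)
    # matches the defining formula directly
    expect_equal(r1$rdi, with(r1, ifelse(fir_late_hz + fir_after_peak_hz > 0,
      (fir_late_hz - fir_after_peak_hz) / (fir_late_hz + fir_after_peak_hz), 0)))
  }
})

test_that("per-trial RDI centres on zero when the rate is flat", {
  rm <- rate_model(onset_peak_hz = 0, sustained_hz = 0,
                   climb_slope_max_hz_per_s = 0, reward_peak_hz = 0,
                   baseline_hz = 30)
  s <- tiny_oddball(seed = 17, n_blocks_per_level = 20, rate = rm)
  r <- session_rdi(s, role = "final")
  se <- sd(r$rdi) / sqrt(nrow(r))
  expect_lt(abs(mean(r$rdi)), 3 * se)
})

test_that("order profile is flat under a flat rate and normalised to order 1", {
  rm <- rate_model(onset_peak_hz = 0, sustained_hz = 0,
                   climb_slope_max_hz_per_s = 0, reward_peak_hz = 0,
                   baseline_hz = 50)
  s <- tiny_oddball(seed = 19, n_blocks_per_level = 20, rate = rm)
  prof <- order_profile(s, window_preset("late"), max_order = 7)
  expect_equal(prof$normalized[prof$order == 1], 1)
  expect_true(all(abs(prof$normalized - 1) < 0.25))

  p1 <- order_profile(s, window_preset("late"), max_order = 1)
  expect_equal(nrow(p1), 1)
  expect_identical(p1$normalized, 1)
})

test_that("onset adaptation shows in the onset profile but not the late one", {
  rm <- rate_model(onset_first_scale = 2, climb_slope_max_hz_per_s = 0,
                   reward_peak_hz = 0)
  s <- tiny_oddball(seed = 23, n_blocks_per_level = 20, rate = rm)
  on_prof <- order_profile(s, window_preset("onset"), max_order = 5)
  expect_true(all(on_prof$normalized[on_prof$order >= 2] < 0.9))
  late_prof <- order_profile(s, window_preset("late"), max_order = 5)
  expect_true(all(abs(late_prof$normalized - 1) < 0.3))
})

test_that("order profile demands data beyond order 1", {
  s <- tiny_oddball(seed = 3)
  s$events <- s$events[s$events$order_index == 1, ]
  expect_error(order_profile(s, window_preset("late")), "insufficient data")
})

test_that("climbing raises RDI: behaviour-like vs passive-like paired sessions", {
  mean_dev_rdi <- function(s) {
    r <- session_rdi(s, role = "final")
    mean(r$rdi[r$deviant_level_n > 0])
  }
  diffs <- vapply(1:80, function(seed) {
    on <- tiny_oddball(seed = seed, n_blocks_per_level = 16,
                       rate = rate_model(climb_slope_max_hz_per_s = 40))
    off <- tiny_oddball(seed = seed, n_blocks_per_level = 16,
                        rate = rate_model(climb_slope_max_hz_per_s = 0))
    mean_dev_rdi(on) - mean_dev_rdi(off)
  }, numeric(1))
  expect_gte(mean(diffs > 0), 0.95)
})
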