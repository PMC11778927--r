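# Independent oracles used across tests. These deliberately use the dumbest
# correct construction (pair enumeration, quadrature, sequential loops) so
# they share no code with the implementation they check.

# ROC area by explicit enumeration of all pairs, ties at half weight
brute_auc <- function(x, y) {
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  mean(cmp)
}

# cumulative-Gaussian press probability by adaptive quadrature of the
# integrand (normal density with mean a, sd b) from 0 to r
quad_psy <- function(a, b, r) {
  vapply(r, function(ri) {
    if (ri == 0) return(0)
    stats::integrate(function(x) stats::dnorm(x, mean = a, sd = b), 0, ri,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
  }, numeric(1))
}

# sequential dead-time deletion, one spike at a time
brute_refractory <- function(times, refr_s) {
  if (!length(times)) return(times)
  kept <- times[1]
  for (t in times[-1]) {
    if (t - kept[length(kept)] >= refr_s) kept <- c(kept, t)
  }
  kept
}

# expected spike count of a rate function over a window, by quadrature
expected_count <- function(rate_fn, t0, t1) {
  stats::integrate(rate_fn, t0, t1, subdivisions = 5000L,
                   rel.tol = 1e-8)$value
}

# closed-form expected total spike count of a simulated oddball session,
# written directly from the model definition (independent of build_rate_fn):
# baseline over the session, sustained + triangular ramp per sound, and
# truncated-exponential transients per onset/reward/press
oddball_total_count <- function(s) {
  rm <- s$meta$rate_model
  t_end <- max(s$meta$segments$t_end)
  ev <- s$events
  dur_s <- ev$duration_ms / 1000
  sat <- rm$climb_saturation_order
  slope <- rm$climb_slope_max_hz_per_s * pmin(ev$order_index - 1, sat - 1) / (sat - 1)
  ramp_len <- pmax(0, dur_s - rm$climb_start_ms / 1000)
  sounds <- sum(rm$sustained_hz * dur_s + slope * ramp_len^2 / 2)

  exp_integral <- function(t0, amp, tau) {
    span <- pmin(8 * tau, t_end - t0)
    sum(amp * tau * (1 - exp(-span / tau)))
  }
  onset_amp <- rm$onset_peak_hz * ifelse(ev$order_index == 1, rm$onset_first_scale, 1)
  b <- s$blocks
  rw <- b[!is.na(b$reward_time_s), ]
  rw_amp <- rm$reward_peak_hz *
    ifelse(rw$outcome == "correct_rejection", 1 + rm$reward_surprise_gain, 1)
  pr_t <- b$press_time_s[!is.na(b$press_time_s)]
  rm$baseline_hz * t_end + sounds +
    exp_integral(ev$onset_s, onset_amp, rm$onset_decay_ms / 1000) +
    exp_integral(rw$reward_time_s, rw_amp, rm$reward_decay_ms / 1000) +
    exp_integral(pr_t, rep(rm$motor_peak_hz, length(pr_t)), rm$motor_decay_ms / 1000)
}

count_in <- function(spikes, t0, t1) sum(spikes >= t0 & spikes < t1)

# small oddball session used by several structural tests
tiny_oddball <- function(seed = 42, n_blocks_per_level = 2, ...) {
  suppressWarnings(simulate_oddball_session(n_blocks_per_level = n_blocks_per_level,
                                            seed = seed, ...))
}
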