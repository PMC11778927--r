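#' Phenomenological firing-rate model
#'
#' Composite instantaneous-rate model for a simulated inferior-colliculus
#' unit. The rate at time `t` is the sum of:
#'
#' * a constant spontaneous `baseline_hz`;
#' * per sound, an onset transient `onset_peak_hz * exp(-t'/onset_decay_ms)`
#'   (`t'` from sound onset), a `sustained_hz` plateau while the sound is on,
#'   and a linear "climbing" ramp starting `climb_start_ms` after onset and
#'   truncated at sound offset, with slope [climb_slope()] depending on the
#'   sound's order within its block;
#' * per reward, a transient `amp * exp(-t'/reward_decay_ms)` whose amplitude
#'   is `reward_peak_hz`, multiplied by `1 + reward_surprise_gain` (scaled by
#'   an optional decay over trials) when the reward is unpredicted;
#' * per button press, a motor transient `motor_peak_hz * exp(-t'/motor_decay_ms)`
#'   (0 by default so decision analyses see press-free reward responses).
#'
#' Exponential transients are truncated at 8 decay constants, which makes the
#' model's stated `rate_max` an exact bound (events are far enough apart that
#' truncated transients never overlap their own kind). An absolute refractory
#' period is applied after sampling by deleting spikes closer than
#' `refractory_ms` to their (kept) predecessor.
#'
#' @param baseline_hz Spontaneous rate.
#' @param onset_peak_hz,onset_decay_ms Onset transient amplitude and decay.
#' @param onset_first_scale Multiplier on the order-1 onset transient (values
#'   above 1 emulate onset adaptation to repeated standards).
#' @param sustained_hz Plateau rate while a sound is on.
#' @param climb_slope_max_hz_per_s Saturating slope of the late-window ramp.
#' @param climb_saturation_order Order at which the ramp slope saturates.
#' @param climb_start_ms Ramp start relative to sound onset.
#' @param reward_peak_hz,reward_decay_ms Reward transient amplitude and decay.
#' @param reward_surprise_gain Extra fractional amplitude for unpredicted
#'   rewards.
#' @param motor_peak_hz,motor_decay_ms Press-locked transient.
#' @param refractory_ms Absolute refractory period.
#' @param rate_max_hz Stated upper bound on the instantaneous rate; `NULL`
#'   computes an exact bound when the model is laid onto a session.
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(baseline_hz = 10,
                       onset_peak_hz = 80, onset_decay_ms = 20,
                       onset_first_scale = 1,
                       sustained_hz = 20,
                       climb_slope_max_hz_per_s = 40,
                       climb_saturation_order = 4,
                       climb_start_ms = 100,
                       reward_peak_hz = 300, reward_decay_ms = 300,
                       reward_surprise_gain = 1,
                       motor_peak_hz = 0, motor_decay_ms = 100,
                       refractory_ms = 0,
                       rate_max_hz = NULL) {
  m <- list(baseline_hz = baseline_hz, onset_peak_hz = onset_peak_hz,
            onset_decay_ms = onset_decay_ms, onset_first_scale = onset_first_scale,
            sustained_hz = sustained_hz,
            climb_slope_max_hz_per_s = climb_slope_max_hz_per_s,
            climb_saturation_order = climb_saturation_order,
            climb_start_ms = climb_start_ms,
            reward_peak_hz = reward_peak_hz, reward_decay_ms = reward_decay_ms,
            reward_surprise_gain = reward_surprise_gain,
            motor_peak_hz = motor_peak_hz, motor_decay_ms = motor_decay_ms,
            refractory_ms = refractory_ms, rate_max_hz = rate_max_hz)
  rates <- c(baseline_hz, onset_peak_hz, sustained_hz, climb_slope_max_hz_per_s,
             reward_peak_hz, motor_peak_hz)
  stopifnot(all(rates >= 0), onset_decay_ms > 0, reward_decay_ms > 0,
            motor_decay_ms > 0, onset_first_scale >= 0, refractory_ms >= 0,
            climb_saturation_order >= 2, climb_start_ms >= 0,
            reward_surprise_gain >= 0)
  structure(m, class = "rate_model")
}

#' Climbing-ramp slope as a function of stimulus order
#'
#' Zero for the first sound of a block, rising linearly with order and
#' constant from `climb_saturation_order` on — the profile behind late-window
#' responses that grow over the first few standards and then plateau.
#'
#' @param rate A [rate_model()].
#' @param order 1-based stimulus order within the block (vectorised).
#' @return Slope(s) in Hz/s.
#' @export
climb_slope <- function(rate, order) {
  stopifnot(inherits(rate, "rate_model"), all(order >= 1))
  k <- rate$climb_saturation_order
  rate$climb_slope_max_hz_per_s * pmin(order - 1, k - 1) / (k - 1)
}

TRANSIENT_SPAN <- 8  # exponential transients truncated at 8 decay constants

# Components: sounds = tibble(onset_s, offset_s, order); transients =
# tibble(kind, time_s, amp_hz, tau_s). Returns a vectorised rate function of
# t (s). Sounds must be non-overlapping; transients of one kind must be
# spaced beyond 8 tau (true for the protocols simulated here), so at any t at
# most the nearest preceding event of each kind contributes.
build_rate_fn <- function(rate, sounds, transients) {
  cs <- rate$climb_start_ms / 1000
  sounds <- sounds[order(sounds$onset_s), ]
  slopes <- climb_slope(rate, sounds$order)
  kinds <- split(transients[order(transients$time_s), ], transients$kind[order(transients$time_s)])
  function(t) {
    r <- rep(rate$baseline_hz, length(t))
    if (nrow(sounds)) {
      i <- findInterval(t, sounds$onset_s)
      ok <- i > 0
      ii <- i[ok]
      inside <- t[ok] < sounds$offset_s[ii]
      add <- ifelse(inside, rate$sustained_hz, 0) +
        ifelse(inside & t[ok] >= sounds$onset_s[ii] + cs,
               slopes[ii] * (t[ok] - sounds$onset_s[ii] - cs), 0)
      r[ok] <- r[ok] + add
    }
    for (k in kinds) {
      i <- findInterval(t, k$time_s)
      ok <- i > 0
      ii <- i[ok]
      dt <- t[ok] - k$time_s[ii]
      act <- dt < TRANSIENT_SPAN * k$tau_s[ii]
      add <- ifelse(act, k$amp_hz[ii] * exp(-dt / k$tau_s[ii]), 0)
      r[ok] <- r[ok] + add
    }
    r
  }
}

# Exact instantaneous-rate bound for components built by build_rate_fn,
# assuming no two transients of the same kind overlap within 8 tau (holds for
# the protocols simulated here).
rate_bound <- function(rate, sounds, transients) {
  climb_max <- if (nrow(sounds)) {
    max(c(0, climb_slope(rate, sounds$order) *
            pmax(0, sounds$offset_s - sounds$onset_s - rate$climb_start_ms / 1000)))
  } else 0
  # transients of different kinds can coincide (press + reward + a tail);
  # same-kind transients are spaced beyond 8 tau, so sum the per-kind maxima
  trans_bound <- if (nrow(transients)) {
    sum(tapply(transients$amp_hz, transients$kind, max))
  } else 0
  rate$baseline_hz + rate$sustained_hz + climb_max + trans_bound
}

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Classical thinning: candidate spikes are drawn from a homogeneous Poisson
#' process at `rate_max_hz` on `[t0_s, t1_s)` and each candidate is kept with
#' probability `rate_fn(t)/rate_max_hz`. An absolute refractory period is then
#' applied by deleting any spike closer than `refractory_ms` to its kept
#' predecessor. The bound is spot-checked on a grid and on the candidates; a
#' rate function exceeding it is a contract error.
#'
#' @param rate_fn Vectorised function of time (s) returning rate in Hz.
#' @param t0_s,t1_s Interval bounds, `t1_s > t0_s`.
#' @param rate_max_hz Upper bound on `rate_fn` over the interval.
#' @param refractory_ms Absolute refractory period (ms).
#' @return Sorted spike times in `[t0_s, t1_s)`.
#' @examples
#' set.seed(1)
#' s <- sample_inhomogeneous_poisson(function(t) 20 + 0 * t, 0, 1, 25)
#' @export
sample_inhomogeneous_poisson <- function(rate_fn, t0_s, t1_s, rate_max_hz,
                                         refractory_ms = 0) {
  stopifnot(t1_s > t0_s, rate_max_hz >= 0)
  if (rate_max_hz == 0) return(numeric())
  grid <- seq(t0_s, t1_s, length.out = 257L)[-257L]
  n <- stats::rpois(1L, rate_max_hz * (t1_s - t0_s))
  cand <- sort(stats::runif(n, t0_s, t1_s))
  lam <- rate_fn(c(grid, cand))
  if (any(lam > rate_max_hz * (1 + 1e-9))) {
    stop("rate_fn exceeds rate_max_hz (", max(lam), " > ", rate_max_hz,
         "): thinning bound violated", call. = FALSE)
  }
  keep <- stats::runif(n) < lam[-seq_along(grid)] / rate_max_hz
  apply_refractory(cand[keep], refractory_ms / 1000)
}

# sequential dead-time deletion: drop any spike within refr of the last kept
apply_refractory <- function(times, refr_s) {
  if (refr_s <= 0 || length(times) < 2L) return(times)
  repeat {
    d <- diff(times)
    bad <- which(d < refr_s)
    if (!length(bad)) return(times)
    # drop the follower at the start of each violation run, then re-examine
    drop <- bad[c(TRUE, diff(bad) > 1L)] + 1L
    times <- times[-drop]
  }
}
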