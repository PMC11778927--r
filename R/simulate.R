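#' Behavioural model for the oddball task
#'
#' Press probability follows the cumulative-Gaussian psychometric law
#' [psychometric_eval()] evaluated at the deviant/standard duration ratio; on
#' control trials (level 0) the press probability is a lapse rate. Reaction
#' times are drawn from a normal truncated to the response window.
#'
#' @param psy_a Psychometric location, duration-ratio units.
#' @param psy_b Psychometric spread, ratio units (> 0).
#' @param lapse_press_control False-alarm probability on control trials.
#' @param rt_mean_ms,rt_sd_ms Reaction-time distribution after deviant offset,
#'   truncated to (0, response window).
#' @return An object of class `behavior_model`.
#' @export
behavior_model <- function(psy_a = 1.3, psy_b = 0.15,
                           lapse_press_control = 0.05,
                           rt_mean_ms = 300, rt_sd_ms = 80) {
  stopifnot(psy_b > 0, lapse_press_control >= 0, lapse_press_control <= 1,
            rt_sd_ms > 0)
  structure(list(psy_a = psy_a, psy_b = psy_b,
                 lapse_press_control = lapse_press_control,
                 rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms),
            class = "behavior_model")
}

#' Simulate one choice in the oddball task
#'
#' Bernoulli press draw at the psychometric probability for the block's
#' deviant level (lapse rate at level 0), with a truncated-normal reaction
#' time relative to the final sound's offset on press trials.
#'
#' @param behavior A [behavior_model()].
#' @param level_n Deviant level, a member of `design$levels_n`.
#' @param design An [oddball_design()].
#' @return List with `choice` (`"press"`/`"no_press"`) and `rt_s` (reaction
#'   time in seconds after deviant offset, `NA` for no-press).
#' @export
simulate_choice <- function(behavior, level_n, design) {
  stopifnot(inherits(behavior, "behavior_model"), inherits(design, "oddball_design"))
  if (!level_n %in% design$levels_n) stop("level_n outside design levels", call. = FALSE)
  p <- if (level_n == 0) {
    behavior$lapse_press_control
  } else {
    psychometric_eval(behavior$psy_a, behavior$psy_b, design$lambda^level_n)
  }
  press <- stats::runif(1) < p
  rt <- if (press) rtruncnorm1(behavior$rt_mean_ms, behavior$rt_sd_ms,
                               0, design$response_window_ms) / 1000 else NA_real_
  list(choice = if (press) "press" else "no_press", rt_s = rt)
}

# inverse-CDF truncated normal draw on (lo, hi), scalar
rtruncnorm1 <- function(mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(1, plo, phi), mean, sd)
}

# Deterministic per-block child seeds (< 2^31) so a session is reproducible
# block-by-block from its master seed.
child_seed <- function(master, index, stream = 0L) {
  x <- (as.double(master) %% 2147483647) + 1
  y <- (x * 48271 + index * 69621 + stream * 40692) %% 2147483647
  as.integer((y * 16807) %% 2147483647)
}

#' Simulate an oddball session
#'
#' Lays out `n_blocks_per_level` blocks per deviant level in randomised order.
#' Each block presents 3–6 standards (uniform) followed by the level's final
#' sound at the design's inter-stimulus interval; the choice comes from
#' [simulate_choice()]; hits are rewarded at the press, correct rejections at
#' `cr_reward_delay_ms` after the final sound's offset. Spikes are drawn from
#' the composite [rate_model()] by thinning, block by block under child seeds
#' derived from `seed`. The surprise gain applies to correct-rejection rewards
#' only (the unpredicted ones — the subject did not act to earn them).
#'
#' @param design An [oddball_design()].
#' @param rate A [rate_model()].
#' @param behavior A [behavior_model()].
#' @param n_blocks_per_level Blocks simulated per deviant level.
#' @param seed Master seed (integer).
#' @param cr_reward_delay_ms Reward latency after final-sound offset on
#'   correct rejections; defaults to the end of the response window.
#' @param inter_block_gap_s Silent gap after each block's response window.
#' @return A validated `icdyn_session` with the generating parameters in
#'   `$meta`.
#' @examples
#' s <- simulate_oddball_session(n_blocks_per_level = 2, seed = 1)
#' s
#' @export
simulate_oddball_session <- function(design = oddball_design(),
                                     rate = rate_model(),
                                     behavior = behavior_model(),
                                     n_blocks_per_level = 30,
                                     seed = 1,
                                     cr_reward_delay_ms = design$response_window_ms,
                                     inter_block_gap_s = 2.5) {
  stopifnot(n_blocks_per_level >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  set.seed(as.integer(seed))
  levels <- rep(design$levels_n, each = n_blocks_per_level)
  levels <- sample(levels)
  isi_s <- design$isi_ms / 1000
  resp_s <- design$response_window_ms / 1000

  blocks <- vector("list", length(levels))
  events <- vector("list", length(levels))
  t_cursor <- 0.5
  for (i in seq_along(levels)) {
    set.seed(child_seed(seed, i, 1L))
    lev <- levels[i]
    n_std <- sample(seq(design$n_standards_range[1], design$n_standards_range[2]), 1L)
    durs_ms <- c(rep(design$standard_duration_ms, n_std), deviant_duration(design, lev))
    onsets <- t_cursor + c(0, cumsum(durs_ms[-length(durs_ms)] / 1000 + isi_s))
    final_off <- onsets[length(onsets)] + durs_ms[length(durs_ms)] / 1000
    ch <- simulate_choice(behavior, lev, design)
    press_t <- if (ch$choice == "press") final_off + ch$rt_s else NA_real_
    outcome <- outcome_label(lev, ch$choice)
    reward_t <- if (outcome == "hit") press_t
      else if (outcome == "correct_rejection") final_off + cr_reward_delay_ms / 1000
      else NA_real_
    blocks[[i]] <- tibble::tibble(
      block_id = i, deviant_level_n = lev, n_standards = n_std,
      choice = ch$choice, press_time_s = press_t, reward_time_s = reward_t,
      outcome = outcome,
      t_start = t_cursor, t_end = final_off + resp_s + inter_block_gap_s)
    events[[i]] <- tibble::tibble(
      block_id = i, onset_s = onsets, duration_ms = durs_ms,
      role = c(rep("standard", n_std), if (lev == 0) "control_final" else "deviant"),
      order_index = seq_len(n_std + 1L))
    t_cursor <- final_off + resp_s + inter_block_gap_s
  }
  blocks <- dplyr::bind_rows(blocks)
  events <- dplyr::bind_rows(events)

  comp <- oddball_components(rate, blocks, events)
  rmax <- rate$rate_max_hz %||% rate_bound(rate, comp$sounds, comp$transients)
  rate_fn <- build_rate_fn(rate, comp$sounds, comp$transients)
  spikes <- purrr::map(seq_len(nrow(blocks)), function(i) {
    set.seed(child_seed(seed, i, 2L))
    t0 <- if (i == 1) 0 else blocks$t_start[i]
    sample_inhomogeneous_poisson(rate_fn, t0, blocks$t_end[i], rmax,
                                 rate$refractory_ms)
  })
  spikes <- sort(unlist(spikes))

  segs <- blocks[c("block_id", "t_start", "t_end")]
  blocks <- blocks[setdiff(names(blocks), c("t_start", "t_end"))]
  s <- new_session(
    session_id = sprintf("sim-oddball-%d", as.integer(seed)),
    protocol = "oddball", design = design, unit_id = "sim-unit-1",
    spike_times = spikes, blocks = blocks, events = events,
    meta = list(generator = "simulate_oddball_session", seed = as.integer(seed),
                rate_model = unclass(rate), behavior_model = unclass(behavior),
                cr_reward_delay_ms = cr_reward_delay_ms,
                inter_block_gap_s = inter_block_gap_s,
                rate_max_hz = rmax, segments = segs))
  validate_session(s)
}

oddball_components <- function(rate, blocks, events) {
  sounds <- tibble::tibble(onset_s = events$onset_s,
                           offset_s = events$onset_s + events$duration_ms / 1000,
                           order = events$order_index)
  onset_amp <- rate$onset_peak_hz *
    ifelse(events$order_index == 1L, rate$onset_first_scale, 1)
  tr_on <- tibble::tibble(kind = "onset", time_s = events$onset_s,
                          amp_hz = onset_amp, tau_s = rate$onset_decay_ms / 1000)
  rw <- blocks[!is.na(blocks$reward_time_s), ]
  surprise <- ifelse(rw$outcome == "correct_rejection",
                     1 + rate$reward_surprise_gain, 1)
  tr_rw <- tibble::tibble(kind = "reward", time_s = rw$reward_time_s,
                          amp_hz = rate$reward_peak_hz * surprise,
                          tau_s = rate$reward_decay_ms / 1000)
  pr <- blocks[!is.na(blocks$press_time_s), ]
  tr_mo <- tibble::tibble(kind = "motor", time_s = pr$press_time_s,
                          amp_hz = rep(rate$motor_peak_hz, nrow(pr)),
                          tau_s = rate$motor_decay_ms / 1000)
  transients <- dplyr::bind_rows(tr_on, tr_rw, tr_mo)
  transients <- transients[transients$amp_hz > 0, ]
  list(sounds = sounds, transients = transients)
}

#' Simulate a reward-protocol session
#'
#' The three-block passive protocol: repeated fixed-duration sounds, rewards
#' delivered only in the middle block at a fixed delay after sound offset. The
#' reward transient amplitude decays over the reward block,
#' `reward_peak_hz * (1 + reward_surprise_gain * exp(-(j-1)/surprise_decay_trials))`
#' for the j-th reward trial, so early (surprising) rewards evoke larger
#' responses — the structure a reward-prediction-error contrast should detect.
#'
#' @param protocol A [reward_protocol()].
#' @param rate A [rate_model()].
#' @param surprise_decay_trials Decay constant of the surprise multiplier in
#'   trials; `Inf` keeps the gain constant, `0` confines it to the first
#'   reward trial.
#' @param seed Integer seed.
#' @return A validated `icdyn_session`.
#' @export
simulate_reward_session <- function(protocol = reward_protocol(),
                                    rate = rate_model(),
                                    surprise_decay_trials = 5,
                                    seed = 1) {
  stopifnot(surprise_decay_trials >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  bs <- protocol$block_sizes
  n <- protocol$n_trials
  dur_s <- protocol$sound_duration_ms / 1000
  onsets <- 0.5 + (seq_len(n) - 1) * protocol$isi_s
  block <- rep(c("early_no_reward", "reward", "late_no_reward"), times = bs)
  reward_t <- rep(NA_real_, n)
  in_rw <- which(block == "reward")
  reward_t[in_rw] <- onsets[in_rw] + dur_s + protocol$reward_delay_after_offset_ms / 1000

  trials <- tibble::tibble(trial = seq_len(n), block = block, onset_s = onsets,
                           duration_ms = protocol$sound_duration_ms,
                           reward_time_s = reward_t)

  j <- seq_along(in_rw)
  surprise <- surprise_multiplier(j, surprise_decay_trials)
  amps <- rate$reward_peak_hz * (1 + rate$reward_surprise_gain * surprise)
  sounds <- tibble::tibble(onset_s = onsets, offset_s = onsets + dur_s, order = 1)
  transients <- dplyr::bind_rows(
    tibble::tibble(kind = "onset", time_s = onsets,
                   amp_hz = rate$onset_peak_hz * rate$onset_first_scale,
                   tau_s = rate$onset_decay_ms / 1000),
    tibble::tibble(kind = "reward", time_s = reward_t[in_rw], amp_hz = amps,
                   tau_s = rate$reward_decay_ms / 1000))
  transients <- transients[transients$amp_hz > 0, ]

  rmax <- rate$rate_max_hz %||% rate_bound(rate, sounds, transients)
  rate_fn <- build_rate_fn(rate, sounds, transients)
  t_end <- max(onsets) + protocol$isi_s
  spikes <- sample_inhomogeneous_poisson(rate_fn, 0, t_end, rmax, rate$refractory_ms)

  s <- new_session(
    session_id = sprintf("sim-reward-%d", as.integer(seed)),
    protocol = "reward", design = protocol, unit_id = "sim-unit-1",
    spike_times = spikes, trials = trials,
    meta = list(generator = "simulate_reward_session", seed = as.integer(seed),
                rate_model = unclass(rate),
                surprise_decay_trials = surprise_decay_trials,
                rate_max_hz = rmax))
  validate_session(s)
}

# exp(-(j-1)/decay) with the 0 and Inf limits handled explicitly
surprise_multiplier <- function(j, decay) {
  if (decay == 0) return(as.numeric(j == 1))
  if (is.infinite(decay)) return(rep(1, length(j)))
  exp(-(j - 1) / decay)
}

#' Rebuild the generating rate function of a simulated session
#'
#' For sessions produced by the simulators, reconstructs the exact
#' instantaneous-rate function from the ground-truth parameters stored in
#' `$meta` and the session's event layout — the oracle against which windowed
#' spike counts can be checked.
#'
#' @param session A simulated `icdyn_session`.
#' @return A vectorised function of time (s) returning rate (Hz).
#' @export
session_rate_fn <- function(session) {
  rm <- session$meta$rate_model
  if (is.null(rm)) stop("session has no stored rate model", call. = FALSE)
  rate <- do.call(rate_model, rm)
  if (session$protocol == "oddball") {
    comp <- oddball_components(rate, session$blocks, session$events)
    build_rate_fn(rate, comp$sounds, comp$transients)
  } else {
    tr <- session$trials
    dur_s <- tr$duration_ms / 1000
    sounds <- tibble::tibble(onset_s = tr$onset_s, offset_s = tr$onset_s + dur_s,
                             order = 1)
    in_rw <- which(!is.na(tr$reward_time_s))
    surprise <- surprise_multiplier(seq_along(in_rw),
                                    session$meta$surprise_decay_trials)
    transients <- dplyr::bind_rows(
      tibble::tibble(kind = "onset", time_s = tr$onset_s,
                     amp_hz = rate$onset_peak_hz * rate$onset_first_scale,
                     tau_s = rate$onset_decay_ms / 1000),
      tibble::tibble(kind = "reward", time_s = tr$reward_time_s[in_rw],
                     amp_hz = rate$reward_peak_hz *
                       (1 + rate$reward_surprise_gain * surprise),
                     tau_s = rate$reward_decay_ms / 1000))
    build_rate_fn(rate, sounds, transients[transients$amp_hz > 0, ])
  }
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
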