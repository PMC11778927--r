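#' Classify a unit as reward-responsive
#'
#' Compares, across the reward-block trials, the firing rate within 100 ms
#' after reward delivery against the rate within 200 ms before it, with a
#' paired two-sided t-test. A unit is called reward-responsive when the
#' difference is significant at `alpha`.
#'
#' @param session A reward-protocol `icdyn_session`.
#' @param alpha Significance level for the responsive call.
#' @return A `reward_response` object: list with `trials` (per-trial pre/post
#'   rates), `pre_rate_hz`, `post_rate_hz` (means), `p_value`, `responsive`,
#'   `alpha`. Has [tidy()][generics::tidy] and [glance()][generics::glance]
#'   methods.
#' @export
classify_reward_responsive <- function(session, alpha = 0.05) {
  stopifnot(inherits(session, "icdyn_session"), session$protocol == "reward")
  rw <- session$trials[!is.na(session$trials$reward_time_s), ]
  if (nrow(rw) < 2L) stop("protocol error: fewer than 2 reward trials", call. = FALSE)
  pre <- windowed_rate(session$spike_times, rw$reward_time_s,
                       window_preset("reward_pre_200"))
  post <- windowed_rate(session$spike_times, rw$reward_time_s,
                        window_preset("reward_post_100"))
  p <- paired_t_p(post, pre)
  structure(list(
    trials = tibble::tibble(trial = rw$trial, pre_rate_hz = pre, post_rate_hz = post),
    pre_rate_hz = mean(pre), post_rate_hz = mean(post),
    p_value = p, responsive = p < alpha, alpha = alpha,
    n_trials = nrow(rw)), class = "reward_response")
}

# paired two-sided t-test p, with the all-differences-equal degenerate case
# mapped to p = 1 (no detectable difference)
paired_t_p <- function(x, y) {
  d <- x - y
  if (stats::sd(d) == 0) return(1)
  stats::t.test(d)$p.value
}

two_sample_p <- function(x, y, pooled = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = pooled)$p.value
}

#' @export
print.reward_response <- function(x, ...) {
  cat(sprintf("<reward_response> pre %.2f Hz, post %.2f Hz over %d reward trials\n",
              x$pre_rate_hz, x$post_rate_hz, x$n_trials))
  cat(sprintf("  paired t-test p = %.3g -> %sresponsive at alpha = %g\n",
              x$p_value, if (x$responsive) "" else "not ", x$alpha))
  invisible(x)
}

#' Reward-prediction-error contrast
#'
#' Contrasts the first `k` against the last `k` reward trials of the reward
#' block, in two windows: the reward window (\[0, 200) ms after reward
#' delivery) and the sound window (the full sound period). A unit carrying a
#' prediction-error-like signal responds more strongly to early (surprising)
#' rewards while its auditory response stays constant, so `p_reward` should be
#' small and `p_auditory` should not.
#'
#' @param session A reward-protocol `icdyn_session`.
#' @param k Trials per contrasted set (default 15).
#' @param pooled Use the pooled-variance two-sample t-test instead of Welch.
#' @return A `prediction_error_contrast` object with per-set mean rates,
#'   `p_reward`, `p_auditory`, and the per-trial rates.
#' @export
prediction_error_contrast <- function(session, k = 15, pooled = FALSE) {
  stopifnot(inherits(session, "icdyn_session"), session$protocol == "reward",
            k >= 2)
  rw <- session$trials[!is.na(session$trials$reward_time_s), ]
  if (nrow(rw) < 2 * k) {
    stop("insufficient data: reward block has ", nrow(rw), " trials, need ",
         2 * k, call. = FALSE)
  }
  first <- rw[seq_len(k), ]
  last <- rw[seq(nrow(rw) - k + 1, nrow(rw)), ]
  rate_in <- function(tr, w) windowed_rate(session$spike_times, tr, w)
  w_rw <- window_preset("reward_post_200")
  sound_w <- analysis_window("sound_onset", 0, session$design$sound_duration_ms)
  rw_first <- rate_in(first$reward_time_s, w_rw)
  rw_last <- rate_in(last$reward_time_s, w_rw)
  au_first <- rate_in(first$onset_s, sound_w)
  au_last <- rate_in(last$onset_s, sound_w)
  structure(list(
    k = k,
    first_block_rate_hz = mean(rw_first), last_block_rate_hz = mean(rw_last),
    auditory_first_hz = mean(au_first), auditory_last_hz = mean(au_last),
    p_reward = two_sample_p(rw_first, rw_last, pooled),
    p_auditory = two_sample_p(au_first, au_last, pooled),
    rates = tibble::tibble(
      set = rep(c("first", "last"), each = k),
      trial = c(first$trial, last$trial),
      reward_rate_hz = c(rw_first, rw_last),
      auditory_rate_hz = c(au_first, au_last))),
    class = "prediction_error_contrast")
}

#' @export
print.prediction_error_contrast <- function(x, ...) {
  cat(sprintf("<prediction_error_contrast> first/last %d reward trials\n", x$k))
  cat(sprintf("  reward window: %.2f vs %.2f Hz (p = %.3g)\n",
              x$first_block_rate_hz, x$last_block_rate_hz, x$p_reward))
  cat(sprintf("  sound window:  %.2f vs %.2f Hz (p = %.3g)\n",
              x$auditory_first_hz, x$auditory_last_hz, x$p_auditory))
  invisible(x)
}

#' Reward response to unexpected reward in control trials
#'
#' In the oddball task, the reward after a correct rejection arrives without a
#' preceding action and is the less predicted one; this contrast compares the
#' \[0, 200) ms post-reward rate on correct-rejection trials against hit
#' trials.
#'
#' @param session An oddball `icdyn_session` containing rewarded correct
#'   rejections and hits.
#' @param pooled Use pooled-variance t-test instead of Welch.
#' @return List with per-outcome mean rates, `difference_hz`
#'   (correct rejection minus hit), `p_value`, and the per-trial `rates`
#'   tibble.
#' @export
unexpected_reward_response <- function(session, pooled = FALSE) {
  stopifnot(inherits(session, "icdyn_session"), session$protocol == "oddball")
  b <- session$blocks[!is.na(session$blocks$reward_time_s), ]
  n_cr <- sum(b$outcome == "correct_rejection")
  n_hit <- sum(b$outcome == "hit")
  if (n_cr < 2 || n_hit < 2) {
    stop("insufficient data: need >= 2 rewarded trials per outcome, have ",
         n_cr, " correct rejections and ", n_hit, " hits", call. = FALSE)
  }
  w <- window_preset("reward_post_200")
  b$rate_hz <- windowed_rate(session$spike_times, b$reward_time_s, w)
  cr <- b$rate_hz[b$outcome == "correct_rejection"]
  hit <- b$rate_hz[b$outcome == "hit"]
  list(cr_rate_hz = mean(cr), hit_rate_hz = mean(hit),
       difference_hz = mean(cr) - mean(hit),
       p_value = two_sample_p(cr, hit, pooled),
       n_cr = n_cr, n_hit = n_hit,
       rates = tibble::tibble(outcome = b$outcome, block_id = b$block_id,
                              rate_hz = b$rate_hz))
}
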