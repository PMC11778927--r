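#' Event-anchored analysis windows
#'
#' An `analysis_window` is a half-open time window `[start_ms, end_ms)`
#' expressed in milliseconds relative to an anchoring event. The half-open
#' convention means a spike falling exactly on the start edge is counted and
#' one exactly on the end edge is not, so adjacent windows never double-count.
#'
#' @param anchor Event the window is measured from: `"sound_onset"`,
#'   `"sound_offset"`, `"reward"`, or `"press"`.
#' @param start_ms,end_ms Signed window bounds in milliseconds relative to the
#'   anchor; `end_ms` must exceed `start_ms`.
#'
#' @return An object of class `analysis_window`: a list with fields `anchor`,
#'   `start_ms`, `end_ms`.
#'
#' @examples
#' analysis_window("sound_offset", -100, 0)   # the late window
#' window_preset("after_peak")
#' @export
analysis_window <- function(anchor = c("sound_onset", "sound_offset", "reward", "press"),
                            start_ms, end_ms) {
  anchor <- match.arg(anchor)
  stopifnot(is.numeric(start_ms), is.numeric(end_ms), length(start_ms) == 1L,
            length(end_ms) == 1L, is.finite(start_ms), is.finite(end_ms))
  if (end_ms <= start_ms) {
    stop("`end_ms` must be strictly greater than `start_ms`", call. = FALSE)
  }
  structure(list(anchor = anchor, start_ms = start_ms, end_ms = end_ms),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> [%g, %g) ms re %s\n", x$start_ms, x$end_ms, x$anchor))
  invisible(x)
}

#' @describeIn analysis_window Named window presets used throughout the
#'   analyses: `"onset"` = \[0, 60) ms re sound onset, `"late"` = \[-100, 0) ms
#'   re sound offset, `"after_peak"` = \[100, 200) ms re sound onset,
#'   `"reward_pre_200"` = \[-200, 0) ms re reward, `"reward_post_100"` =
#'   \[0, 100) ms re reward, `"reward_post_200"` = \[0, 200) ms re reward.
#' @param name Preset name.
#' @export
window_preset <- function(name = c("onset", "late", "after_peak",
                                   "reward_pre_200", "reward_post_100",
                                   "reward_post_200")) {
  name <- match.arg(name)
  switch(name,
    onset           = analysis_window("sound_onset", 0, 60),
    late            = analysis_window("sound_offset", -100, 0),
    after_peak      = analysis_window("sound_onset", 100, 200),
    reward_pre_200  = analysis_window("reward", -200, 0),
    reward_post_100 = analysis_window("reward", 0, 100),
    reward_post_200 = analysis_window("reward", 0, 200)
  )
}

window_length_s <- function(window) (window$end_ms - window$start_ms) / 1000

#' Windowed firing rate
#'
#' Counts spikes in the half-open interval
#' `[anchor + start, anchor + end)` and divides by the window length, giving a
#' rate in Hz. Vectorised over anchor times, so one call returns the per-trial
#' rates for a whole trial set.
#'
#' @param spike_times Numeric vector of sorted spike times in seconds.
#' @param anchor_times_s Numeric vector of anchor event times in seconds.
#' @param window An [analysis_window()].
#'
#' @return Numeric vector of rates (Hz), one per anchor time. An empty spike
#'   train gives 0 Hz everywhere.
#' @examples
#' w <- window_preset("late")
#' windowed_rate(c(0.25, 0.28), anchor_times_s = 0.3, w)  # 2 spikes / 0.1 s
#' @export
windowed_rate <- function(spike_times, anchor_times_s, window) {
  stopifnot(inherits(window, "analysis_window"), is.numeric(anchor_times_s))
  lo <- anchor_times_s + window$start_ms / 1000
  hi <- anchor_times_s + window$end_ms / 1000
  # findInterval on sorted spikes: count of spikes < t
  n_lo <- findInterval(lo, spike_times, left.open = TRUE)
  n_hi <- findInterval(hi, spike_times, left.open = TRUE)
  (n_hi - n_lo) / window_length_s(window)
}
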