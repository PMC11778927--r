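#' Event-aligned peri-stimulus time histogram
#'
#' Bins spikes relative to a set of anchor events and averages across trials,
#' giving rate in Hz per bin. Optional Gaussian smoothing (sigma in ms) is
#' applied to the rate vector with reflected boundaries, which preserves the
#' time-integral of the rate exactly.
#'
#' @param spike_times Sorted spike times (s).
#' @param anchor_times_s Anchor event times (s), one per trial.
#' @param window An [analysis_window()] giving the span of the histogram
#'   relative to the anchors; `bin_ms` must divide its length.
#' @param bin_ms Bin width (ms). Default 10 ms resolves the 60 ms onset window.
#' @param smoothing_sigma_ms Gaussian kernel sigma (ms); 0 disables smoothing.
#' @return A `psth` object: a tibble with `bin_start_ms`, `bin_mid_ms`,
#'   `rate_hz`, plus attributes `anchor`, `n_trials`, `bin_ms`,
#'   `smoothing_sigma_ms`.
#' @examples
#' p <- compute_psth(c(0.105, 0.31), anchor_times_s = c(0.1, 0.3),
#'                   window = analysis_window("sound_onset", 0, 100),
#'                   bin_ms = 20, smoothing_sigma_ms = 0)
#' @export
compute_psth <- function(spike_times, anchor_times_s, window,
                         bin_ms = 10, smoothing_sigma_ms = 15) {
  stopifnot(inherits(window, "analysis_window"), length(anchor_times_s) >= 1,
            bin_ms > 0, smoothing_sigma_ms >= 0)
  span <- window$end_ms - window$start_ms
  n_bins <- span / bin_ms
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("bin_ms = ", bin_ms, " does not divide the window length ", span, " ms",
         call. = FALSE)
  }
  n_bins <- as.integer(round(n_bins))
  edges_ms <- window$start_ms + bin_ms * (0:n_bins)

  counts <- numeric(n_bins)
  for (a in anchor_times_s) {
    rel_ms <- (spike_times - a) * 1000
    rel_ms <- rel_ms[rel_ms >= window$start_ms & rel_ms < window$end_ms]
    if (length(rel_ms)) {
      idx <- pmin(n_bins, 1L + floor((rel_ms - window$start_ms) / bin_ms))
      counts <- counts + tabulate(idx, nbins = n_bins)
    }
  }
  rate <- counts / (length(anchor_times_s) * bin_ms / 1000)
  if (smoothing_sigma_ms > 0) {
    rate <- gaussian_smooth_reflect(rate, smoothing_sigma_ms / bin_ms)
  }
  structure(
    tibble::tibble(bin_start_ms = edges_ms[-length(edges_ms)],
                   bin_mid_ms = edges_ms[-length(edges_ms)] + bin_ms / 2,
                   rate_hz = rate),
    anchor = window$anchor, n_trials = length(anchor_times_s),
    bin_ms = bin_ms, smoothing_sigma_ms = smoothing_sigma_ms,
    class = c("psth", class(tibble::tibble())))
}

# discrete Gaussian smoothing with reflected boundaries; kernel normalised, so
# the vector sum (hence the rate integral) is conserved exactly
gaussian_smooth_reflect <- function(x, sigma_bins) {
  r <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(-r:r, sd = sigma_bins)
  k <- k / sum(k)
  n <- length(x)
  if (n == 1L) return(x)
  # reflected padding: x[r], ..., x[1] | x | x[n], ..., x[n-r+1]
  pad <- c(x[pmin(n, r:1)], x, x[pmax(1, n - (1:r) + 1)])
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(r + 1):(r + n)])
}

#' Response Dynamic Index
#'
#' Quantifies the "climbing" of sustained activity during a sound as the
#' normalised difference between the firing rate in the late window
#' (\[-100, 0) ms before sound offset) and the after-peak window
#' (\[100, 200) ms after sound onset):
#' `RDI = (F_late - F_after_peak) / (F_late + F_after_peak)`,
#' with the 0/0 case defined as 0 (no dynamic change detectable). Positive
#' values mean the rate grew between the early sustained period and the end of
#' the sound. The two windows must not overlap, which requires a sound of at
#' least 300 ms.
#'
#' Vectorised over sounds: one row per anchor, so per-trial RDIs can be
#' averaged downstream without pooling spike counts across unequal trial sets.
#'
#' @param spike_times Sorted spike times (s).
#' @param onset_s Sound onset time(s) (s).
#' @param duration_ms Sound duration(s) (ms), each >= 300.
#' @return Tibble with `onset_s`, `duration_ms`, `fir_late_hz`,
#'   `fir_after_peak_hz`, `rdi`.
#' @examples
#' # 1 spike in the after-peak window, 3 in the late window of a 600 ms sound
#' compute_rdi(c(0.15, 0.52, 0.55, 0.58), onset_s = 0, duration_ms = 600)
#' @export
compute_rdi <- function(spike_times, onset_s, duration_ms) {
  stopifnot(length(onset_s) == length(duration_ms) || length(duration_ms) == 1L)
  duration_ms <- rep_len(duration_ms, length(onset_s))
  if (any(duration_ms < 300)) {
    stop("RDI windows overlap for sounds shorter than 300 ms", call. = FALSE)
  }
  fl <- windowed_rate(spike_times, onset_s + duration_ms / 1000, window_preset("late"))
  fa <- windowed_rate(spike_times, onset_s, window_preset("after_peak"))
  tibble::tibble(onset_s = onset_s, duration_ms = duration_ms,
                 fir_late_hz = fl, fir_after_peak_hz = fa,
                 rdi = rdi_value(fl, fa))
}

rdi_value <- function(fir_late, fir_after_peak) {
  s <- fir_late + fir_after_peak
  ifelse(s > 0, (fir_late - fir_after_peak) / s, 0)
}

#' Per-block RDI table for an oddball session
#'
#' Applies [compute_rdi()] to the final sound of every block (or to standards
#' of a given order), joining in block metadata so results can be grouped by
#' level, choice or outcome with ordinary dplyr verbs.
#'
#' @param session An oddball `icdyn_session`.
#' @param role Which sounds to analyse: `"final"` (deviant or control final,
#'   the default) or `"standard"`.
#' @return Tibble with one row per analysed sound: block metadata plus the
#'   [compute_rdi()] columns.
#' @export
session_rdi <- function(session, role = c("final", "standard")) {
  stopifnot(inherits(session, "icdyn_session"), session$protocol == "oddball")
  role <- match.arg(role)
  ev <- session$events
  ev <- if (role == "final") ev[ev$role != "standard", ]
        else ev[ev$role == "standard" & ev$duration_ms >= 300, ]
  res <- compute_rdi(session$spike_times, ev$onset_s, ev$duration_ms)
  res$block_id <- ev$block_id
  res$order_index <- ev$order_index
  dplyr::left_join(res, session$blocks, by = "block_id")
}

#' Stimulus-order response profile
#'
#' Mean windowed firing rate as a function of the order of the sound within
#' its block, pooled over blocks (orders beyond a block's length are simply
#' absent), and normalised by the order-1 rate — the profile used to show
#' onset adaptation and late-window growth over successive standards.
#'
#' @param session An oddball `icdyn_session`.
#' @param window An [analysis_window()] anchored at `sound_onset` or
#'   `sound_offset`.
#' @param max_order Largest order retained.
#' @return Tibble with `order`, `n` (sounds contributing), `rate_hz`,
#'   `normalized` (`rate_hz` / order-1 rate).
#' @export
order_profile <- function(session, window = window_preset("late"), max_order = 7) {
  stopifnot(inherits(session, "icdyn_session"), session$protocol == "oddball",
            window$anchor %in% c("sound_onset", "sound_offset"))
  ev <- session$events[session$events$order_index <= max_order, ]
  if (!any(ev$order_index >= 2) && max_order > 1) {
    stop("insufficient data: no blocks reach stimulus order 2", call. = FALSE)
  }
  anchor <- if (window$anchor == "sound_onset") ev$onset_s
            else ev$onset_s + ev$duration_ms / 1000
  ev$rate_hz <- windowed_rate(session$spike_times, anchor, window)
  prof <- dplyr::summarise(dplyr::group_by(ev, order = .data$order_index),
                           n = dplyr::n(), rate_hz = mean(.data$rate_hz),
                           .groups = "drop")
  r1 <- prof$rate_hz[prof$order == 1L]
  if (length(r1) != 1L || r1 <= 0) {
    stop("insufficient data: order-1 rate unavailable or zero; cannot normalise",
         call. = FALSE)
  }
  prof$normalized <- prof$rate_hz / r1
  prof
}
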