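#' Oddball task design
#'
#' Parameters of the duration-deviation oddball task: blocks of 3–6 standard
#' white-noise bursts at a fixed inter-stimulus interval, ending in a final
#' sound whose duration is `standard_duration_ms * lambda^n` for a deviant
#' level `n`. Level 0 is the control condition (final sound equals the
#' standard); the subject must press within `response_window_ms` of the
#' deviant's offset to score a hit, and withhold the press on control trials
#' to score a correct rejection.
#'
#' @param standard_duration_ms Duration of the standard sound (ms).
#' @param lambda Ratio between successive deviant durations (> 1).
#' @param levels_n Integer deviant levels; 0 is the control.
#' @param isi_ms Inter-stimulus interval, onset-to-onset gap after each
#'   sound's offset (ms).
#' @param n_standards_range Inclusive range the per-block number of standards
#'   is drawn from.
#' @param response_window_ms Response window after the final sound's offset (ms).
#'
#' @return An object of class `oddball_design`.
#' @examples
#' d <- oddball_design()
#' deviant_duration(d, 0:4)
#' @export
oddball_design <- function(standard_duration_ms = 300,
                           lambda = 1.19,
                           levels_n = 0:4,
                           isi_ms = 600,
                           n_standards_range = c(3L, 6L),
                           response_window_ms = 600) {
  stopifnot(standard_duration_ms > 0, lambda > 1,
            all(levels_n == as.integer(levels_n)), all(levels_n >= 0),
            isi_ms > 0, length(n_standards_range) == 2L,
            n_standards_range[1] >= 1, n_standards_range[2] >= n_standards_range[1],
            response_window_ms > 0)
  structure(list(
    standard_duration_ms = standard_duration_ms,
    lambda = lambda,
    levels_n = sort(as.integer(unique(levels_n))),
    isi_ms = isi_ms,
    n_standards_range = as.integer(n_standards_range),
    response_window_ms = response_window_ms
  ), class = "oddball_design")
}

#' Deviant duration ladder
#'
#' The final-sound duration at deviant level `n` is
#' `round(standard_duration_ms * lambda^n)`, rounded half-up to an integer
#' millisecond. With the defaults (300 ms standard, lambda 1.19) the ladder is
#' 300, 357, 425, 506, 602 ms for n = 0..4. Published stimulus sets often
#' quote 600 ms at the top level; `printed_ladder()` returns that conventional
#' list so both forms are available.
#'
#' @param design An [oddball_design()].
#' @param n Integer level(s); must be members of `design$levels_n`.
#' @return Integer duration(s) in ms.
#' @export
deviant_duration <- function(design, n) {
  stopifnot(inherits(design, "oddball_design"))
  if (!all(n %in% design$levels_n)) {
    stop("level n = ", paste(setdiff(n, design$levels_n), collapse = ", "),
         " not in design levels {", paste(design$levels_n, collapse = ", "), "}",
         call. = FALSE)
  }
  round_half_up(design$standard_duration_ms * design$lambda^n)
}

round_half_up <- function(x) floor(x + 0.5)

#' @describeIn deviant_duration The conventional printed stimulus ladder for
#'   the default design (top level flattened to 600 ms).
#' @export
printed_ladder <- function() c(300, 357, 425, 506, 600)

#' @describeIn deviant_duration Deviant/standard duration ratios
#'   `lambda^n` for every level of the design.
#' @export
duration_ratios <- function(design) {
  stopifnot(inherits(design, "oddball_design"))
  design$lambda^design$levels_n
}

#' Reward protocol design
#'
#' A passive listening protocol used to dissociate reward effects from
#' sound-driven dynamics: a fixed-duration white-noise burst repeated over
#' three consecutive blocks — no reward, reward delivered at a fixed delay
#' after sound offset, no reward again.
#'
#' @param sound_duration_ms Sound duration (ms).
#' @param block_sizes Trials per block, early-no-reward / reward /
#'   late-no-reward.
#' @param isi_s Inter-stimulus interval, onset to onset (s).
#' @param reward_delay_after_offset_ms Reward delivery latency after sound
#'   offset in the reward block (ms).
#' @param level_db_spl Sound level, informational only.
#'
#' @return An object of class `reward_protocol`.
#' @export
reward_protocol <- function(sound_duration_ms = 1000,
                            block_sizes = c(50L, 50L, 50L),
                            isi_s = 4,
                            reward_delay_after_offset_ms = 500,
                            level_db_spl = 60) {
  stopifnot(sound_duration_ms > 0, length(block_sizes) == 3L, all(block_sizes >= 0),
            isi_s * 1000 >= sound_duration_ms, reward_delay_after_offset_ms >= 0)
  structure(list(
    sound_duration_ms = sound_duration_ms,
    n_trials = sum(as.integer(block_sizes)),
    block_sizes = as.integer(block_sizes),
    isi_s = isi_s,
    reward_delay_after_offset_ms = reward_delay_after_offset_ms,
    level_db_spl = level_db_spl
  ), class = "reward_protocol")
}
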