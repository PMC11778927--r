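#' Session objects
#'
#' A session bundles one unit's spike train with the event and trial structure
#' of the protocol it was recorded (or simulated) under. Oddball sessions
#' carry a `blocks` tibble (one row per trial block: deviant level, number of
#' standards, choice, press/reward times, outcome) and a flat `events` tibble
#' (one row per stimulus with its block id, onset, duration, role and
#' within-block order). Reward sessions carry a `trials` tibble (one row per
#' sound presentation with its block label and reward time, if any).
#'
#' All stored times are seconds from session start; window bounds elsewhere in
#' the package are milliseconds, converted once at the windowing boundary.
#'
#' @param session_id Character identifier.
#' @param protocol `"oddball"` or `"reward"`.
#' @param design An [oddball_design()] or [reward_protocol()] matching
#'   `protocol`.
#' @param unit_id Character unit identifier.
#' @param spike_times Sorted, nonnegative spike times in seconds.
#' @param blocks,events,trials Protocol tables, see Details.
#' @param meta Named list of free-form provenance (generator seed, ground
#'   truth parameters, ...). A `schema` entry is added automatically.
#'
#' @return An object of class `icdyn_session`.
#' @seealso [validate_session()], [read_session()], [write_session()]
#' @export
new_session <- function(session_id, protocol = c("oddball", "reward"), design,
                        unit_id, spike_times, blocks = NULL, events = NULL,
                        trials = NULL, meta = list()) {
  protocol <- match.arg(protocol)
  meta$schema <- "icdyn-session/1"
  structure(list(
    session_id = as.character(session_id),
    protocol = protocol,
    design = design,
    unit_id = as.character(unit_id),
    spike_times = as.numeric(spike_times),
    blocks = blocks,
    events = events,
    trials = trials,
    meta = meta
  ), class = "icdyn_session")
}

#' @export
print.icdyn_session <- function(x, ...) {
  cat(sprintf("<icdyn_session> %s  protocol=%s  unit=%s\n",
              x$session_id, x$protocol, x$unit_id))
  cat(sprintf("  %d spikes over %.1f s\n", length(x$spike_times),
              if (length(x$spike_times)) max(x$spike_times) else 0))
  if (x$protocol == "oddball") {
    cat(sprintf("  %d blocks, %d stimulus events\n", nrow(x$blocks), nrow(x$events)))
  } else {
    cat(sprintf("  %d trials (%s rewarded)\n", nrow(x$trials),
                sum(!is.na(x$trials$reward_time_s))))
  }
  invisible(x)
}

#' Outcome label implied by level and choice
#'
#' Pure bookkeeping: control blocks (level 0) score a correct rejection when
#' the press is withheld and a false alarm otherwise; deviant blocks (level >
#' 0) score a hit on press and a miss otherwise. Rewards follow correct
#' outcomes (hit, correct rejection) only.
#'
#' @param deviant_level_n Integer level (0 = control), vectorised.
#' @param choice `"press"` or `"no_press"`, vectorised.
#' @return Character vector of outcomes.
#' @export
outcome_label <- function(deviant_level_n, choice) {
  stopifnot(all(choice %in% c("press", "no_press")))
  dplyr::case_when(
    deviant_level_n == 0 & choice == "no_press" ~ "correct_rejection",
    deviant_level_n == 0 & choice == "press"    ~ "false_alarm",
    deviant_level_n > 0  & choice == "press"    ~ "hit",
    TRUE                                        ~ "miss"
  )
}

validation_fail <- function(field, msg, block = NULL) {
  where <- if (is.null(block)) field else sprintf("%s (block %s)", field, block)
  stop(sprintf("session validation failed at `%s`: %s", where, msg), call. = FALSE)
}

#' Validate a session against the schema invariants
#'
#' Checks every structural invariant of the session container: sorted finite
#' nonnegative spike times, event roles and order indices, press/choice and
#' reward/outcome consistency, and that the stored outcome labels agree with
#' [outcome_label()] recomputed from level and choice. Duplicate spike times
#' (possible for multi-unit records) and event times beyond the last spike
#' raise warnings, not errors.
#'
#' @param session An `icdyn_session`.
#' @return The session, invisibly, if valid; otherwise an error naming the
#'   offending field and block index.
#' @export
validate_session <- function(session) {
  if (!inherits(session, "icdyn_session")) {
    validation_fail("class", "not an icdyn_session")
  }
  st <- session$spike_times
  if (any(!is.finite(st)) || any(st < 0)) {
    validation_fail("times", "spike times must be finite and nonnegative")
  }
  if (is.unsorted(st)) validation_fail("times", "spike times must be sorted ascending")
  if (anyDuplicated(st)) {
    warning("duplicate spike times present (multi-unit record?)", call. = FALSE)
  }

  if (session$protocol == "oddball") {
    if (!inherits(session$design, "oddball_design")) {
      validation_fail("design", "oddball protocol requires an oddball_design")
    }
    b <- session$blocks
    ev <- session$events
    req_b <- c("block_id", "deviant_level_n", "n_standards", "choice",
               "press_time_s", "reward_time_s", "outcome")
    if (!all(req_b %in% names(b))) {
      validation_fail("blocks", paste("missing columns:",
                                      paste(setdiff(req_b, names(b)), collapse = ", ")))
    }
    if (!all(ev$duration_ms > 0)) validation_fail("events$duration_ms", "must be > 0")
    if (!all(ev$onset_s >= 0)) validation_fail("events$onset_s", "must be >= 0")
    if (!all(ev$role %in% c("standard", "deviant", "control_final"))) {
      validation_fail("events$role", "unknown role")
    }
    for (i in seq_len(nrow(b))) {
      bi <- b[i, ]
      evi <- ev[ev$block_id == bi$block_id, ]
      evi <- evi[order(evi$order_index), ]
      if (sum(evi$role == "standard") != bi$n_standards) {
        validation_fail("n_standards", "does not match count of standard events",
                        bi$block_id)
      }
      last_role <- evi$role[nrow(evi)]
      if (any(evi$role[-nrow(evi)] != "standard")) {
        validation_fail("events$role", "deviant/control_final only at last position",
                        bi$block_id)
      }
      expected_last <- if (bi$deviant_level_n == 0) "control_final" else "deviant"
      if (last_role != expected_last) {
        validation_fail("events$role", sprintf("final role %s but level %d", last_role,
                                               bi$deviant_level_n), bi$block_id)
      }
      if (!all(evi$order_index == seq_len(nrow(evi)))) {
        validation_fail("events$order_index", "must be 1..K in order", bi$block_id)
      }
      if ((bi$choice == "press") != !is.na(bi$press_time_s)) {
        validation_fail("press_time_s", "present iff choice == press", bi$block_id)
      }
      if (outcome_label(bi$deviant_level_n, bi$choice) != bi$outcome) {
        validation_fail("outcome", "inconsistent with (level, choice)", bi$block_id)
      }
      if ((bi$outcome %in% c("hit", "correct_rejection")) != !is.na(bi$reward_time_s)) {
        validation_fail("reward_time_s", "present iff outcome is hit/correct_rejection",
                        bi$block_id)
      }
    }
    t_events <- c(ev$onset_s, b$press_time_s, b$reward_time_s)
  } else {
    if (!inherits(session$design, "reward_protocol")) {
      validation_fail("design", "reward protocol requires a reward_protocol")
    }
    tr <- session$trials
    req_t <- c("trial", "block", "onset_s", "duration_ms", "reward_time_s")
    if (!all(req_t %in% names(tr))) {
      validation_fail("trials", paste("missing columns:",
                                      paste(setdiff(req_t, names(tr)), collapse = ", ")))
    }
    if (!all(tr$block %in% c("early_no_reward", "reward", "late_no_reward"))) {
      validation_fail("trials$block", "unknown block label")
    }
    if (any(!is.na(tr$reward_time_s) & tr$block != "reward")) {
      validation_fail("trials$reward_time_s", "reward outside the reward block")
    }
    t_events <- c(tr$onset_s, tr$reward_time_s)
  }

  t_events <- t_events[!is.na(t_events)]
  if (length(st) && length(t_events) && max(t_events) > max(st) + 5) {
    warning("event times extend well beyond the last spike; check alignment",
            call. = FALSE)
  }
  invisible(session)
}
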