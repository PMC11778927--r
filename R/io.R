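#' Read and write session files
#'
#' Sessions are stored as JSON under the `icdyn-session/1` schema (a
#' JSON-Schema document describing the format ships in
#' `system.file("extdata", "session.schema.json", package = "icdyn")`). Keys
#' are written in a fixed order and floats at full precision, so writing the
#' same session twice produces byte-identical files and a write/read
#' round-trip is lossless. Unknown top-level keys found in a file are
#' preserved and written back.
#'
#' `write_session()` refuses sessions that fail [validate_session()];
#' `read_session()` validates after parsing and reports the offending field
#' and block index on failure.
#'
#' @param session An `icdyn_session`.
#' @param path File path.
#' @return `read_session()` returns a validated `icdyn_session`;
#'   `write_session()` returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  obj <- list(
    schema = session$meta$schema %||% "icdyn-session/1",
    session_id = session$session_id,
    protocol = session$protocol,
    design = design_to_list(session$design),
    spikes = list(unit_id = session$unit_id, times = as.numeric(session$spike_times)),
    blocks = session$blocks,
    events = session$events,
    trials = session$trials,
    meta = session$meta[setdiff(names(session$meta), "schema")]
  )
  obj <- c(obj, session$extra %||% list())
  obj <- obj[!vapply(obj, is.null, logical(1))]
  json <- jsonlite::toJSON(obj, dataframe = "columns", digits = I(17), na = "null",
                           auto_unbox = TRUE, pretty = FALSE, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(as.character(json)), con)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed session JSON: ",
                                           conditionMessage(e), call. = FALSE))
  known <- c("schema", "session_id", "protocol", "design", "spikes", "blocks",
             "events", "trials", "meta")
  protocol <- raw$protocol
  if (is.null(protocol) || !protocol %in% c("oddball", "reward")) {
    stop("session validation failed at `protocol`: missing or unknown", call. = FALSE)
  }
  design <- design_from_list(raw$design)
  meta <- as.list(raw$meta)
  meta$schema <- raw$schema %||% "icdyn-session/1"

  s <- new_session(
    session_id = raw$session_id,
    protocol = protocol,
    design = design,
    unit_id = raw$spikes$unit_id,
    spike_times = as.numeric(raw$spikes$times %||% numeric()),
    blocks = if (!is.null(raw$blocks)) coerce_blocks(raw$blocks),
    events = if (!is.null(raw$events)) coerce_events(raw$events),
    trials = if (!is.null(raw$trials)) coerce_trials(raw$trials),
    meta = meta
  )
  extra <- raw[setdiff(names(raw), known)]
  if (length(extra)) s$extra <- extra
  validate_session(s)
  s
}

design_to_list <- function(design) {
  c(list(type = class(design)[1]), unclass(design))
}

design_from_list <- function(x) {
  if (is.null(x$type)) stop("session validation failed at `design$type`: missing",
                            call. = FALSE)
  if (x$type == "oddball_design") {
    oddball_design(standard_duration_ms = x$standard_duration_ms,
                   lambda = x$lambda, levels_n = x$levels_n, isi_ms = x$isi_ms,
                   n_standards_range = x$n_standards_range,
                   response_window_ms = x$response_window_ms)
  } else if (x$type == "reward_protocol") {
    reward_protocol(sound_duration_ms = x$sound_duration_ms,
                    block_sizes = x$block_sizes, isi_s = x$isi_s,
                    reward_delay_after_offset_ms = x$reward_delay_after_offset_ms,
                    level_db_spl = x$level_db_spl)
  } else {
    stop("session validation failed at `design$type`: unknown type ", x$type,
         call. = FALSE)
  }
}

coerce_blocks <- function(x) {
  tibble::tibble(
    block_id = as.integer(x$block_id),
    deviant_level_n = as.integer(x$deviant_level_n),
    n_standards = as.integer(x$n_standards),
    choice = as.character(x$choice),
    press_time_s = as.numeric(x$press_time_s),
    reward_time_s = as.numeric(x$reward_time_s),
    outcome = as.character(x$outcome)
  )
}

coerce_events <- function(x) {
  tibble::tibble(
    block_id = as.integer(x$block_id),
    onset_s = as.numeric(x$onset_s),
    duration_ms = as.numeric(x$duration_ms),
    role = as.character(x$role),
    order_index = as.integer(x$order_index)
  )
}

coerce_trials <- function(x) {
  tibble::tibble(
    trial = as.integer(x$trial),
    block = as.character(x$block),
    onset_s = as.numeric(x$onset_s),
    duration_ms = as.numeric(x$duration_ms),
    reward_time_s = as.numeric(x$reward_time_s)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
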