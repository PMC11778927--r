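#' Run configuration
#'
#' Reads a YAML run configuration whose keys mirror the constructor arguments
#' of [oddball_design()], [reward_protocol()], [rate_model()] and
#' [behavior_model()] one-to-one, fills defaults, and validates it. A config
#' plus a master seed fully determines a pipeline run.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @param overrides Named list merged over the file's values (used by
#'   [run_pipeline()] for `seed`).
#' @return A `run_config`: list with `protocol`, `design`, `rate`, `behavior`,
#'   `analysis` (windows/k/n_perm/bins), `n_blocks_per_level`,
#'   `surprise_decay_trials`, `seed`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides)
  protocol <- cfg$protocol %||% "oddball"
  if (!protocol %in% c("oddball", "reward")) {
    stop("config validation failed at `protocol`: must be oddball or reward",
         call. = FALSE)
  }
  known <- c("protocol", "design", "rate", "behavior", "analysis",
             "n_blocks_per_level", "surprise_decay_trials", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("config validation failed: unknown field(s) ",
         paste0("`", unknown, "`", collapse = ", "), call. = FALSE)
  }
  design <- if (protocol == "oddball") {
    do.call(oddball_design, cfg$design %||% list())
  } else {
    do.call(reward_protocol, cfg$design %||% list())
  }
  analysis <- utils::modifyList(
    list(bin_ms = 10, smoothing_sigma_ms = 15, k = 15, n_perm = 1999,
         dp_window = "late", max_order = 7),
    cfg$analysis %||% list())
  structure(list(
    protocol = protocol, design = design,
    rate = do.call(rate_model, cfg$rate %||% list()),
    behavior = do.call(behavior_model, cfg$behavior %||% list()),
    analysis = analysis,
    n_blocks_per_level = cfg$n_blocks_per_level %||% 30,
    surprise_decay_trials = cfg$surprise_decay_trials %||% 5,
    seed = as.integer(cfg$seed %||% 1L)), class = "run_config")
}

#' Simulate, analyse, and write a full report bundle
#'
#' Runs the whole pipeline for one session under a fixed seed: simulates the
#' configured protocol, writes the session JSON, runs every applicable
#' analysis, and writes tidy CSVs plus one machine-readable `summary.json`.
#' Outputs are a pure function of (config, seed): the same inputs give
#' byte-identical summaries.
#'
#' For oddball sessions the bundle holds per-trial and per-level RDI tables,
#' order profiles in the late and onset windows, press ratios with the
#' psychometric fit and QC verdict, a per-level detection-probability table,
#' and the unexpected-reward contrast (when both rewarded outcomes occur).
#' For reward sessions it holds the reward-responsiveness classification and
#' the first-vs-last reward-trial contrast.
#'
#' @param config A `run_config` from [read_run_config()].
#' @param out_dir Output directory, created if needed.
#' @return The summary as a list, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(config = read_run_config(), out_dir = tempfile("icdyn-")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  logf("icdyn %s | protocol=%s seed=%d",
       as.character(utils::packageVersion("icdyn")), config$protocol, config$seed)

  if (config$protocol == "oddball") {
    session <- simulate_oddball_session(
      design = config$design, rate = config$rate, behavior = config$behavior,
      n_blocks_per_level = config$n_blocks_per_level, seed = config$seed)
  } else {
    session <- simulate_reward_session(
      protocol = config$design, rate = config$rate,
      surprise_decay_trials = config$surprise_decay_trials, seed = config$seed)
  }
  write_session(session, file.path(out_dir, "session.json"))
  logf("simulated %s: %d spikes", session$session_id, length(session$spike_times))

  summary <- list(seed = config$seed, protocol = config$protocol,
                  session_id = session$session_id)
  write_tbl <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }

  if (config$protocol == "oddball") {
    rdi <- session_rdi(session, role = "final")
    write_tbl(rdi[c("block_id", "deviant_level_n", "choice", "outcome",
                    "duration_ms", "fir_late_hz", "fir_after_peak_hz", "rdi")],
              "rdi.csv")
    rdi_by_level <- dplyr::summarise(
      dplyr::group_by(rdi, level_n = .data$deviant_level_n),
      n = dplyr::n(), mean_rdi = mean(.data$rdi), .groups = "drop")
    summary$rdi <- list(mean_all = mean(rdi$rdi), by_level = rdi_by_level)

    profs <- dplyr::bind_rows(
      late = order_profile(session, window_preset("late"), config$analysis$max_order),
      onset = order_profile(session, window_preset("onset"), config$analysis$max_order),
      .id = "window")
    write_tbl(profs, "profiles.csv")
    summary$order_profile <- profs

    pr <- press_ratios(session)
    qc <- session_qc(pr)
    fit <- fit_psychometric(pr)
    write_tbl(dplyr::mutate(pr, a = fit$a, b = fit$b, keep = qc$keep),
              "psychometric.csv")
    summary$psychometric <- c(as.list(glance(fit)), list(qc = as.list(qc)))
    logf("psychometric a=%.3f b=%.3f qc_keep=%s", fit$a, fit$b, qc$keep)

    dp_levels <- setdiff(unique(session$blocks$deviant_level_n), 0)
    dp <- purrr::map(dp_levels, function(lv) {
      tryCatch(glance(detection_probability(
        session, lv, n_perm = config$analysis$n_perm,
        seed = child_seed(config$seed, lv, 3L))),
        error = function(e) {
          logf("detection probability skipped at level %d: %s", lv,
               conditionMessage(e))
          NULL
        })
    })
    dp <- dplyr::bind_rows(dp)
    if (nrow(dp)) write_tbl(dp, "dp.csv")
    summary$detection_probability <- dp

    ur <- tryCatch(unexpected_reward_response(session), error = function(e) {
      logf("unexpected-reward contrast skipped: %s", conditionMessage(e))
      NULL
    })
    if (!is.null(ur)) summary$unexpected_reward <- ur[setdiff(names(ur), "rates")]
  } else {
    rr <- classify_reward_responsive(session)
    pe <- prediction_error_contrast(session, k = config$analysis$k)
    write_tbl(dplyr::bind_cols(glance(rr), glance(pe)), "reward.csv")
    summary$reward_response <- as.list(glance(rr))
    summary$prediction_error <- as.list(glance(pe))
    logf("reward response p=%.3g; PE contrast p=%.3g", rr$p_value, pe$p_reward)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  logf("bundle written to %s", out_dir)
  invisible(summary)
}
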