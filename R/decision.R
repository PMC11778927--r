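#' Area under the ROC curve between two rate distributions
#'
#' The Mann–Whitney construction, exact over all pairs: the proportion of
#' (press, no-press) pairs in which the press-trial rate exceeds the no-press
#' rate, counting ties with weight 1/2. Computed from midranks, which is
#' algebraically identical to explicit pair counting. 0.5 is chance; 1 means
#' every press rate exceeds every no-press rate.
#'
#' @param rates_press,rates_nopress Non-empty numeric vectors of per-trial
#'   firing rates.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(2, 3, 4), c(1, 2, 3))  # 7/9
#' @export
roc_auc <- function(rates_press, rates_nopress) {
  n1 <- length(rates_press); n2 <- length(rates_nopress)
  if (n1 == 0L || n2 == 0L) stop("both classes must be non-empty", call. = FALSE)
  rk <- rank(c(rates_press, rates_nopress))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Permutation test for detection probability
#'
#' Two-sided permutation test of the null that press and no-press rates come
#' from one distribution, using `|AUC - 0.5|` as the statistic. Labels are
#' shuffled preserving class sizes;
#' `p = (1 + #\{permutations at least as extreme\}) / (n_perm + 1)` (the
#' add-one estimator, so p is never 0). When the total number of distinct
#' label arrangements is at most `n_perm`, the test enumerates all of them
#' exactly instead (with a message), and p is the exact tail proportion.
#'
#' @inheritParams roc_auc
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Optional integer seed for the shuffles.
#' @return List with `auc`, `p_value`, `n_perm` (permutations actually used),
#'   `exact` (logical).
#' @export
permutation_test_auc <- function(rates_press, rates_nopress, n_perm = 1999,
                                 seed = NULL) {
  stopifnot(n_perm >= 100)
  n1 <- length(rates_press); n2 <- length(rates_nopress)
  auc_obs <- roc_auc(rates_press, rates_nopress)
  stat_obs <- abs(auc_obs - 0.5)
  rk <- rank(c(rates_press, rates_nopress))
  n <- n1 + n2
  auc_of <- function(idx_mat) {
    # idx_mat: n1 x m matrix of class-1 indices
    u <- colSums(matrix(rk[idx_mat], nrow = n1)) - n1 * (n1 + 1) / 2
    u / (n1 * n2)
  }
  n_arr <- choose(n, n1)
  if (n_arr <= n_perm) {
    message("only ", n_arr, " distinct label arrangements; enumerating exactly")
    idx <- utils::combn(n, n1)
    stat <- abs(auc_of(idx) - 0.5)
    p <- mean(stat >= stat_obs - 1e-12)
    return(list(auc = auc_obs, p_value = p, n_perm = n_arr, exact = TRUE))
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  idx <- replicate(n_perm, sample.int(n, n1))
  stat <- abs(auc_of(idx) - 0.5)
  p <- (1 + sum(stat >= stat_obs - 1e-12)) / (n_perm + 1)
  list(auc = auc_obs, p_value = p, n_perm = n_perm, exact = FALSE)
}

#' Detection probability for one deviant level
#'
#' Splits a level's blocks by the subject's choice, computes per-trial firing
#' rates in a deviant-anchored window (default: the late window, \[-100, 0) ms
#' before deviant offset), and reports the ROC area between the press and
#' no-press distributions with a permutation p-value. Levels are analysed
#' separately, never pooled.
#'
#' @param session An oddball `icdyn_session`.
#' @param level_n Deviant level to analyse (> 0 for an actual deviant).
#' @param window An [analysis_window()] anchored at `sound_onset` or
#'   `sound_offset` of the final sound.
#' @param n_perm,seed Passed to [permutation_test_auc()].
#' @return A `detection_probability` object: list with `auc`, `p_value`,
#'   `n_press`, `n_nopress`, `n_perm`, `exact`, `level_n`, `window`, `rates`
#'   (per-trial tibble). Supports [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @export
detection_probability <- function(session, level_n,
                                  window = window_preset("late"),
                                  n_perm = 1999, seed = NULL) {
  stopifnot(inherits(session, "icdyn_session"), session$protocol == "oddball",
            window$anchor %in% c("sound_onset", "sound_offset"))
  b <- session$blocks[session$blocks$deviant_level_n == level_n, ]
  ev <- session$events[session$events$role != "standard", ]
  ev <- ev[match(b$block_id, ev$block_id), ]
  n_press <- sum(b$choice == "press"); n_nopress <- sum(b$choice == "no_press")
  if (n_press == 0L || n_nopress == 0L) {
    stop("insufficient data at level ", level_n, ": ", n_press, " press and ",
         n_nopress, " no-press trials", call. = FALSE)
  }
  anchor <- if (window$anchor == "sound_onset") ev$onset_s
            else ev$onset_s + ev$duration_ms / 1000
  r <- windowed_rate(session$spike_times, anchor, window)
  press <- r[b$choice == "press"]; nopress <- r[b$choice == "no_press"]
  pt <- permutation_test_auc(press, nopress, n_perm = n_perm, seed = seed)
  structure(list(
    auc = pt$auc, p_value = pt$p_value, n_press = n_press,
    n_nopress = n_nopress, n_perm = pt$n_perm, exact = pt$exact,
    level_n = level_n, window = window,
    rates = tibble::tibble(block_id = b$block_id, choice = b$choice, rate_hz = r)),
    class = "detection_probability")
}

#' @export
print.detection_probability <- function(x, ...) {
  cat(sprintf("<detection_probability> level %d: AUC = %.3f (p = %.3g, %d %s)\n",
              x$level_n, x$auc, x$p_value, x$n_perm,
              if (x$exact) "arrangements, exact" else "permutations"))
  cat(sprintf("  %d press vs %d no-press trials, window [%g, %g) ms re %s\n",
              x$n_press, x$n_nopress, x$window$start_ms, x$window$end_ms,
              x$window$anchor))
  invisible(x)
}
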