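#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return One row per parameter (`a`, `b`) with the estimate.
#' @method tidy psychometric_fit
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @rdname tidy.psychometric_fit
#' @method glance psychometric_fit
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, loglik = x$loglik, converged = x$converged,
                 method = x$method, n_levels = nrow(x$data),
                 n_trials = sum(x$data$n))
}

#' Tidy a detection-probability result
#'
#' @param x A `detection_probability`.
#' @param ... Unused.
#' @return `tidy()` returns the per-trial rates; `glance()` the one-row
#'   summary (AUC, permutation p, counts).
#' @method tidy detection_probability
#' @export
tidy.detection_probability <- function(x, ...) x$rates

#' @rdname tidy.detection_probability
#' @method glance detection_probability
#' @export
glance.detection_probability <- function(x, ...) {
  tibble::tibble(level_n = x$level_n, auc = x$auc, p_value = x$p_value,
                 n_press = x$n_press, n_nopress = x$n_nopress,
                 n_perm = x$n_perm, exact = x$exact)
}

#' Tidy a reward-responsiveness result
#'
#' @param x A `reward_response`.
#' @param ... Unused.
#' @method tidy reward_response
#' @export
tidy.reward_response <- function(x, ...) x$trials

#' @rdname tidy.reward_response
#' @method glance reward_response
#' @export
glance.reward_response <- function(x, ...) {
  tibble::tibble(pre_rate_hz = x$pre_rate_hz, post_rate_hz = x$post_rate_hz,
                 p_value = x$p_value, responsive = x$responsive,
                 alpha = x$alpha, n_trials = x$n_trials)
}

#' Tidy a reward-prediction-error contrast
#'
#' @param x A `prediction_error_contrast`.
#' @param ... Unused.
#' @method tidy prediction_error_contrast
#' @export
tidy.prediction_error_contrast <- function(x, ...) x$rates

#' @rdname tidy.prediction_error_contrast
#' @method glance prediction_error_contrast
#' @export
glance.prediction_error_contrast <- function(x, ...) {
  tibble::tibble(k = x$k,
                 first_block_rate_hz = x$first_block_rate_hz,
                 last_block_rate_hz = x$last_block_rate_hz,
                 auditory_first_hz = x$auditory_first_hz,
                 auditory_last_hz = x$auditory_last_hz,
                 p_reward = x$p_reward, p_auditory = x$p_auditory)
}
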