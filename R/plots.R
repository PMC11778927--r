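#' Plot a PSTH
#'
#' @param object A `psth` from [compute_psth()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psth
#' @export
autoplot.psth <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid_ms, y = .data$rate_hz)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = sprintf("time re %s (ms)", attr(object, "anchor")),
                  y = "firing rate (Hz)",
                  subtitle = sprintf("%d trials, %g ms bins",
                                     attr(object, "n_trials"),
                                     attr(object, "bin_ms"))) +
    ggplot2::theme_minimal()
}

#' Plot a psychometric fit
#'
#' Observed press ratios with the fitted cumulative-Gaussian curve.
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psychometric_fit
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  grid <- tibble::tibble(r = seq(min(object$data$r) * 0.95,
                                 max(object$data$r) * 1.05, length.out = 200))
  grid$p <- psychometric_eval(object$a, object$b, grid$r)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$r, y = .data$ratio)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "deviant / standard duration ratio", y = "press ratio",
                  subtitle = sprintf("a = %.3f, b = %.3f", object$a, object$b)) +
    ggplot2::theme_minimal()
}

#' Plot an order profile
#'
#' @param profile Tibble from [order_profile()].
#' @return A ggplot of the normalised rate against stimulus order.
#' @export
plot_order_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$order, y = .data$normalized)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "stimulus order in block",
                  y = "rate normalised to first stimulus") +
    ggplot2::theme_minimal()
}

#' Plot press/no-press rate distributions behind a detection probability
#'
#' @param object A `detection_probability`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot detection_probability
#' @export
autoplot.detection_probability <- function(object, ...) {
  ggplot2::ggplot(object$rates, ggplot2::aes(x = .data$rate_hz, fill = .data$choice)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 15) +
    ggplot2::labs(x = "late-window rate (Hz)", y = "trials",
                  subtitle = sprintf("level %d: AUC = %.3f, p = %.3g",
                                     object$level_n, object$auc, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
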