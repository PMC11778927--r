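#' Cumulative-Gaussian psychometric function
#'
#' Press probability as a function of the deviant/standard duration ratio `r`:
#' the integral of a Gaussian with mean `a` and SD `b` from 0 to `r`, i.e.
#' `p(r) = Phi((r - a)/b) - Phi(-a/b)`. The integral starts at 0 (a duration
#' ratio cannot be negative), so the asymptote is `1 - Phi(-a/b)` — strictly
#' below 1, though negligibly so when `a/b` is large.
#'
#' @param a Location in duration-ratio units.
#' @param b Spread in ratio units (> 0).
#' @param r Duration ratio(s), >= 0.
#' @return Probability in `[0, 1)`, vectorised over `r`.
#' @examples
#' psychometric_eval(1.3, 0.15, c(1, 1.19, 1.19^4))
#' @export
psychometric_eval <- function(a, b, r) {
  if (!is.numeric(b) || b <= 0) stop("`b` must be > 0", call. = FALSE)
  stopifnot(all(r >= 0))
  stats::pnorm((r - a) / b) - stats::pnorm(-a / b)
}

#' Fit the psychometric function by binomial maximum likelihood
#'
#' Estimates location `a` and spread `b` of [psychometric_eval()] from
#' per-level press counts by maximising the binomial log-likelihood, with
#' multi-start Nelder–Mead over `(a, log b)`. Degenerate data (every level all
#' presses or all non-presses) cannot identify the parameters; the fit then
#' returns boundary-ish values with `converged = FALSE` and a warning.
#'
#' @param data Data frame with one row per level and columns `r` (duration
#'   ratio), `k` (presses), `n` (trials); at least 3 distinct levels.
#' @param least_squares Fit by least squares on the press ratios instead of
#'   the binomial likelihood (for comparison only).
#' @return A `psychometric_fit` object: list with `a`, `b`, `loglik`,
#'   `converged`, `data` (augmented with fitted probabilities), `method`.
#'   Supports [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [ggplot2::autoplot()].
#' @examples
#' d <- tibble::tibble(r = 1.19^(0:4), n = 40,
#'                     k = rbinom(5, 40, psychometric_eval(1.3, 0.15, 1.19^(0:4))))
#' fit_psychometric(d)
#' @export
fit_psychometric <- function(data, least_squares = FALSE) {
  stopifnot(is.data.frame(data), all(c("r", "k", "n") %in% names(data)))
  data <- tibble::as_tibble(data)[c("r", "k", "n")]
  stopifnot(all(data$k >= 0), all(data$k <= data$n), all(data$n > 0))
  if (length(unique(data$r)) < 3) {
    stop("need at least 3 distinct levels to fit", call. = FALSE)
  }
  data <- data[order(data$r), ]
  ratio <- data$k / data$n
  degenerate <- all(data$k == 0) || all(data$k == data$n) ||
    stats::sd(ratio) == 0

  objective <- if (least_squares) {
    function(par) {
      p <- psychometric_eval(par[1], exp(par[2]), data$r)
      sum((ratio - p)^2)
    }
  } else {
    function(par) {
      p <- pmin(pmax(psychometric_eval(par[1], exp(par[2]), data$r), 1e-12),
                1 - 1e-12)
      -sum(data$k * log(p) + (data$n - data$k) * log(1 - p))
    }
  }

  # moment start: location where the ratio crosses 1/2, spread from the range
  a0 <- tryCatch(stats::approx(ratio, data$r, xout = 0.5, ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(a0)) a0 <- mean(range(data$r))
  spread0 <- diff(range(data$r)) / 4
  starts <- rbind(c(a0, log(spread0)),
                  c(mean(data$r), log(spread0 / 2)),
                  c(max(data$r), log(spread0 * 2)))
  fits <- apply(starts, 1L, function(s) {
    stats::optim(s, objective, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  converged <- best$convergence == 0 && !degenerate && exp(best$par[2]) < 1e3
  if (degenerate) {
    warning("psychometric data are flat; parameters not identifiable", call. = FALSE)
  }
  fitted_p <- psychometric_eval(best$par[1], exp(best$par[2]), data$r)
  structure(list(
    a = unname(best$par[1]), b = unname(exp(best$par[2])),
    loglik = if (least_squares) NA_real_ else -best$value,
    objective = best$value,
    converged = converged,
    method = if (least_squares) "least_squares" else "binomial_ml",
    data = tibble::tibble(data, ratio = ratio, fitted = fitted_p)),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> a = %.4f, b = %.4f (%s%s)\n", x$a, x$b,
              x$method, if (x$converged) "" else ", NOT converged"))
  print(x$data)
  invisible(x)
}

#' Per-level press ratios of an oddball session
#'
#' @param session An oddball `icdyn_session`.
#' @return Tibble with `level_n`, `r` (duration ratio), `n` (blocks), `k`
#'   (presses), `ratio`.
#' @export
press_ratios <- function(session) {
  stopifnot(inherits(session, "icdyn_session"), session$protocol == "oddball")
  d <- session$design
  dplyr::summarise(
    dplyr::group_by(session$blocks, level_n = .data$deviant_level_n),
    n = dplyr::n(), k = sum(.data$choice == "press"),
    .groups = "drop") |>
    dplyr::mutate(r = d$lambda^.data$level_n, ratio = .data$k / .data$n) |>
    dplyr::select("level_n", "r", "n", "k", "ratio")
}

#' Behavioural session quality control
#'
#' A session is kept only when the subject pressed on fewer than 10% of
#' control blocks (reliable correct rejection) and on more than 85% of
#' maximal-level blocks (reliable hits). Both inequalities are strict.
#'
#' @param ratios Tibble as returned by [press_ratios()] (columns `level_n`,
#'   `ratio`), or an oddball `icdyn_session`.
#' @return Tibble with one row: `keep`, `control_ratio`, `max_level_ratio`,
#'   `reasons` (empty string when kept).
#' @export
session_qc <- function(ratios) {
  if (inherits(ratios, "icdyn_session")) ratios <- press_ratios(ratios)
  stopifnot(all(c("level_n", "ratio") %in% names(ratios)))
  if (!0 %in% ratios$level_n) stop("control level (0) missing", call. = FALSE)
  max_lev <- max(ratios$level_n)
  if (max_lev == 0) stop("no deviant level present", call. = FALSE)
  p0 <- ratios$ratio[ratios$level_n == 0]
  pmax_ <- ratios$ratio[ratios$level_n == max_lev]
  reasons <- c(
    if (!(p0 < 0.1)) "correct-rejection criterion (control press ratio >= 0.1)",
    if (!(pmax_ > 0.85)) "hit criterion (max-level press ratio <= 0.85)")
  tibble::tibble(keep = length(reasons) == 0L, control_ratio = p0,
                 max_level_ratio = pmax_,
                 reasons = paste(reasons, collapse = "; "))
}
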