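#' Four-parameter declining logistic drying curve
#'
#' The seasonal course of live fuel moisture content (LFMC) through a fire
#' season is well described by a four-parameter logistic curve that declines
#' from an upper asymptote `A` (moisture at the start of the fire season) to a
#' lower asymptote `w` (the stabilised end-of-season minimum),
#' \deqn{y(t) = w + \frac{A - w}{1 + e^{(m - t)/s}},}
#' where `m` is the inflection time (the day of fastest drying) and `s` is a
#' steepness scale in days, negative for a declining curve.  At `t = m` the
#' curve passes exactly through the midpoint `(A + w)/2`.
#'
#' @param t Numeric vector of times, in days since the first measurement.
#' @param A Upper asymptote (LFMC, percent of dry weight).
#' @param w Lower asymptote (LFMC, percent).
#' @param m Inflection time (days).
#' @param s Steepness scale (days); must be non-zero, negative for drying.
#'
#' @return Numeric vector of LFMC values (percent), one per element of `t`.
#' @seealso [lfmc_logistic_rate()] for the instantaneous drying speed,
#'   [lfmc_self_start()] for data-driven initial values.
#' @examples
#' lfmc_logistic(c(0, 30, 89), A = 100, w = 20, m = 30, s = -16)
#' @export
lfmc_logistic <- function(t, A, w, m, s) {
  check_logistic_params(A, w, m, s)
  if (!all(is.finite(t))) {
    abort("`t` must be finite.", class = "fuelmoist_invalid_parameter")
  }
  w + (A - w) / (1 + exp((m - t) / s))
}

#' Instantaneous drying rate of the logistic curve
#'
#' Analytic first derivative of [lfmc_logistic()] with respect to time,
#' \deqn{\frac{dy}{dt} = \frac{(A - w)\,E}{s\,(1 + E)^2}, \quad
#'       E = e^{(m - t)/s},}
#' interpreted as the instantaneous drying speed in LFMC percentage points per
#' day.  For a declining curve (`A > w`, `s < 0`) it is negative everywhere,
#' with the largest magnitude `(A - w)/(4s)` at `t = m`, and it is symmetric
#' about `m`.
#'
#' @inheritParams lfmc_logistic
#' @return Numeric vector of drying rates (LFMC percent per day).
#' @examples
#' lfmc_logistic_rate(30, A = 100, w = 20, m = 30, s = -16)  # (A - w) / (4 s)
#' @export
lfmc_logistic_rate <- function(t, A, w, m, s) {
  check_logistic_params(A, w, m, s)
  if (!all(is.finite(t))) {
    abort("`t` must be finite.", class = "fuelmoist_invalid_parameter")
  }
  # E/(1+E)^2 written via the logistic cdf P = 1/(1+E) so it underflows
  # gracefully for |m - t| >> |s|
  P <- 1 / (1 + exp((m - t) / s))
  (A - w) * P * (1 - P) / s
}

check_logistic_params <- function(A, w, m, s) {
  vals <- c(A = A, w = w, m = m, s = s)
  if (!all(is.finite(vals))) {
    abort("Logistic parameters must all be finite.",
          class = "fuelmoist_invalid_parameter")
  }
  if (any(s == 0)) {
    abort("Steepness `s` must be non-zero.",
          class = "fuelmoist_invalid_parameter")
  }
  invisible(TRUE)
}

#' Self-starting initial values for the logistic drying curve
#'
#' Produces finite starting values for iterative fitting of the
#' four-parameter logistic from raw data alone.  The asymptotes are anchored
#' at the means of the largest and smallest responses, expanded by
#' `epsilon = 0.05 * range(y)` so every observation lies strictly between
#' them; the logit transform
#' `z = log((A0 - y) / (y - w0))` is then linear in time,
#' `z = m/s - t/s`, and an ordinary least-squares line through `(t, z)`
#' yields `s0 = -1/slope` and `m0 = intercept * s0`.  The sign of `s0`
#' follows the empirical trend: declining data give `s0 < 0`.
#'
#' @param data A data frame containing the time and response columns, or
#'   `NULL` when `t` and `y` are given directly.
#' @param t,y Column names (when `data` is supplied) or numeric vectors of
#'   days and LFMC values.
#' @return A one-row tibble with columns `A`, `w`, `m`, `s`.
#' @examples
#' d <- tibble::tibble(day = seq(0, 90, by = 2),
#'                     lfmc = lfmc_logistic(day, 100, 20, 30, -16))
#' lfmc_self_start(d, t = day, y = lfmc)
#' @export
lfmc_self_start <- function(data = NULL, t = day, y = lfmc) {
  if (is.null(data)) {
    tv <- t
    yv <- y
  } else {
    tv <- dplyr::pull(data, {{ t }})
    yv <- dplyr::pull(data, {{ y }})
  }
  ok <- is.finite(tv) & is.finite(yv)
  tv <- tv[ok]
  yv <- yv[ok]
  if (length(yv) < 5 || length(unique(tv)) < 3) {
    abort("Self-start needs at least 5 points with at least 3 distinct times.",
          class = "fuelmoist_insufficient_data")
  }
  rng <- diff(range(yv))
  if (rng == 0) {
    abort("Self-start is undefined for a constant response.",
          class = "fuelmoist_degenerate_data")
  }
  k <- max(3L, ceiling(0.1 * length(yv)))
  ys <- sort(yv)
  eps <- 0.05 * rng
  A0 <- max(mean(tail(ys, k)) + eps, max(yv) + 1e-3 * rng)
  w0 <- min(mean(head(ys, k)) - eps, min(yv) - 1e-3 * rng)
  z <- log((A0 - yv) / (yv - w0))
  fit <- lm(z ~ tv)
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope == 0) {
    abort("Self-start logit regression is degenerate.",
          class = "fuelmoist_degenerate_data")
  }
  s0 <- -1 / slope
  m0 <- coef(fit)[[1]] * s0
  tibble::tibble(A = A0, w = w0, m = m0, s = s0)
}
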