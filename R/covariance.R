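#' Per-stratum residual standard deviations (varIdent)
#'
#' A varIdent variance function gives each stratum of a grouping factor its
#' own residual standard deviation, expressed as a reference SD
#' (`sigma_base`, the SD of the reference stratum) multiplied by per-stratum
#' ratios `delta`; the reference ratio is fixed at 1.
#'
#' @param sigma_base Reference residual SD (LFMC percent); positive scalar.
#' @param delta Named numeric vector of ratios to `sigma_base` for the
#'   non-reference strata, e.g. `c(GE = 0.9, SM = 3.2, SS = 3.0)`; all
#'   positive.
#' @param reference Label of the reference stratum (default `"GW"`).
#' @return An object of class `var_ident`.
#' @examples
#' vi <- var_ident(7.1, c(GE = 0.9, SM = 3.2, SS = 3.0))
#' varident_sd(vi, c("GW", "SM", "GE"))
#' @export
var_ident <- function(sigma_base, delta = numeric(), reference = "GW") {
  stopifnot(is.numeric(sigma_base), length(sigma_base) == 1L)
  if (!is.finite(sigma_base) || sigma_base <= 0) {
    abort("`sigma_base` must be a positive number.",
          class = "fuelmoist_invalid_parameter")
  }
  if (length(delta) && (is.null(names(delta)) || any(!nzchar(names(delta))))) {
    abort("`delta` must be a named vector of stratum ratios.",
          class = "fuelmoist_invalid_parameter")
  }
  if (any(!is.finite(delta) | delta <= 0)) {
    abort("All variance ratios must be positive.",
          class = "fuelmoist_invalid_parameter")
  }
  if (reference %in% names(delta)) {
    abort("The reference stratum must not appear in `delta` (its ratio is 1).",
          class = "fuelmoist_invalid_parameter")
  }
  structure(list(sigma_base = sigma_base, delta = delta, reference = reference),
            class = "var_ident")
}

#' Evaluate varIdent standard deviations over a stratum vector
#'
#' @param spec A [var_ident()] specification.
#' @param strata Character (or factor) vector of stratum labels.
#' @return Numeric vector of residual SDs, `sigma_base * delta[stratum]`,
#'   with the reference stratum receiving exactly `sigma_base`.
#' @export
varident_sd <- function(spec, strata) {
  stopifnot(inherits(spec, "var_ident"))
  strata <- as.character(strata)
  ratio <- c(setNames(1, spec$reference), spec$delta)
  unknown <- setdiff(unique(strata), names(ratio))
  if (length(unknown)) {
    abort(paste0("Unknown stratum label(s): ", paste(unknown, collapse = ", ")),
          class = "fuelmoist_labeling_error")
  }
  unname(spec$sigma_base * ratio[strata])
}

#' ARMA residual correlation specification
#'
#' Stationary autoregressive--moving-average correlation for within-series
#' residuals at integer time positions (here, sampling-date ranks).  Orders
#' up to (1, 1) are supported: (0,0) is white noise, (1,0) an AR(1), (0,1) an
#' MA(1) and (1,1) the mixed model.  Stationarity/invertibility requires
#' `|rho| < 1` and `|theta| < 1`.
#'
#' @param p,q Non-negative integer orders (autoregressive, moving-average);
#'   at most 1 each.
#' @param rho Autoregressive coefficient (length `p`).
#' @param theta Moving-average coefficient (length `q`).
#' @return An object of class `corr_arma`.
#' @examples
#' arma_correlation(corr_arma(1, 0, rho = 0.5), n = 4)
#' @export
corr_arma <- function(p = 0L, q = 0L, rho = numeric(), theta = numeric()) {
  p <- as.integer(p)
  q <- as.integer(q)
  if (p < 0 || q < 0 || p > 1 || q > 1) {
    abort("Only ARMA orders (0,0), (1,0), (0,1) and (1,1) are supported.",
          class = "fuelmoist_unsupported_order")
  }
  if (length(rho) != p || length(theta) != q) {
    abort("`rho` must have length p and `theta` length q.",
          class = "fuelmoist_invalid_parameter")
  }
  if (any(abs(rho) >= 1) || any(abs(theta) >= 1)) {
    abort("Stationarity/invertibility requires |rho| < 1 and |theta| < 1.",
          class = "fuelmoist_nonstationary")
  }
  structure(list(p = p, q = q, rho = rho, theta = theta), class = "corr_arma")
}

#' Stationary ARMA correlation matrix
#'
#' Builds the `n` x `n` correlation matrix of a stationary ARMA process at
#' integer lags (a symmetric positive-definite Toeplitz matrix with unit
#' diagonal).  For an AR(1) the lag-`k` entry is `rho^k`; for an ARMA(1,1)
#' the lag-1 autocorrelation is
#' `(1 + rho * theta) * (rho + theta) / (1 + theta^2 + 2 * rho * theta)` and
#' higher lags decay geometrically with `rho`.
#'
#' @param spec A [corr_arma()] specification.
#' @param n Series length (number of distinct time positions), `n >= 1`.
#' @param positions Optional integer vector of time positions (defaults to
#'   `1:n`); lags are differences in position, so series with missing dates
#'   get the correct longer-lag correlations.
#' @return An `n` x `n` correlation matrix.
#' @export
arma_correlation <- function(spec, n, positions = seq_len(n)) {
  stopifnot(inherits(spec, "corr_arma"), n >= 1, length(positions) == n)
  if (spec$p == 0 && spec$q == 0) {
    return(diag(1, n))
  }
  max_lag <- max(positions) - min(positions)
  rho_k <- c(1, if (max_lag > 0) {
    ARMAacf(ar = spec$rho, ma = spec$theta, lag.max = max_lag)[-1]
  })
  lag <- abs(outer(positions, positions, "-"))
  matrix(rho_k[lag + 1L], n, n)
}

#' Assemble a within-group residual covariance block
#'
#' Composes the heteroscedastic SDs and the serial correlation into the
#' within-group covariance `Sigma = diag(sds) %*% corr %*% diag(sds)`.
#'
#' @param sds Positive numeric vector of per-observation SDs.
#' @param corr Correlation matrix of matching dimension.
#' @return The covariance matrix, symmetric with `Sigma[i, i] = sds[i]^2`.
#' @export
assemble_group_covariance <- function(sds, corr) {
  n <- length(sds)
  if (!is.matrix(corr) || nrow(corr) != n || ncol(corr) != n) {
    abort("`corr` must be a square matrix matching length(sds).",
          class = "fuelmoist_shape_error")
  }
  if (any(!is.finite(sds) | sds <= 0)) {
    abort("`sds` must be positive and finite.",
          class = "fuelmoist_invalid_parameter")
  }
  corr * tcrossprod(sds)
}
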