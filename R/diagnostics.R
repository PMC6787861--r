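#' Residuals backing the assumption checks
#'
#' Computes the three residual flavours used to check the drying model's
#' assumptions, at plot level (conditional on the random-effect modes):
#' raw residuals, Pearson residuals (raw divided by the modelled
#' per-observation SD) and normalized residuals (Pearson residuals
#' pre-multiplied, series by series, by the inverse Cholesky factor of the
#' estimated within-series correlation, so a correctly specified model
#' leaves approximately iid standard-normal values).  For independence
#' structures the normalized residuals equal the Pearson residuals.
#'
#' @param fit An `lfmc_fit`.
#' @param level `"plot"` (default; conditional on the random-effect modes)
#'   or `"population"` (fixed effects only).
#' @return A tibble in the original row order with the design columns plus
#'   `.fitted`, `.resid`, `.pearson`, `.normalized`, `series`, `date_rank`.
#' @export
lfmc_residuals <- function(fit, level = c("plot", "population")) {
  stopifnot(inherits(fit, "lfmc_fit"))
  level <- match.arg(level)
  aug <- augment(fit)
  if (level == "population") {
    aug$.resid <- aug$lfmc - aug$.fitted_pop
    aug$.pearson <- aug$.resid / aug$.sd
  }
  spec <- fit$spec
  if (is.null(spec$correlation)) {
    aug$.normalized <- aug$.pearson
    return(aug)
  }
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  cs <- corr_arma(spec$correlation$p, spec$correlation$q,
                  rho = if (spec$correlation$p) est[["rho"]] else numeric(),
                  theta = if (spec$correlation$q) est[["theta"]] else numeric())
  aug$.normalized <- NA_real_
  for (idx in split(seq_len(nrow(aug)), aug$series)) {
    o <- idx[order(aug$date_rank[idx])]
    R <- arma_correlation(cs, length(o), positions = aug$date_rank[o])
    aug$.normalized[o] <- backsolve(chol(R), aug$.pearson[o],
                                    transpose = TRUE)
  }
  aug
}

#' Numeric residual summaries for assumption checking
#'
#' Summarises a residual set into the quantities the usual four diagnostic
#' panels display: per-leaf-type SD of the Pearson residuals
#' (heteroscedasticity), lag-1..3 autocorrelations of the normalized
#' residuals per series (serial dependence; `NA` when a series is too
#' short), observed-vs-normal quantile pairs (normality), and a
#' location-scale trend statistic, the correlation of the absolute Pearson
#' residual with the fitted value.
#'
#' @param res A residual tibble from [lfmc_residuals()].
#' @return A list with tibbles `by_stratum`, `autocorrelation`, `qq` and
#'   the scalar `trend`.
#' @export
residual_summaries <- function(res) {
  if (!nrow(res)) {
    abort("Empty residual set.", class = "fuelmoist_empty_input")
  }
  by_stratum <- res |>
    dplyr::group_by(.data$leaf_type) |>
    dplyr::summarise(n = dplyr::n(), sd_pearson = sd(.data$.pearson),
                     mean_pearson = mean(.data$.pearson), .groups = "drop")
  autoc <- res |>
    dplyr::group_by(.data$series) |>
    dplyr::arrange(.data$date_rank, .by_group = TRUE) |>
    dplyr::summarise(n = dplyr::n(),
                     lag1 = series_acf(.data$.normalized, 1),
                     lag2 = series_acf(.data$.normalized, 2),
                     lag3 = series_acf(.data$.normalized, 3),
                     .groups = "drop")
  zn <- sort(res$.normalized)
  qq <- tibble::tibble(theoretical = qnorm(ppoints(length(zn))),
                       observed = zn)
  trend <- if (sd(res$.fitted) == 0 || sd(abs(res$.pearson)) == 0) {
    NA_real_
  } else {
    cor(abs(res$.pearson), res$.fitted)
  }
  list(by_stratum = by_stratum, autocorrelation = autoc,
       qq = qq, trend = trend)
}

series_acf <- function(x, lag) {
  n <- length(x)
  if (n <= lag + 1L || sd(x) == 0) return(NA_real_)
  x <- x - mean(x)
  sum(x[seq_len(n - lag)] * x[-seq_len(lag)]) / sum(x^2)
}

#' Descriptive intraclass correlation under the fitted model
#'
#' The within-plot correlation induced by the plot-level random effects has
#' no closed form for a nonlinear mean, so it is reported descriptively: a
#' large number of within-plot observation pairs are simulated under the
#' fitted model (at design points resampled from the data) and their
#' empirical correlation returned.
#'
#' @param fit An `lfmc_fit`.
#' @param n_pairs Number of simulated within-plot pairs.
#' @param seed Seed for the simulation.
#' @return Scalar correlation estimate.
#' @export
lfmc_icc <- function(fit, n_pairs = 1e4, seed = 1L) {
  stopifnot(inherits(fit, "lfmc_fit"))
  spec <- fit$spec
  if (!length(spec$random)) return(0)
  set.seed(seed)
  d <- fit$mf$df
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  i1 <- sample.int(nrow(d), n_pairs, replace = TRUE)
  i2 <- sample.int(nrow(d), n_pairs, replace = TRUE)
  phi_pop <- resolve_parameters(fit,
                                d |> dplyr::arrange(.data$.row),
                                "population")
  sim_at <- function(rows, b) {
    phi <- lapply(phi_pop$phi, function(v) v[rows])
    for (p in spec$random) {
      phi[[p]] <- phi[[p]] + b[[p]]
    }
    mu <- mean_fun(spec$mean, phi, phi_pop$day[rows])
    sds <- fit$fitted$.sd[rows]
    rnorm(length(rows), mu, sds)
  }
  b <- lapply(spec$random, function(p) rnorm(n_pairs, 0, est[[paste0("sd_", p)]]))
  names(b) <- spec$random
  y1 <- sim_at(i1, b)
  y2 <- sim_at(i2, b)
  cor(y1, y2)
}

# ---- plotting -------------------------------------------------------------

#' Diagnostic and prediction plots for an LFMC fit
#'
#' @param object An `lfmc_fit`.
#' @param type `"fit"` (data with population and plot-level curves by leaf
#'   type), `"residuals"` (the four assumption-check panels: standardized
#'   residuals vs fitted, vs leaf type, vs time, and a normal Q-Q plot) or
#'   `"rate"` (the drying-speed curves).
#' @param ... Unused.
#' @return A ggplot object (a patchwork of four panels for
#'   `type = "residuals"` when patchwork is installed, else a single
#'   faceted plot).
#' @method autoplot lfmc_fit
#' @export
autoplot.lfmc_fit <- function(object, type = c("fit", "residuals", "rate"),
                              ...) {
  type <- match.arg(type)
  aug <- augment(object)
  if (type == "fit") {
    grid <- tidyr::expand_grid(
      leaf_type = factor(object$mf$leaf_levels,
                         levels = lfmc_leaf_levels()),
      day = seq(min(aug$day), max(aug$day), length.out = 80))
    grid$.pred <- predict(object, grid, level = "population")
    return(
      ggplot2::ggplot(aug, ggplot2::aes(x = .data$day, y = .data$lfmc)) +
        ggplot2::geom_point(alpha = 0.4, size = 0.9) +
        ggplot2::geom_line(data = grid,
                           ggplot2::aes(y = .data$.pred),
                           colour = "#2166ac", linewidth = 0.9) +
        ggplot2::facet_wrap(~leaf_type, scales = "free_y") +
        ggplot2::labs(x = "Days since first measurement",
                      y = "LFMC (%)",
                      title = "Fitted drying curves (population level)") +
        ggplot2::theme_minimal()
    )
  }
  if (type == "rate") {
    grid <- tidyr::expand_grid(
      leaf_type = factor(object$mf$leaf_levels,
                         levels = lfmc_leaf_levels()),
      day = seq(min(aug$day), max(aug$day), length.out = 120))
    grid$.rate <- lfmc_drying_speed(object, grid)
    return(
      ggplot2::ggplot(grid, ggplot2::aes(x = .data$day, y = .data$.rate,
                                         colour = .data$leaf_type)) +
        ggplot2::geom_line(linewidth = 0.9) +
        ggplot2::labs(x = "Days since first measurement",
                      y = "Drying speed (LFMC %/day)", colour = "Leaf type",
                      title = "Instantaneous drying speed") +
        ggplot2::theme_minimal()
    )
  }
  res <- lfmc_residuals(object)
  p1 <- ggplot2::ggplot(res, ggplot2::aes(.data$.fitted, .data$.pearson)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Fitted", y = "Standardized residuals") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(res, ggplot2::aes(.data$leaf_type, .data$.pearson)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Leaf type", y = "Standardized residuals") +
    ggplot2::theme_minimal()
  p3 <- ggplot2::ggplot(res, ggplot2::aes(.data$day, .data$.normalized)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Day", y = "Normalized residuals") +
    ggplot2::theme_minimal()
  p4 <- ggplot2::ggplot(res, ggplot2::aes(sample = .data$.normalized)) +
    ggplot2::stat_qq(alpha = 0.5) + ggplot2::stat_qq_line() +
    ggplot2::labs(x = "Normal quantiles", y = "Observed quantiles") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    (p1 + p2) / (p3 + p4)
  } else {
    long <- dplyr::bind_rows(
      tibble::tibble(panel = "vs fitted", x = res$.fitted,
                     y = res$.pearson),
      tibble::tibble(panel = "vs day", x = res$day, y = res$.normalized))
    ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::facet_wrap(~panel, scales = "free_x") +
      ggplot2::theme_minimal()
  }
}
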