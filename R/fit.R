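#' Fit an LFMC model by marginal maximum likelihood
#'
#' Estimates all parameters of an [lfmc_model()] specification by maximising
#' the marginal likelihood (ML, not REML -- ML is required for AIC
#' comparisons across fixed-effect structures).  Standard deviations and
#' variance ratios are optimised on the log scale and ARMA coefficients
#' through an inverse hyperbolic tangent, so the optimisation is
#' unconstrained; a short derivative-free polish of the starting values is
#' followed by a quasi-Newton search, with up to `restarts` jittered
#' restarts on non-convergence.  Standard errors come from the inverse
#' numerical Hessian; 95 percent Wald intervals are computed on the
#' transformed scale and mapped back, so intervals for SDs and ratios are
#' asymmetric (log-normal style) as is conventional for variance components.
#'
#' @param data Observation table with columns `site`, `plot`, `point`,
#'   `leaf_type` (GW/GE/SM/SS), `day` (days since first measurement) and
#'   `lfmc` (percent).
#' @param spec An [lfmc_model()] specification (default:
#'   [lfmc_final_model()]).
#' @param start Optional named vector of natural-scale starting values; by
#'   default self-starting values are derived from the data
#'   ([lfmc_self_start()] per leaf type).
#' @param method Marginal-likelihood path: `"auto"` picks the exact Gaussian
#'   integral when all random effects enter linearly, adaptive
#'   Gauss--Hermite quadrature for up to two nonlinear random-effect
#'   dimensions and a Laplace approximation beyond.
#' @param nodes Quadrature nodes per dimension (default 7).
#' @param restarts Maximum jittered restarts after non-convergence.
#' @param seed Seed for the restart jitter (fits are otherwise
#'   deterministic).
#' @param self_attempt When a warm `start` is supplied, also try the
#'   self-derived starting values and keep the better optimum (default);
#'   `FALSE` accepts a converged warm-started fit directly.
#' @param control List overriding `nlminb` control parameters.
#' @return An object of class `lfmc_fit`; see [tidy.lfmc_fit()],
#'   [glance.lfmc_fit()], [augment.lfmc_fit()], [predict.lfmc_fit()].
#' @examples
#' d <- simulate_lfmc(lfmc_design(), lfmc_truth(), seed = 42)
#' fit <- fit_lfmc(d, lfmc_final_model())
#' glance(fit)
#' @export
fit_lfmc <- function(data, spec = lfmc_final_model(), start = NULL,
                     method = c("auto", "exact", "agq", "laplace"),
                     nodes = 7L, restarts = 5L, seed = 1L,
                     self_attempt = TRUE, control = list()) {
  method <- match.arg(method)
  cl <- match.call()
  mf <- prepare_model_frame(data, spec)
  ev <- make_evaluator(mf, spec, method = method, nodes = nodes)

  theta0 <- make_start(mf, spec, start)
  obj <- function(theta) {
    v <- ev$nll(theta)
    if (!is.finite(v)) 1e12 else v
  }
  ctrl <- utils::modifyList(list(rel.tol = 1e-10, eval.max = 20000L,
                                 iter.max = 2000L), control)
  # box bounds on the transformed scale: log-SDs are kept above e^-7 (the
  # boundary detector for vanishing variance components), correlations
  # inside tanh(+/-5)
  lower <- ifelse(mf$par_tab$transform == "log", -7,
                  ifelse(mf$par_tab$transform == "tanh", -5, -Inf))
  upper <- ifelse(mf$par_tab$transform == "log", 12,
                  ifelse(mf$par_tab$transform == "tanh", 5, Inf))

  # acceptably converged: nlminb success, or a small projected gradient
  grad_ok <- function(res) {
    g <- num_gradient(obj, res$par)
    free <- res$par > lower + 1e-6 & res$par < upper - 1e-6
    gn <- if (any(free)) max(abs(g[free])) else 0
    list(ok = all(is.finite(g[free])) &&
           gn < max(1e-3 * max(1, abs(res$objective)), 1e-4),
         norm = gn)
  }

  # attempt sequence: the caller's warm start (if any), then the
  # self-derived start, then seeded jitters of the latter; with
  # self_attempt = FALSE a converged warm start is accepted directly
  theta_self <- if (is.null(start)) theta0 else make_start(mf, spec, NULL)
  min_attempts <- if (is.null(start) || !self_attempt) 0L else 1L
  if (!is.null(start) && !self_attempt) theta_self <- theta0

  best <- NULL
  best_g <- NULL
  set.seed(seed)
  for (attempt in 0:(restarts + min_attempts)) {
    th <- if (attempt == 0) theta0
    else if (attempt == min_attempts) theta_self
    else theta_self + rnorm(length(theta_self), 0,
                            0.2 * (1 + abs(theta_self)))
    th <- pmin(pmax(th, lower + 1e-3), upper - 1e-3)
    # derivative-free polish of the starting values (shorter for the warm
    # start, which is already near an optimum)
    polish <- tryCatch(
      optim(th, obj, method = "Nelder-Mead",
            control = list(maxit = if (attempt == 0 && !is.null(start))
              100L else 250L)),
      error = function(e) list(par = th))
    res <- tryCatch(nlminb(pmin(pmax(polish$par, lower), upper), obj,
                           lower = lower, upper = upper, control = ctrl),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective) ||
        res$objective > 1e11) next
    g <- grad_ok(res)
    if (is.null(best) || res$objective < best$objective - 1e-8) {
      best <- res
      best_g <- g
    }
    if (attempt >= min_attempts && !is.null(best) &&
        (best$convergence == 0 || best_g$ok)) break
  }
  if (is.null(best)) {
    abort("Optimisation failed on every attempt.",
          class = "fuelmoist_convergence_error")
  }
  theta_hat <- setNames(best$par, mf$par_tab$name)
  nll <- best$objective
  converged <- best$convergence == 0 || best_g$ok
  boundary <- any(mf$par_tab$transform == "log" & theta_hat < -6.5)

  H <- tryCatch(pracma::hessian(obj, theta_hat), error = function(e) NULL)
  V <- NULL
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && any(!is.finite(V))) V <- NULL
    if (!is.null(V) && any(diag(V) < 0)) {
      # near-singular information (typically an SD at the boundary)
      diag(V) <- pmax(diag(V), 0)
    }
  }
  if (is.null(V)) {
    V <- matrix(NA_real_, length(theta_hat), length(theta_hat))
  }
  dimnames(V) <- list(mf$par_tab$name, mf$par_tab$name)

  det_ <- ev$detail(theta_hat)
  k <- length(theta_hat)
  n <- mf$n
  estimates <- summarise_estimates(theta_hat, V, mf$par_tab)

  fitted_tbl <- tibble::tibble(.row = mf$df$.row,
                               .fitted_pop = det_$mu_pop,
                               .fitted = det_$mu_plot,
                               .sd = det_$sds) |>
    dplyr::arrange(.data$.row)

  ranef_tbl <- if (length(spec$random)) {
    tibble::as_tibble(det_$ranef, rownames = "plot_id") |>
      tidyr::pivot_longer(-"plot_id", names_to = "term",
                          values_to = "mode")
  } else {
    tibble::tibble(plot_id = character(), term = character(),
                   mode = numeric())
  }

  structure(list(spec = spec, mf = mf, theta = theta_hat, vcov = V,
                 estimates = estimates, logLik = -nll,
                 AIC = 2 * nll + 2 * k, BIC = 2 * nll + log(n) * k,
                 k = k, n = n, converged = converged, boundary = boundary,
                 grad_norm = best_g$norm, path = ev$path,
                 ranef = ranef_tbl, fitted = fitted_tbl,
                 data = dplyr::as_tibble(data), call = cl),
            class = "lfmc_fit")
}

num_gradient <- function(f, x, h = 1e-6 * (1 + abs(x))) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- replace(numeric(length(x)), i, h[i])
    g[i] <- (f(x + e) - f(x - e)) / (2 * h[i])
  }
  g
}

summarise_estimates <- function(theta, V, par_tab) {
  se_t <- sqrt(pmax(diag(V), 0))
  est_t <- theta
  lo_t <- est_t - 1.96 * se_t
  hi_t <- est_t + 1.96 * se_t
  est <- theta_to_natural(est_t, par_tab)
  lo <- theta_to_natural(lo_t, par_tab)
  hi <- theta_to_natural(hi_t, par_tab)
  # delta-method SE on the natural scale
  deriv <- rep(1, length(theta))
  deriv[par_tab$transform == "log"] <- est[par_tab$transform == "log"]
  deriv[par_tab$transform == "tanh"] <-
    1 - est[par_tab$transform == "tanh"]^2
  tibble::tibble(term = par_tab$name, type = par_tab$role,
                 estimate = unname(est),
                 std.error = unname(abs(deriv) * se_t),
                 conf.low = unname(pmin(lo, hi)),
                 conf.high = unname(pmax(lo, hi)))
}

# Self-start-based initial values for the full parameter vector, on the
# transformed scale.  `start` may override any term by name (natural scale).
make_start <- function(mf, spec, start = NULL) {
  d <- mf$df
  pars <- mean_parameters(spec$mean)
  nat <- setNames(numeric(nrow(mf$par_tab)), mf$par_tab$name)

  ss_for <- function(rows) {
    tv <- d$day[rows]
    yv <- d$lfmc[rows]
    out <- tryCatch(lfmc_self_start(t = tv, y = yv), error = function(e) NULL)
    if (is.null(out) || !all(is.finite(unlist(out)))) {
      rng <- range(yv)
      out <- tibble::tibble(A = rng[2], w = rng[1],
                            m = stats::median(tv),
                            s = -max(diff(range(tv)) / 5, 1))
    }
    out
  }

  if (spec$mean == "logistic") {
    lev <- mf$leaf_levels
    by_lev <- lapply(lev, function(l) ss_for(which(d$leaf_type == l)))
    names(by_lev) <- lev
    pooled <- ss_for(seq_len(nrow(d)))
    for (p in pars) {
      if (spec$fixed[[p]] == "leaf_type") {
        nat[p] <- by_lev[[1]][[p]]
        for (l in lev[-1]) {
          nat[paste0(p, "_", l)] <- by_lev[[l]][[p]] - by_lev[[1]][[p]]
        }
      } else {
        nat[p] <- pooled[[p]]
      }
    }
  } else if (spec$mean == "linear") {
    lev <- mf$leaf_levels
    for (p in pars) nat[p] <- 0
    cf_lev <- lapply(lev, function(l) {
      rows <- which(d$leaf_type == l)
      coef(lm(d$lfmc[rows] ~ d$day[rows]))
    })
    names(cf_lev) <- lev
    pooled_cf <- coef(lm(d$lfmc ~ d$day))
    map <- c(a = 1L, b = 2L)
    for (p in pars) {
      if (spec$fixed[[p]] == "leaf_type") {
        nat[p] <- cf_lev[[1]][[map[[p]]]]
        for (l in lev[-1]) {
          nat[paste0(p, "_", l)] <- cf_lev[[l]][[map[[p]]]] -
            cf_lev[[1]][[map[[p]]]]
        }
      } else {
        nat[p] <- pooled_cf[[map[[p]]]]
      }
    }
  } else {
    nat["c"] <- mean(d$lfmc)
  }
  # plot offsets start at zero (already zero)

  # residual scale from the start-curve residuals, per stratum
  phi0 <- list()
  for (p in pars) {
    phi0[[p]] <- drop(mf$X[[p]] %*% nat[colnames(mf$X[[p]])])
  }
  r0 <- d$lfmc - mean_fun(spec$mean, phi0, d$day)
  sd_ref <- max(sd(r0[d$leaf_type == mf$leaf_levels[1]]), 1e-2)
  if (!is.finite(sd_ref)) sd_ref <- max(sd(r0), 1e-2)
  nat["sigma"] <- sd_ref
  if (spec$variance == "varident") {
    for (l in mf$leaf_levels[-1]) {
      sl <- sd(r0[d$leaf_type == l])
      nat[paste0("delta_", l)] <-
        if (is.finite(sl) && sl > 0) max(sl / sd_ref, 0.05) else 1
    }
  }
  for (p in spec$random) nat[paste0("sd_", p)] <- max(0.5 * sd_ref, 0.1)
  if (!is.null(spec$correlation)) {
    if (spec$correlation$p > 0) nat["rho"] <- 0.2
    if (spec$correlation$q > 0) nat["theta"] <- 0.1
  }

  if (!is.null(start)) {
    common <- intersect(names(start), names(nat))
    nat[common] <- start[common]
  }
  natural_to_theta(nat, mf$par_tab)
}

# ---- methods --------------------------------------------------------------

#' @export
print.lfmc_fit <- function(x, ...) {
  cat("LFMC nonlinear mixed-effects fit (marginal ML, ", x$path,
      " path)\n", sep = "")
  cat(sprintf("  n = %d, parameters = %d, logLik = %.1f, AIC = %.1f\n",
              x$n, x$k, x$logLik, x$AIC))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (x$boundary) cat("  note: a variance component is at the boundary\n")
  print(x$estimates, n = Inf)
  invisible(x)
}

#' Tidy an LFMC fit
#'
#' @param x An `lfmc_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `term`, `type`
#'   (fixed / ranef_sd / sigma / delta / cor), `estimate`, `std.error`,
#'   `conf.low`, `conf.high` (95 percent Wald).
#' @method tidy lfmc_fit
#' @export
tidy.lfmc_fit <- function(x, ...) x$estimates

#' One-row summary of an LFMC fit
#'
#' @param x An `lfmc_fit` object.
#' @param ... Unused.
#' @return A tibble with `logLik`, `AIC`, `BIC`, `df` (parameter count),
#'   `nobs`, `converged`, `boundary`.
#' @method glance lfmc_fit
#' @export
glance.lfmc_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, AIC = x$AIC, BIC = x$BIC, df = x$k,
                 nobs = x$n, converged = x$converged, boundary = x$boundary)
}

#' Augment data with fitted values and residuals
#'
#' @param x An `lfmc_fit` object.
#' @param ... Unused.
#' @return The model data with `.fitted` (plot-level, conditional on the
#'   random-effect modes), `.fitted_pop` (population level), `.sd` (modelled
#'   residual SD), `.resid` (raw) and `.pearson` residual columns, in the
#'   original row order.
#' @method augment lfmc_fit
#' @export
augment.lfmc_fit <- function(x, ...) {
  d <- x$mf$df |>
    dplyr::arrange(.data$.row) |>
    dplyr::select("site", "plot", "point", "leaf_type", "day", "lfmc",
                  ".plot_id", "series", "date_rank")
  dplyr::bind_cols(d, x$fitted[, c(".fitted", ".fitted_pop", ".sd")]) |>
    dplyr::mutate(.resid = .data$lfmc - .data$.fitted,
                  .pearson = .data$.resid / .data$.sd)
}

#' @export
logLik.lfmc_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
vcov.lfmc_fit <- function(object, ...) object$vcov

#' Predict LFMC at new design points
#'
#' @param object An `lfmc_fit`.
#' @param newdata Tibble with `leaf_type` and `day`; `site` and `plot` are
#'   required for `level = "plot"` (and for models with fixed plot
#'   offsets).
#' @param level `"population"` (fixed effects only) or `"plot"` (adds the
#'   plot's conditional-mode random effects).
#' @param ... Unused.
#' @return Numeric vector of predicted LFMC (percent).
#' @export
predict.lfmc_fit <- function(object, newdata = NULL,
                             level = c("population", "plot"), ...) {
  level <- match.arg(level)
  phi <- resolve_parameters(object, newdata, level)
  mean_fun(object$spec$mean, phi$phi, phi$day)
}

resolve_parameters <- function(object, newdata, level) {
  spec <- object$spec
  mf <- object$mf
  if (is.null(newdata)) {
    newdata <- mf$df |> dplyr::arrange(.data$.row)
  }
  nd <- dplyr::as_tibble(newdata)
  if (!all(c("leaf_type", "day") %in% names(nd))) {
    abort("`newdata` needs `leaf_type` and `day` columns.",
          class = "fuelmoist_schema_error")
  }
  leaf <- as.character(nd$leaf_type)
  if (!all(leaf %in% mf$leaf_levels)) {
    abort("`newdata` contains leaf types absent from the fit.",
          class = "fuelmoist_labeling_error")
  }
  plot_id <- NULL
  if (level == "plot" || length(spec$plot_fixed)) {
    if (!all(c("site", "plot") %in% names(nd)) && level == "plot") {
      abort("Plot-level prediction needs `site` and `plot` columns.",
            class = "fuelmoist_schema_error")
    }
    if (all(c("site", "plot") %in% names(nd))) {
      plot_id <- paste(nd$site, nd$plot, sep = ":")
      if (level == "plot" && !all(plot_id %in% mf$plot_levels)) {
        abort("`newdata` contains plots absent from the fit.",
              class = "fuelmoist_labeling_error")
      }
    }
  }
  est <- setNames(object$estimates$estimate, object$estimates$term)
  phi <- list()
  for (p in mean_parameters(spec$mean)) {
    v <- rep(est[[p]], nrow(nd))
    if (spec$fixed[[p]] == "leaf_type") {
      for (l in mf$leaf_levels[-1]) {
        v <- v + est[[paste0(p, "_", l)]] * (leaf == l)
      }
    }
    if (p %in% spec$plot_fixed && !is.null(plot_id)) {
      for (pl in mf$plot_levels[-1]) {
        nmpl <- paste0(p, "_plot_", pl)
        v <- v + est[[nmpl]] * (plot_id == pl)
      }
    }
    phi[[p]] <- v
  }
  if (level == "plot" && length(spec$random)) {
    re <- object$ranef
    for (p in spec$random) {
      modes <- re$mode[re$term == p]
      names(modes) <- re$plot_id[re$term == p]
      phi[[p]] <- phi[[p]] + unname(modes[plot_id])
    }
  }
  list(phi = phi, day = nd$day)
}

#' Instantaneous drying speed from a fitted model
#'
#' Applies the analytic logistic derivative at the parameters resolved for
#' each row of `newdata` (population level, or plot level when plot columns
#' are given and `level = "plot"`).
#'
#' @inheritParams predict.lfmc_fit
#' @return Numeric vector of drying rates (LFMC percent per day; negative
#'   while drying).
#' @export
lfmc_drying_speed <- function(object, newdata = NULL,
                              level = c("population", "plot")) {
  stopifnot(inherits(object, "lfmc_fit"))
  if (object$spec$mean != "logistic") {
    abort("Drying speed is defined for the logistic mean only.",
          class = "fuelmoist_unsupported_operation")
  }
  level <- match.arg(level)
  ph <- resolve_parameters(object, newdata, level)
  (ph$phi$A - ph$phi$w) *
    {
      P <- 1 / (1 + exp((ph$phi$m - ph$day) / ph$phi$s))
      P * (1 - P)
    } / ph$phi$s
}
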