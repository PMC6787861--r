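# Marginal-likelihood machinery for the LFMC nonlinear mixed-effects model.
#
# Conditional on the plot-level random effects b_j, observations within a
# plot are Gaussian with mean from the (logistic / linear / constant) curve
# and covariance Sigma_j = D R D, where D holds the varIdent SDs and R is
# block-diagonal over within-plot series with stationary ARMA blocks.  Plots
# are independent, so the marginal likelihood is a product over plots of
# integrals over b_j.  When every random parameter enters the conditional
# mean linearly (A and w of the logistic; intercept and slope of the linear
# mean) the integral is an exact Gaussian one and is computed in closed form
# via the Woodbury identity; otherwise adaptive Gauss-Hermite quadrature
# (<= 2 random dimensions) or a Laplace approximation (3-4 dimensions) is
# used, centred and scaled at the conditional mode.

mean_fun <- function(mean, phi, t) {
  switch(mean,
         logistic = {
           E <- exp((phi$m - t) / phi$s)
           phi$w + (phi$A - phi$w) / (1 + E)
         },
         linear = phi$a + phi$b * t,
         constant = rep_len(phi$c, length(t)))
}

# derivative of the conditional mean wrt a linearly-entering parameter
lin_deriv <- function(mean, phi, t, p) {
  switch(mean,
         logistic = {
           P <- 1 / (1 + exp((phi$m - t) / phi$s))
           if (p == "A") P else 1 - P
         },
         linear = if (p == "a") rep(1, length(t)) else t,
         constant = rep(1, length(t)))
}

# analytic Jacobian of the conditional mean wrt any curve parameter
mean_deriv <- function(mean, phi, t, p) {
  if (mean != "logistic" || p %in% c("A", "w")) {
    return(lin_deriv(mean, phi, t, p))
  }
  P <- 1 / (1 + exp((phi$m - t) / phi$s))
  g <- (phi$A - phi$w) * P * (1 - P)
  if (p == "m") -g / phi$s else g * (phi$m - t) / phi$s^2
}

# ---- model frame ----------------------------------------------------------

prepare_model_frame <- function(data, spec) {
  d <- dplyr::as_tibble(data)
  needed <- c("site", "plot", "leaf_type", "day", "lfmc")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols)) {
    abort(paste0("Data is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fuelmoist_schema_error")
  }
  if (!"point" %in% names(d)) {
    d <- d |>
      dplyr::group_by(.data$site, .data$plot, .data$leaf_type, .data$day) |>
      dplyr::mutate(point = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  drop <- !is.finite(d$lfmc)
  if (any(drop)) d <- d[!drop, , drop = FALSE]
  if (!nrow(d)) {
    abort("No observations with a finite response.",
          class = "fuelmoist_empty_input")
  }
  d$leaf_type <- factor(as.character(d$leaf_type),
                        levels = lfmc_leaf_levels())
  if (anyNA(d$leaf_type)) {
    abort("Unknown leaf-type label(s); expected GW, GE, SM, SS.",
          class = "fuelmoist_labeling_error")
  }
  d$.row <- seq_len(nrow(d))
  d <- add_series(d)
  d <- dplyr::arrange(d, .data$.plot_id, .data$leaf_type, .data$series,
                      .data$date_rank)

  leaf_levels <- levels(droplevels(d$leaf_type))
  plot_levels <- sort(unique(d$.plot_id))
  if (length(spec$random) && length(plot_levels) < 2) {
    abort("Random plot effects need at least 2 plots.",
          class = "fuelmoist_degenerate_data")
  }

  par_tab <- build_parameterisation(spec, leaf_levels, plot_levels)

  # fixed-effect design matrix per mean parameter
  X <- list()
  for (p in mean_parameters(spec$mean)) {
    cols <- list(rep(1, nrow(d)))
    nm <- p
    if (spec$fixed[[p]] == "leaf_type") {
      for (l in leaf_levels[-1]) {
        cols <- c(cols, list(as.numeric(d$leaf_type == l)))
        nm <- c(nm, paste0(p, "_", l))
      }
    }
    if (p %in% spec$plot_fixed) {
      for (pl in plot_levels[-1]) {
        cols <- c(cols, list(as.numeric(d$.plot_id == pl)))
        nm <- c(nm, paste0(p, "_plot_", pl))
      }
    }
    X[[p]] <- matrix(unlist(cols), nrow = nrow(d),
                     dimnames = list(NULL, nm))
  }

  # per-observation variance stratum index (1 = reference level)
  strata_idx <- match(as.character(d$leaf_type), leaf_levels)

  plot_rows <- split(seq_len(nrow(d)), d$.plot_id)[plot_levels]

  # series patterns (positions = date ranks) for the ARMA blocks
  pattern_key <- tapply(d$date_rank, d$series, paste, collapse = ",")
  patterns <- lapply(strsplit(unique(unname(pattern_key)), ","), as.integer)
  names(patterns) <- unique(unname(pattern_key))
  series_of <- split(seq_len(nrow(d)), d$series)
  plot_series <- lapply(plot_rows, function(rows) {
    ids <- unique(d$series[rows])
    lapply(ids, function(sid) {
      list(local = match(series_of[[sid]], rows),
           pattern = unname(pattern_key[sid]))
    })
  })

  list(df = d, n = nrow(d), y = d$lfmc, t = d$day,
       leaf_levels = leaf_levels, plot_levels = plot_levels,
       par_tab = par_tab, X = X, strata_idx = strata_idx,
       plot_rows = plot_rows, patterns = patterns,
       plot_series = plot_series)
}

build_parameterisation <- function(spec, leaf_levels, plot_levels) {
  rows <- list()
  add <- function(name, role, transform) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name, role = role, transform = transform)
  }
  for (p in mean_parameters(spec$mean)) {
    add(p, "fixed", "id")
    if (spec$fixed[[p]] == "leaf_type") {
      for (l in leaf_levels[-1]) add(paste0(p, "_", l), "fixed", "id")
    }
    if (p %in% spec$plot_fixed) {
      for (pl in plot_levels[-1]) {
        add(paste0(p, "_plot_", pl), "fixed", "id")
      }
    }
  }
  for (p in spec$random) add(paste0("sd_", p), "ranef_sd", "log")
  add("sigma", "sigma", "log")
  if (spec$variance == "varident") {
    for (l in leaf_levels[-1]) add(paste0("delta_", l), "delta", "log")
  }
  if (!is.null(spec$correlation)) {
    if (spec$correlation$p > 0) add("rho", "cor", "tanh")
    if (spec$correlation$q > 0) add("theta", "cor", "tanh")
  }
  dplyr::bind_rows(rows)
}

theta_to_natural <- function(theta, par_tab) {
  out <- theta
  lg <- par_tab$transform == "log"
  th <- par_tab$transform == "tanh"
  out[lg] <- exp(theta[lg])
  out[th] <- tanh(theta[th])
  out
}

natural_to_theta <- function(nat, par_tab) {
  out <- nat
  lg <- par_tab$transform == "log"
  th <- par_tab$transform == "tanh"
  out[lg] <- log(nat[lg])
  out[th] <- atanh(nat[th])
  out
}

# ---- objective ------------------------------------------------------------

gh_grid <- function(nodes, d) {
  gh <- pracma::gaussHermite(nodes)
  if (d == 1) {
    list(Z = matrix(gh$x, ncol = 1), logw = log(gh$w) + gh$x^2)
  } else {
    g <- expand.grid(i = seq_len(nodes), j = seq_len(nodes))
    list(Z = cbind(gh$x[g$i], gh$x[g$j]),
         logw = log(gh$w[g$i]) + log(gh$w[g$j]) + gh$x[g$i]^2 + gh$x[g$j]^2)
  }
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

safe_chol <- function(H) {
  out <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(out)) {
    ridge <- abs(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values))
    out <- chol(H + diag(ridge + 1e-6, nrow(H)))
  }
  out
}

# Build the evaluator.  Returns nll(theta) and detail(theta).
make_evaluator <- function(mf, spec, method = "auto", nodes = 7L) {
  pars <- mean_parameters(spec$mean)
  random <- spec$random
  d_re <- length(random)
  linear_ok <- all(random %in% linear_parameters(spec$mean))
  method <- match.arg(method, c("auto", "exact", "agq", "laplace"))
  if (method == "exact" && !linear_ok) {
    abort("Exact marginalisation needs random effects on linear parameters.",
          class = "fuelmoist_invalid_spec")
  }
  path <- if (d_re == 0) "none"
  else if (method == "auto") {
    if (linear_ok) "exact" else if (d_re <= 2) "agq" else "laplace"
  } else method
  grid <- if (path == "agq" && d_re >= 1) gh_grid(nodes, d_re)
  use_arma <- !is.null(spec$correlation)
  n_plots <- length(mf$plot_rows)
  log2pi <- log(2 * pi)

  beta_idx <- lapply(pars, function(p) {
    match(colnames(mf$X[[p]]), mf$par_tab$name)
  })
  names(beta_idx) <- pars
  sd_idx <- match(paste0("sd_", random), mf$par_tab$name)
  sigma_idx <- match("sigma", mf$par_tab$name)
  delta_idx <- match(paste0("delta_", mf$leaf_levels[-1]), mf$par_tab$name)
  rho_idx <- match("rho", mf$par_tab$name)
  theta_idx <- match("theta", mf$par_tab$name)

  evaluate <- function(theta, want_detail = FALSE) {
    nat <- theta_to_natural(theta, mf$par_tab)
    phi <- list()
    for (p in pars) phi[[p]] <- drop(mf$X[[p]] %*% nat[beta_idx[[p]]])
    sigma <- nat[sigma_idx]
    ratio <- rep(1, length(mf$leaf_levels))
    if (spec$variance == "varident") ratio[-1] <- nat[delta_idx]
    sds <- sigma * ratio[mf$strata_idx]
    psd <- nat[sd_idx]

    chols <- NULL
    if (use_arma) {
      rho <- if (!is.na(rho_idx)) nat[rho_idx] else numeric()
      tht <- if (!is.na(theta_idx)) nat[theta_idx] else numeric()
      cs <- tryCatch(corr_arma(length(rho), length(tht), rho, tht),
                     error = function(e) NULL)
      if (is.null(cs)) return(list(nll = 1e12))
      chols <- lapply(mf$patterns, function(pos) {
        R <- arma_correlation(cs, length(pos), positions = pos)
        ch <- tryCatch(chol(R), error = function(e) NULL)
        if (is.null(ch)) return(NULL)
        ch
      })
      if (any(vapply(chols, is.null, logical(1)))) return(list(nll = 1e12))
    }

    total <- 0
    detail <- if (want_detail) {
      list(mu_pop = numeric(mf$n), mu_plot = numeric(mf$n),
           ranef = matrix(0, n_plots, d_re,
                          dimnames = list(names(mf$plot_rows), random)))
    }

    for (jj in seq_len(n_plots)) {
      rows <- mf$plot_rows[[jj]]
      nj <- length(rows)
      yj <- mf$y[rows]
      tj <- mf$t[rows]
      sdj <- sds[rows]
      phij <- lapply(phi, function(v) v[rows])
      sl <- mf$plot_series[[jj]]

      # whitening: x -> L^{-1} (x / sd) seriswise; logdet of Sigma_j
      whiten <- function(x) {
        x <- as.matrix(x)
        xs <- x / sdj
        if (!use_arma) return(xs)
        for (srs in sl) {
          L <- chols[[srs$pattern]]
          xs[srs$local, ] <- backsolve(L, xs[srs$local, , drop = FALSE],
                                       transpose = TRUE)
        }
        xs
      }
      logdet_sigma <- 2 * sum(log(sdj)) +
        if (use_arma) {
          2 * sum(vapply(sl, function(srs)
            sum(log(diag(chols[[srs$pattern]]))), numeric(1)))
        } else 0

      if (path %in% c("none", "exact")) {
        mu0 <- mean_fun(spec$mean, phij, tj)
        r <- yj - mu0
        if (d_re == 0) {
          wr <- whiten(r)
          nll_j <- 0.5 * (sum(wr^2) + logdet_sigma + nj * log2pi)
          bhat <- numeric(0)
          mu_plot <- mu0
        } else {
          C <- vapply(random, function(p) lin_deriv(spec$mean, phij, tj, p),
                      numeric(nj))
          C <- matrix(C, nrow = nj)
          wA <- whiten(cbind(r, C))
          wr <- wA[, 1]
          wC <- wA[, -1, drop = FALSE]
          u <- drop(crossprod(wC, wr))
          W <- crossprod(wC)
          M <- W + diag(1 / psd^2, d_re)
          cM <- safe_chol(M)
          v <- backsolve(cM, backsolve(cM, u, transpose = TRUE))
          nll_j <- 0.5 * (sum(wr^2) - sum(u * v) + logdet_sigma +
                            2 * sum(log(psd)) + 2 * sum(log(diag(cM))) +
                            nj * log2pi)
          bhat <- v
          mu_plot <- mu0 + drop(C %*% bhat)
        }
      } else {
        const_b <- 0.5 * (logdet_sigma + nj * log2pi) +
          0.5 * sum(log(2 * pi * psd^2))
        gneg <- function(b) {
          phib <- phij
          for (k in seq_len(d_re)) {
            phib[[random[k]]] <- phib[[random[k]]] + b[k]
          }
          r <- yj - mean_fun(spec$mean, phib, tj)
          wr <- whiten(r)
          0.5 * sum(wr^2) + 0.5 * sum((b / psd)^2) + const_b
        }
        # value, analytic gradient and Gauss-Newton curvature in one pass
        gparts <- function(b) {
          phib <- phij
          for (k in seq_len(d_re)) {
            phib[[random[k]]] <- phib[[random[k]]] + b[k]
          }
          r <- yj - mean_fun(spec$mean, phib, tj)
          J <- vapply(random, function(p)
            mean_deriv(spec$mean, phib, tj, p), numeric(nj))
          wall <- whiten(cbind(r, matrix(J, nrow = nj)))
          wr <- wall[, 1]
          wJ <- wall[, -1, drop = FALSE]
          list(value = 0.5 * sum(wr^2) + 0.5 * sum((b / psd)^2) + const_b,
               grad = -drop(crossprod(wJ, wr)) + b / psd^2,
               H = crossprod(wJ) + diag(1 / psd^2, d_re))
        }
        # Newton search for the conditional mode (backtracking line search)
        bhat <- numeric(d_re)
        gp <- gparts(bhat)
        for (it in 1:50) {
          step <- tryCatch(solve(gp$H, gp$grad), error = function(e) gp$grad)
          lam <- 1
          repeat {
            bnew <- bhat - lam * step
            gp_new <- gparts(bnew)
            if (is.finite(gp_new$value) && gp_new$value <= gp$value + 1e-12) {
              break
            }
            lam <- lam / 2
            if (lam < 1e-8) {
              bnew <- bhat
              gp_new <- gp
              break
            }
          }
          moved <- sum(abs(bnew - bhat))
          bhat <- bnew
          gp <- gp_new
          if (max(abs(gp$grad)) < 1e-9 || moved < 1e-11) break
        }
        H <- gp$H
        U <- safe_chol(H)
        if (path == "agq") {
          Ainv <- backsolve(U, diag(d_re))
          # all nodes at once: B is K x d, curve parameters become
          # n_j x K matrices and the mean/whitening operate columnwise
          B <- sweep(grid$Z %*% t(Ainv) * sqrt(2), 2, bhat, "+")
          K <- nrow(B)
          phib <- phij
          for (k in seq_len(d_re)) {
            phib[[random[k]]] <- outer(phij[[random[k]]], B[, k], "+")
          }
          MU <- mean_fun(spec$mean, phib, tj)
          WR <- whiten(yj - MU)
          gvals <- 0.5 * colSums(WR^2) +
            0.5 * colSums((t(B) / psd)^2) + const_b
          vals <- grid$logw - gvals
          logLj <- (d_re / 2) * log(2) - sum(log(diag(U))) + logsumexp(vals)
        } else {
          logLj <- -gp$value + (d_re / 2) * log2pi - sum(log(diag(U)))
        }
        nll_j <- -logLj
        phib <- phij
        for (k in seq_len(d_re)) {
          phib[[random[k]]] <- phib[[random[k]]] + bhat[k]
        }
        mu_plot <- mean_fun(spec$mean, phib, tj)
        mu0 <- mean_fun(spec$mean, phij, tj)
      }

      if (!is.finite(nll_j)) return(list(nll = 1e12))
      total <- total + nll_j
      if (want_detail) {
        detail$mu_pop[rows] <- mu0
        detail$mu_plot[rows] <- mu_plot
        if (d_re > 0) detail$ranef[jj, ] <- bhat
      }
    }
    if (want_detail) {
      list(nll = total, mu_pop = detail$mu_pop, mu_plot = detail$mu_plot,
           ranef = detail$ranef, sds = sds, path = path)
    } else {
      list(nll = total)
    }
  }

  list(nll = function(theta) evaluate(theta)$nll,
       detail = function(theta) evaluate(theta, want_detail = TRUE),
       path = path)
}

#' Marginal negative log-likelihood of an LFMC model
#'
#' Evaluates minus the log marginal likelihood (plot random effects
#' integrated out) at user-supplied parameter values, without fitting.
#' Useful for likelihood-surface checks and for comparing the exact
#' linear-random-effect marginalisation with the quadrature path.
#'
#' @param data Observation table (`site`, `plot`, `point`, `leaf_type`,
#'   `day`, `lfmc`).
#' @param spec An [lfmc_model()] specification.
#' @param params Named numeric vector of parameter values on their natural
#'   scale, using the fitted-model term names (e.g. `A`, `A_GE`, `sd_A`,
#'   `sigma`, `delta_SM`, `rho`).
#' @param method Integration method: `"auto"`, `"exact"` (closed-form
#'   Gaussian integral; random effects must be on linearly-entering
#'   parameters), `"agq"` (adaptive Gauss--Hermite) or `"laplace"`.
#' @param nodes Quadrature nodes per random-effect dimension.
#' @return The negative log-likelihood (scalar).
#' @export
lfmc_negloglik <- function(data, spec, params,
                           method = c("auto", "exact", "agq", "laplace"),
                           nodes = 7L) {
  method <- match.arg(method)
  mf <- prepare_model_frame(data, spec)
  miss <- setdiff(mf$par_tab$name, names(params))
  if (length(miss)) {
    abort(paste0("`params` is missing: ", paste(miss, collapse = ", ")),
          class = "fuelmoist_invalid_parameter")
  }
  theta <- natural_to_theta(params[mf$par_tab$name], mf$par_tab)
  ev <- make_evaluator(mf, spec, method = method, nodes = nodes)
  ev$nll(theta)
}
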