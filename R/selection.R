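# Stepwise AIC protocol and alternative-model suite.

fit_candidate <- function(data, spec, label, step, log_env, seed = 1L, ...) {
  fit <- tryCatch(fit_lfmc(data, spec, seed = seed, ...),
                  error = function(e) {
                    warn(paste0("Candidate '", label, "' failed: ",
                                conditionMessage(e)))
                    NULL
                  })
  row <- tibble::tibble(
    step = step, model = label,
    k = if (is.null(fit)) NA_integer_ else fit$k,
    logLik = if (is.null(fit)) NA_real_ else fit$logLik,
    AIC = if (is.null(fit)) NA_real_ else fit$AIC,
    converged = if (is.null(fit)) FALSE else fit$converged)
  log_env$log <- dplyr::bind_rows(log_env$log, row)
  fit
}

#' Stepwise model selection for the LFMC drying model
#'
#' Applies the standard mixed-model building protocol with an AIC gate:
#' starting from the full leaf-type fixed-effects map, (1) the random
#' structure is chosen by forward addition of plot random effects (starting
#' from a random `A`, the most identifiable parameter) followed by pruning;
#' (2) the per-leaf-type variance function (varIdent) and then an ARMA
#' serial-correlation structure (orders (1,0), (0,1), (1,1), best first)
#' are offered; (3) each mean parameter's leaf-type map is tested against a
#' common coefficient.  At every comparison the richer model is kept only if
#' its AIC is lower by more than `gate` (default 2); ties favour the
#' simpler model.  Every comparison is recorded in the decision log.
#'
#' @param data Observation table (see [fit_lfmc()]).
#' @param gate AIC improvement required to keep the richer model.
#' @param seed Seed passed to the component fits (restart jitter).
#' @param verbose Print each decision as it is made.
#' @return An object of class `lfmc_selection`: a list with the selected
#'   `spec`, the final `fit`, and the decision `log` tibble.
#' @examples
#' \donttest{
#' d <- simulate_lfmc(lfmc_design(), lfmc_truth(), seed = 7)
#' sel <- select_lfmc_model(d)
#' sel$spec
#' }
#' @export
select_lfmc_model <- function(data, gate = 2, seed = 1L, verbose = FALSE) {
  env <- new.env()
  env$log <- tibble::tibble()
  say <- function(...) if (verbose) cat(sprintf(...), "\n")
  decisions <- list()
  note <- function(step, comparison, kept) {
    decisions[[length(decisions) + 1L]] <<-
      tibble::tibble(step = step, comparison = comparison, kept = kept)
    say("[%s] %s -> keep %s", step, comparison, kept)
  }
  full_fixed <- c(A = "leaf_type", w = "leaf_type",
                  m = "leaf_type", s = "leaf_type")
  mk <- function(random, variance = "constant", correlation = NULL,
                 fixed = full_fixed) {
    lfmc_model(mean = "logistic", fixed = fixed, random = random,
               variance = variance, correlation = correlation)
  }
  lab_re <- function(r) if (length(r)) paste0("random{", paste(r, collapse = ","), "}") else "random{}"
  warm <- function(fit) setNames(fit$estimates$estimate, fit$estimates$term)

  # -- step 1: random structure (full fixed map, simple residuals) ----------
  cur_random <- "A"
  search_ctrl <- list(rel.tol = 1e-9)
  cur <- fit_candidate(data, mk(cur_random), lab_re(cur_random),
                       "1-random", env, seed, control = search_ctrl)
  if (is.null(cur)) {
    abort("The base model (random A) failed to fit.",
          class = "fuelmoist_convergence_error")
  }
  repeat {
    cands <- setdiff(c("A", "w", "m", "s"), cur_random)
    if (!length(cands)) break
    fits <- lapply(cands, function(p) {
      fit_candidate(data, mk(c(cur_random, p)), lab_re(c(cur_random, p)),
                    "1-random", env, seed, start = warm(cur),
                    self_attempt = p %in% c("A", "w"),
                    control = search_ctrl)
    })
    aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$AIC,
                   numeric(1))
    if (min(aics) < cur$AIC - gate) {
      i <- which.min(aics)
      note("1-random", paste0("add random ", cands[i]), "richer")
      cur_random <- c(cur_random, cands[i])
      cur <- fits[[i]]
    } else {
      if (length(cands)) {
        note("1-random", paste0("add random {",
                                paste(cands, collapse = ","), "}"), "simpler")
      }
      break
    }
  }
  repeat {
    dropped <- FALSE
    for (p in cur_random) {
      reduced <- setdiff(cur_random, p)
      f0 <- fit_candidate(data, mk(reduced), lab_re(reduced),
                          "1-random-prune", env, seed, start = warm(cur),
                          control = search_ctrl)
      if (is.null(f0)) next
      if (!(cur$AIC < f0$AIC - gate)) {
        note("1-random-prune", paste0("drop random ", p), "simpler")
        cur_random <- reduced
        cur <- f0
        dropped <- TRUE
        break
      } else {
        note("1-random-prune", paste0("drop random ", p), "richer")
      }
    }
    if (!dropped) break
  }

  # -- step 2: variance and correlation structures --------------------------
  cur_var <- "constant"
  f_vi <- fit_candidate(data, mk(cur_random, "varident"),
                        "varIdent", "2-variance", env, seed,
                        start = warm(cur), control = search_ctrl)
  if (!is.null(f_vi) && f_vi$AIC < cur$AIC - gate) {
    note("2-variance", "varIdent vs homoscedastic", "richer")
    cur_var <- "varident"
    cur <- f_vi
  } else {
    note("2-variance", "varIdent vs homoscedastic", "simpler")
  }
  orders <- list(c(p = 1, q = 0), c(p = 0, q = 1), c(p = 1, q = 1))
  arma_fits <- lapply(orders, function(o) {
    fit_candidate(data, mk(cur_random, cur_var, o),
                  sprintf("ARMA(%d,%d)", o[["p"]], o[["q"]]),
                  "2-correlation", env, seed, start = warm(cur),
                  control = search_ctrl)
  })
  aics <- vapply(arma_fits, function(f) if (is.null(f)) Inf else f$AIC,
                 numeric(1))
  cur_cor <- NULL
  if (min(aics) < cur$AIC - gate) {
    i <- which.min(aics)
    note("2-correlation", "best ARMA vs independence", "richer")
    cur_cor <- orders[[i]]
    cur <- arma_fits[[i]]
  } else {
    note("2-correlation", "best ARMA vs independence", "simpler")
  }

  # -- step 3: fixed effects ------------------------------------------------
  cur_fixed <- full_fixed
  for (p in c("A", "w", "m", "s")) {
    cand_fixed <- cur_fixed
    cand_fixed[p] <- "common"
    # collapsing a leaf-type map: start the common coefficient at the mean
    # of the fitted level values
    st <- warm(cur)
    offs <- st[grep(paste0("^", p, "_(GE|SM|SS)$"), names(st))]
    st[p] <- st[[p]] + mean(c(0, offs))
    f0 <- fit_candidate(data, mk(cur_random, cur_var, cur_cor, cand_fixed),
                        paste0("common ", p), "3-fixed", env, seed,
                        start = st, control = search_ctrl)
    if (is.null(f0)) next
    if (!(cur$AIC < f0$AIC - gate)) {
      note("3-fixed", paste0("leaf type on ", p), "simpler")
      cur_fixed <- cand_fixed
      cur <- f0
    } else {
      note("3-fixed", paste0("leaf type on ", p), "richer")
    }
  }

  spec <- mk(cur_random, cur_var, cur_cor, cur_fixed)
  final <- tryCatch(fit_lfmc(data, spec, start = warm(cur), seed = seed),
                    error = function(e) cur)
  if (final$AIC > cur$AIC + 1e-6) final <- cur
  structure(list(spec = spec, fit = final,
                 log = env$log,
                 decisions = dplyr::bind_rows(decisions)),
            class = "lfmc_selection")
}

#' @export
print.lfmc_selection <- function(x, ...) {
  cat("LFMC stepwise selection (AIC gate)\n\nSelected structure:\n")
  print(x$spec)
  cat(sprintf("\nFinal fit: k = %d, logLik = %.1f, AIC = %.1f\n",
              x$fit$k, x$fit$logLik, x$fit$AIC))
  cat("\nDecisions:\n")
  print(x$decisions, n = Inf)
  invisible(x)
}

#' Fit the suite of alternative models (M1--M5)
#'
#' Fits and ranks by AIC the five model families used to benchmark the
#' nonlinear mixed-effects drying model: M1, the selected nonlinear
#' mixed-effects model; M2, a nonlinear fixed-effects model (leaf-type
#' logistic coefficients plus fixed plot offsets on both asymptotes,
#' homoscedastic iid errors); M3, a linear mixed-effects model (day by
#' leaf-type mean, plot random intercept, varIdent and ARMA(1,1)
#' residuals); M4, classical linear regression (day by leaf type plus fixed
#' plot offsets, iid errors); and M5, the null model (grand mean and a
#' single variance).
#'
#' @param data Observation table.
#' @param m1 Optional: a pre-computed `lfmc_selection` or `lfmc_fit` to use
#'   as M1; by default the stepwise protocol is run.
#' @param simplify Apply the AIC gate to each alternative's leaf-type map
#'   (and search the ARMA order for M3) before comparison.
#' @param gate AIC gate used when `simplify = TRUE` (and inside the M1
#'   selection).
#' @param seed Seed passed to component fits.
#' @return An object of class `lfmc_comparison`: a ranking tibble with
#'   columns `model`, `description`, `k`, `logLik`, `AIC`, `dAIC` (best
#'   model first, dAIC 0), with the fitted objects in `attr(, "fits")`.
#' @export
fit_alternatives <- function(data, m1 = NULL, simplify = FALSE, gate = 2,
                             seed = 1L) {
  if (is.null(m1)) m1 <- select_lfmc_model(data, gate = gate, seed = seed)
  fit1 <- if (inherits(m1, "lfmc_selection")) m1$fit else m1
  stopifnot(inherits(fit1, "lfmc_fit"))

  spec2 <- lfmc_model(mean = "logistic",
                      fixed = c(A = "leaf_type", w = "leaf_type",
                                m = "leaf_type", s = "leaf_type"),
                      plot_fixed = c("A", "w"),
                      variance = "constant")
  spec3 <- lfmc_model(mean = "linear",
                      fixed = c(a = "leaf_type", b = "leaf_type"),
                      random = "a", variance = "varident",
                      correlation = c(p = 1, q = 1))
  spec4 <- lfmc_model(mean = "linear",
                      fixed = c(a = "leaf_type", b = "leaf_type"),
                      plot_fixed = c("a", "b"),
                      variance = "constant")
  spec5 <- lfmc_model(mean = "constant", variance = "constant")

  if (simplify) {
    spec2 <- simplify_fixed(data, spec2, gate, seed)
    spec3 <- pick_arma(data, simplify_fixed(data, spec3, gate, seed),
                       gate, seed)
    spec4 <- simplify_fixed(data, spec4, gate, seed)
  }

  fits <- list(
    M1 = fit1,
    M2 = fit_lfmc(data, spec2, seed = seed),
    M3 = fit_lfmc(data, spec3, seed = seed),
    M4 = fit_lfmc(data, spec4, seed = seed),
    M5 = fit_lfmc(data, spec5, seed = seed))
  desc <- c(M1 = "nonlinear mixed-effects",
            M2 = "nonlinear fixed-effects",
            M3 = "linear mixed-effects",
            M4 = "classical regression",
            M5 = "null")
  tab <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(model = nm, description = desc[[nm]], k = f$k,
                   logLik = f$logLik, AIC = f$AIC)
  }) |>
    dplyr::arrange(.data$AIC) |>
    dplyr::mutate(dAIC = .data$AIC - min(.data$AIC))
  attr(tab, "fits") <- fits
  class(tab) <- c("lfmc_comparison", class(tab))
  tab
}

# AIC-gated leaf-type map reduction for an alternative family
simplify_fixed <- function(data, spec, gate, seed) {
  cur <- fit_lfmc(data, spec, seed = seed)
  for (p in names(spec$fixed)) {
    if (spec$fixed[[p]] != "leaf_type") next
    cand <- spec
    cand$fixed[p] <- "common"
    f0 <- tryCatch(fit_lfmc(data, cand, seed = seed),
                   error = function(e) NULL)
    if (!is.null(f0) && !(cur$AIC < f0$AIC - gate)) {
      spec <- cand
      cur <- f0
    }
  }
  spec
}

pick_arma <- function(data, spec, gate, seed) {
  base <- spec
  base$correlation <- NULL
  f_base <- fit_lfmc(data, base, seed = seed)
  orders <- list(c(p = 1, q = 0), c(p = 0, q = 1), c(p = 1, q = 1))
  fits <- lapply(orders, function(o) {
    cand <- spec
    cand$correlation <- as.list(o)
    tryCatch(fit_lfmc(data, cand, seed = seed), error = function(e) NULL)
  })
  aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$AIC,
                 numeric(1))
  if (min(aics) < f_base$AIC - gate) {
    spec$correlation <- as.list(orders[[which.min(aics)]])
    spec
  } else {
    base
  }
}

#' Pairwise leaf-type contrasts for a curve parameter
#'
#' Wald contrasts between all pairs of leaf-type levels for a parameter
#' fitted with a leaf-type map (typically the asymptotes `A` or `w`), with
#' delta-method standard errors from the estimate covariance and optional
#' single-step (Tukey-style, studentised-range) multiplicity adjustment.
#'
#' @param fit An `lfmc_fit`.
#' @param parameter Mean parameter name (e.g. `"A"` or `"w"`).
#' @param adjust `"none"` (unadjusted Wald, the default) or `"tukey"`.
#' @return A tibble with one row per ordered pair: `parameter`, `contrast`
#'   (e.g. `"GE - GW"`), `estimate`, `std.error`, `statistic`, `p.value`,
#'   `conf.low`, `conf.high`.
#' @export
leaf_type_contrasts <- function(fit, parameter = "A",
                                adjust = c("none", "tukey")) {
  stopifnot(inherits(fit, "lfmc_fit"))
  adjust <- match.arg(adjust)
  spec <- fit$spec
  if (!parameter %in% names(spec$fixed) ||
      spec$fixed[[parameter]] != "leaf_type") {
    abort(paste0("Parameter '", parameter,
                 "' was not fitted with a leaf-type map."),
          class = "fuelmoist_unsupported_contrast")
  }
  lev <- fit$mf$leaf_levels
  terms <- fit$mf$par_tab$name
  V <- fit$vcov
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  # level value = reference coefficient + offset (offset absent for ref)
  lvec <- function(l) {
    v <- setNames(numeric(length(terms)), terms)
    v[parameter] <- 1
    if (l != lev[1]) v[paste0(parameter, "_", l)] <- 1
    v
  }
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  nlev <- length(lev)
  crit <- if (adjust == "tukey") qtukey(0.95, nlev, Inf) / sqrt(2) else 1.96
  purrr::map_dfr(pairs, function(pr) {
    cc <- lvec(pr[2]) - lvec(pr[1])
    delta <- sum(cc * est[terms])
    se <- sqrt(drop(t(cc) %*% V %*% cc))
    z <- delta / se
    p <- if (adjust == "tukey") {
      stats::ptukey(sqrt(2) * abs(z), nlev, Inf, lower.tail = FALSE)
    } else {
      2 * pnorm(-abs(z))
    }
    tibble::tibble(parameter = parameter,
                   contrast = paste(pr[2], "-", pr[1]),
                   estimate = delta, std.error = se, statistic = z,
                   p.value = p,
                   conf.low = delta - crit * se,
                   conf.high = delta + crit * se)
  })
}
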