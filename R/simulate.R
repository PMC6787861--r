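#' Design skeleton for the two-site LFMC field study
#'
#' Builds the observation skeleton of the field design: two sites along an
#' aridity gradient, three plots per site, seven sampling dates across the
#' fire season, and three sampled points per plot, date and leaf type.  Only
#' grasses (GW) occur at the wetter western site; grasses (GE) and the two
#' shrubs (SM, SS) at the eastern site.  The default design has
#' 3 types x 3 points x 3 plots x 7 dates = 189 cells at E plus
#' 1 x 3 x 3 x 7 = 63 at W, i.e. 252 cells.
#'
#' @param sites Character vector of site labels.
#' @param plots_per_site Number of plots per site.
#' @param dates Numeric vector of sampling days (days since the first
#'   measurement).  Default: seven days spread evenly over 0--89.
#' @param points Points per plot x date x leaf type.
#' @param leaf_types Named list mapping site to its leaf types.
#' @return A tibble with columns `site`, `plot`, `point`, `leaf_type`,
#'   `day` and no response.
#' @examples
#' nrow(lfmc_design())  # 252
#' @export
lfmc_design <- function(sites = c("W", "E"),
                        plots_per_site = 3,
                        dates = round(seq(0, 89, length.out = 7)),
                        points = 3,
                        leaf_types = list(W = "GW", E = c("GE", "SM", "SS"))) {
  rows <- purrr::map_dfr(sites, function(st) {
    types <- leaf_types[[st]]
    if (is.null(types)) {
      abort(paste0("No leaf types declared for site ", st),
            class = "fuelmoist_invalid_spec")
    }
    tidyr::expand_grid(site = st,
                       plot = seq_len(plots_per_site),
                       leaf_type = types,
                       day = as.numeric(dates),
                       point = seq_len(points))
  })
  rows |>
    dplyr::mutate(leaf_type = factor(.data$leaf_type,
                                     levels = lfmc_leaf_levels())) |>
    dplyr::select("site", "plot", "point", "leaf_type", "day")
}

lfmc_leaf_levels <- function() c("GW", "GE", "SM", "SS")

#' Generating parameters for synthetic LFMC data
#'
#' Truth values for the synthetic generator, defaulting to the fitted
#' parsimonious drying model: leaf-type-specific asymptotes (GW A = 54.3,
#' w = 29.1; offsets +30.9/-20.7 for GE, +223.4/+31.7 for SM, +240.3/+26.7
#' for SS), a common inflection time m = 30.9 days and steepness s = -16.1
#' days, a plot-level SD of 9.4 on A, reference residual SD 7.1 with
#' variance ratios 0.9 (GE), 3.2 (SM) and 3.0 (SS), and no serial
#' correlation.
#'
#' @param A,w Named numeric vectors of asymptotes per leaf type (percent).
#' @param m,s Inflection time and steepness; scalars (common to all types)
#'   or named per-type vectors.
#' @param sd_A,sd_w,sd_m,sd_s Plot-level random-effect SDs.
#' @param sigma_base Reference residual SD (GW).
#' @param delta Named variance ratios for the non-reference leaf types.
#' @param rho,theta Optional ARMA(1,1) coefficients for serially correlated
#'   residual noise (`NULL` for independence).
#' @return A list of class `lfmc_truth`.
#' @export
lfmc_truth <- function(A = c(GW = 54.3, GE = 54.3 + 30.9,
                             SM = 54.3 + 223.4, SS = 54.3 + 240.3),
                       w = c(GW = 29.1, GE = 29.1 - 20.7,
                             SM = 29.1 + 31.7, SS = 29.1 + 26.7),
                       m = 30.9, s = -16.1,
                       sd_A = 9.4, sd_w = 0, sd_m = 0, sd_s = 0,
                       sigma_base = 7.1,
                       delta = c(GE = 0.9, SM = 3.2, SS = 3.0),
                       rho = NULL, theta = NULL) {
  sds <- c(sd_A = sd_A, sd_w = sd_w, sd_m = sd_m, sd_s = sd_s)
  if (any(sds < 0) || sigma_base <= 0 || any(delta <= 0)) {
    abort("SDs must be non-negative and variance parameters positive.",
          class = "fuelmoist_invalid_parameter")
  }
  structure(list(A = A, w = w, m = m, s = s,
                 sd_A = sd_A, sd_w = sd_w, sd_m = sd_m, sd_s = sd_s,
                 sigma_base = sigma_base, delta = delta,
                 rho = rho, theta = theta),
            class = "lfmc_truth")
}

truth_param <- function(x, leaf) {
  if (length(x) == 1L && is.null(names(x))) rep(x, length(leaf))
  else unname(x[as.character(leaf)])
}

#' Simulate an LFMC dataset from the drying model
#'
#' Draws a dataset from the generative structure of the nonlinear
#' mixed-effects drying model: plot-level random deviations on the curve
#' parameters, logistic mean curves per leaf type, heteroscedastic
#' (varIdent) Gaussian noise, optional ARMA serial correlation along each
#' within-plot series, and random loss of a few observations.
#'
#' @param design A design skeleton from [lfmc_design()] (or any tibble with
#'   `site`, `plot`, `point`, `leaf_type`, `day`).
#' @param truth Generating parameters from [lfmc_truth()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param n_lost Number of observations dropped uniformly at random
#'   (default 5, emulating field losses: 252 cells -> 247 observations).
#' @return A tibble like `design` with an added `lfmc` column.
#' @examples
#' d <- simulate_lfmc(lfmc_design(), lfmc_truth(), seed = 1)
#' nrow(d)  # 247
#' @export
simulate_lfmc <- function(design, truth = lfmc_truth(), seed = NULL,
                          n_lost = 5) {
  stopifnot(inherits(truth, "lfmc_truth"))
  if (!is.null(seed)) set.seed(seed)
  d <- dplyr::as_tibble(design)
  d$plot_id <- paste(d$site, d$plot, sep = ":")
  plots <- unique(d$plot_id)
  re <- list()
  for (p in c("A", "w", "m", "s")) {
    sdp <- truth[[paste0("sd_", p)]]
    re[[p]] <- setNames(if (sdp > 0) rnorm(length(plots), 0, sdp)
                        else rep(0, length(plots)), plots)
  }
  A <- truth_param(truth$A, d$leaf_type) + re$A[d$plot_id]
  w <- truth_param(truth$w, d$leaf_type) + re$w[d$plot_id]
  m <- truth_param(truth$m, d$leaf_type) + re$m[d$plot_id]
  s <- truth_param(truth$s, d$leaf_type) + re$s[d$plot_id]
  mu <- w + (A - w) / (1 + exp((m - d$day) / s))

  vi <- var_ident(truth$sigma_base, truth$delta)
  sds <- varident_sd(vi, d$leaf_type)

  p_ar <- as.integer(!is.null(truth$rho))
  q_ma <- as.integer(!is.null(truth$theta))
  if (p_ar || q_ma) {
    cs <- corr_arma(p_ar, q_ma,
                    rho = truth$rho %||% numeric(),
                    theta = truth$theta %||% numeric())
    d2 <- add_series(d)
    z <- numeric(nrow(d))
    for (sid in split(seq_len(nrow(d2)), d2$series)) {
      pos <- d2$date_rank[sid]
      o <- order(pos)
      R <- arma_correlation(cs, length(sid), positions = pos[o])
      z[sid[o]] <- drop(crossprod(chol(R), rnorm(length(sid))))
    }
  } else {
    z <- rnorm(nrow(d))
  }
  d$lfmc <- unname(mu + sds * z)
  d$plot_id <- NULL
  if (n_lost > 0) {
    if (n_lost >= nrow(d)) {
      abort("`n_lost` must be smaller than the design size.",
            class = "fuelmoist_invalid_parameter")
    }
    d <- d[-sample.int(nrow(d), n_lost), ]
  }
  d
}

# Series bookkeeping shared by the simulator, the likelihood and the
# diagnostics: a series is plot x leaf type x replicate rank (1..points,
# ordered by point id within each date), positions are sampling-date ranks.
add_series <- function(d) {
  d |>
    dplyr::mutate(.plot_id = paste(.data$site, .data$plot, sep = ":"),
                  date_rank = dplyr::dense_rank(.data$day)) |>
    dplyr::group_by(.data$.plot_id, .data$leaf_type, .data$day) |>
    dplyr::mutate(.rank = rank(.data$point, ties.method = "first")) |>
    dplyr::ungroup() |>
    dplyr::mutate(series = paste(.data$.plot_id, .data$leaf_type,
                                 .data$.rank, sep = "/")) |>
    dplyr::select(-".rank")
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates datasets from given truth values, fits the
#' generating model by marginal maximum likelihood and summarises how well
#' each parameter is recovered: bias, empirical SD, RMSE and the coverage of
#' the 95 percent Wald intervals.
#'
#' @param truth Generating parameters ([lfmc_truth()]).
#' @param design Design skeleton (default [lfmc_design()]).
#' @param spec Model specification fitted to each replicate (default the
#'   generating structure, [lfmc_final_model()]).
#' @param n_reps Number of replicates (>= 2).
#' @param seed Integer seed for the whole experiment.
#' @param n_lost Observations lost per replicate (default 5).
#' @return A tibble with one row per parameter: `term`, `truth`, `bias`,
#'   `sd`, `rmse`, `coverage`, plus attributes `n_converged` and `n_failed`.
#' @export
lfmc_recovery <- function(truth = lfmc_truth(), design = lfmc_design(),
                          spec = lfmc_final_model(), n_reps = 50,
                          seed = 1, n_lost = 5) {
  if (n_reps < 2) {
    abort("`n_reps` must be at least 2.", class = "fuelmoist_invalid_parameter")
  }
  truth_vec <- truth_as_terms(truth, spec)
  set.seed(seed)
  seeds <- sample.int(2^30, n_reps)
  ests <- list()
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    d <- simulate_lfmc(design, truth, seed = seeds[r], n_lost = n_lost)
    fit <- tryCatch(fit_lfmc(d, spec, seed = seeds[r] + 1L),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    td <- tidy(fit)
    td$rep <- r
    ests[[length(ests) + 1L]] <- td
  }
  if (!length(ests)) {
    abort("No replicate converged.", class = "fuelmoist_convergence_error")
  }
  all_est <- dplyr::bind_rows(ests) |>
    dplyr::filter(.data$term %in% names(truth_vec))
  out <- all_est |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      truth = truth_vec[[dplyr::first(.data$term)]],
      bias = mean(.data$estimate) - .data$truth,
      sd = sd(.data$estimate),
      rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
      coverage = mean(.data$conf.low <= .data$truth &
                        .data$truth <= .data$conf.high),
      mean_se = mean(.data$std.error),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$term, names(truth_vec)))
  attr(out, "n_converged") <- n_reps - n_failed
  attr(out, "n_failed") <- n_failed
  out
}

# truth values keyed by the fitted model's term names
truth_as_terms <- function(truth, spec) {
  out <- c()
  ref <- "GW"
  offs <- c("GE", "SM", "SS")
  for (p in c("A", "w", "m", "s")) {
    v <- truth[[p]]
    if (spec$fixed[[p]] == "leaf_type") {
      vv <- if (length(v) == 1L) setNames(rep(v, 4), lfmc_leaf_levels()) else v
      out[p] <- vv[[ref]]
      for (l in offs) out[paste0(p, "_", l)] <- vv[[l]] - vv[[ref]]
    } else {
      out[p] <- if (length(v) == 1L) v else mean(v)
    }
  }
  for (p in spec$random) {
    out[paste0("sd_", p)] <- truth[[paste0("sd_", p)]]
  }
  out["sigma"] <- truth$sigma_base
  if (spec$variance == "varident") {
    for (l in names(truth$delta)) out[paste0("delta_", l)] <- truth$delta[[l]]
  }
  if (!is.null(spec$correlation)) {
    if (spec$correlation$p > 0) out["rho"] <- truth$rho %||% 0
    if (spec$correlation$q > 0) out["theta"] <- truth$theta %||% 0
  }
  out
}
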