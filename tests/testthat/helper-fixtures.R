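# Shared fixtures, built in code and cached across test files.
#
# The reference dataset is the package's shipped synthetic stand-in for the
# field campaign: the full two-site design simulated from the fitted drying
# model's parameter values (seed chosen as the campaign start date,
# 2013-11-13).

.fx <- new.env(parent = emptyenv())

fixture_data <- function() {
  if (is.null(.fx$data)) {
    path <- system.file("extdata", "lfmc_synthetic.txt",
                        package = "fuelmoist")
    .fx$data <- read_lfmc(path)
  }
  .fx$data
}

fixture_fit <- function() {
  if (is.null(.fx$fit)) {
    .fx$fit <- fit_lfmc(fixture_data(), lfmc_final_model())
  }
  .fx$fit
}

# independent closed-form ARMA(1,1) stationary ACF (oracle, not the package
# implementation)
oracle_arma11_acf <- function(rho, theta, lags) {
  r1 <- (1 + rho * theta) * (rho + theta) / (1 + theta^2 + 2 * rho * theta)
  vapply(lags, function(k) {
    if (k == 0) 1 else r1 * rho^(k - 1)
  }, numeric(1))
}

# Bartlett large-sample SE of an estimated autocorrelation at lag k, given
# the theoretical ACF
bartlett_se <- function(acf_fun, k, n, vmax = 200) {
  v <- seq_len(vmax)
  rv <- acf_fun(v)
  rvk <- acf_fun(v + k)
  rvmk <- acf_fun(abs(v - k))
  rk <- acf_fun(k)
  s <- sum((rvk + rvmk - 2 * rk * rv)^2)
  # v = 0 term
  s0 <- (acf_fun(k) + acf_fun(k) - 2 * rk * 1)^2
  sqrt((s0 + s) / n)
}

# dense multivariate-normal negative log-likelihood, assembled directly from
# full per-plot covariance matrices (independent oracle for the engine)
oracle_dense_negloglik <- function(data, spec, params) {
  d <- dplyr::as_tibble(data)
  d$plot_id <- paste(d$site, d$plot, sep = ":")
  d <- d |>
    dplyr::mutate(date_rank = dplyr::dense_rank(day)) |>
    dplyr::group_by(plot_id, leaf_type, day) |>
    dplyr::mutate(rank = rank(point, ties.method = "first")) |>
    dplyr::ungroup() |>
    dplyr::mutate(series = paste(plot_id, leaf_type, rank, sep = "/"))
  lev <- intersect(c("GW", "GE", "SM", "SS"), unique(as.character(d$leaf_type)))
  ratio <- setNames(rep(1, length(lev)), lev)
  if (spec$variance == "varident") {
    for (l in lev[-1]) ratio[l] <- params[[paste0("delta_", l)]]
  }
  sds <- params[["sigma"]] * ratio[as.character(d$leaf_type)]
  # per-row curve parameters (no plot offsets in the oracle's scope)
  val <- function(p) {
    v <- rep(params[[p]], nrow(d))
    if (spec$fixed[[p]] == "leaf_type") {
      for (l in lev[-1]) {
        v <- v + params[[paste0(p, "_", l)]] *
          (as.character(d$leaf_type) == l)
      }
    }
    v
  }
  if (spec$mean == "logistic") {
    A <- val("A"); w <- val("w"); m <- val("m"); s <- val("s")
    E <- exp((m - d$day) / s)
    mu <- w + (A - w) / (1 + E)
    dA <- 1 / (1 + E)
  } else if (spec$mean == "linear") {
    mu <- val("a") + val("b") * d$day
    dA <- rep(1, nrow(d))
  } else {
    mu <- val("c")
    dA <- rep(1, nrow(d))
  }
  nll <- 0
  for (pl in unique(d$plot_id)) {
    ix <- which(d$plot_id == pl)
    n_j <- length(ix)
    R <- diag(1, n_j)
    if (!is.null(spec$correlation)) {
      rho <- if (spec$correlation$p) params[["rho"]] else 0
      theta <- if (spec$correlation$q) params[["theta"]] else 0
      for (a in seq_len(n_j)) for (b in seq_len(n_j)) {
        if (a != b && d$series[ix[a]] == d$series[ix[b]]) {
          k <- abs(d$date_rank[ix[a]] - d$date_rank[ix[b]])
          R[a, b] <- if (spec$correlation$q == 0) rho^k
          else oracle_arma11_acf(rho, theta, k)
        }
      }
    }
    Sigma <- diag(sds[ix]) %*% R %*% diag(sds[ix])
    for (p in spec$random) {
      cvec <- switch(p, A = dA[ix], a = dA[ix],
                     stop("oracle only covers linear random effects"))
      Sigma <- Sigma + params[[paste0("sd_", p)]]^2 * tcrossprod(cvec)
    }
    r <- d$lfmc[ix] - mu[ix]
    ch <- chol(Sigma)
    z <- backsolve(ch, r, transpose = TRUE)
    nll <- nll + 0.5 * (sum(z^2) + 2 * sum(log(diag(ch))) +
                          n_j * log(2 * pi))
  }
  nll
}
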