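test_that("with no structures the likelihood reduces to iid Gaussian", {
  d <- fixture_data()
  spec <- lfmc_model(mean = "constant", variance = "constant")
  pars <- c(c = 100, sigma = 50)
  nll <- lfmc_negloglik(d, spec, pars)
  r <- d$lfmc - 100
  direct <- 0.5 * (sum(r^2) / 50^2 + length(r) * log(2 * pi * 50^2))
  expect_equal(nll, direct, tolerance = 1e-10)
})

test_that("exact Gaussian marginalisation agrees with quadrature and a dense oracle", {
  d <- fixture_data()
  spec <- lfmc_final_model()
  pars <- c(A = 54.3, A_GE = 30.9, A_SM = 223.4, A_SS = 240.3,
            w = 29.1, w_GE = -20.7, w_SM = 31.7, w_SS = 26.7,
            m = 30.9, s = -16.1, sd_A = 9.4, sigma = 7.1,
            delta_GE = 0.9, delta_SM = 3.2, delta_SS = 3.0)
  nll_exact <- lfmc_negloglik(d, spec, pars, method = "exact")
  nll_agq <- lfmc_negloglik(d, spec, pars, method = "agq")
  nll_lap <- lfmc_negloglik(d, spec, pars, method = "laplace")
  expect_equal(nll_agq, nll_exact, tolerance = 1e-6)
  # the integrand is Gaussian in the random effect, so Laplace is exact too
  expect_equal(nll_lap, nll_exact, tolerance = 1e-6)
  # independent dense multivariate-normal assembly
  expect_equal(nll_exact, oracle_dense_negloglik(d, spec, as.list(pars)),
               tolerance = 1e-8)
})

test_that("the dense oracle also validates varIdent + ARMA structures", {
  tr <- lfmc_truth(rho = 0.5, theta = 0.2)
  d <- simulate_lfmc(lfmc_design(), tr, seed = 77)
  spec <- lfmc_model(fixed = c(A = "leaf_type", w = "leaf_type",
                               m = "common", s = "common"),
                     random = "A", variance = "varident",
                     correlation = c(p = 1, q = 1))
  pars <- c(A = 54.3, A_GE = 30.9, A_SM = 223.4, A_SS = 240.3,
            w = 29.1, w_GE = -20.7, w_SM = 31.7, w_SS = 26.7,
            m = 30.9, s = -16.1, sd_A = 9.4, sigma = 7.1,
            delta_GE = 0.9, delta_SM = 3.2, delta_SS = 3.0,
            rho = 0.5, theta = 0.2)
  expect_equal(lfmc_negloglik(d, spec, pars, method = "exact"),
               oracle_dense_negloglik(d, spec, as.list(pars)),
               tolerance = 1e-8)
  # AR(1) variant
  specar <- spec
  specar$correlation <- list(p = 1L, q = 0L)
  parsar <- pars[setdiff(names(pars), "theta")]
  expect_equal(lfmc_negloglik(d, specar, parsar, method = "exact"),
               oracle_dense_negloglik(d, specar, as.list(parsar)),
               tolerance = 1e-8)
})

test_that("likelihood obeys the Gaussian scaling relation", {
  d <- fixture_data()
  spec <- lfmc_final_model()
  pars <- c(A = 54.3, A_GE = 30.9, A_SM = 223.4, A_SS = 240.3,
            w = 29.1, w_GE = -20.7, w_SM = 31.7, w_SS = 26.7,
            m = 30.9, s = -16.1, sd_A = 9.4, sigma = 7.1,
            delta_GE = 0.9, delta_SM = 3.2, delta_SS = 3.0)
  # scale residuals about the population mean and all SDs by c: the
  # negative log-likelihood shifts by exactly n * log(c)
  cc <- 2
  mu <- {
    lev <- as.character(d$leaf_type)
    A <- pars["A"] + c(GW = 0, GE = pars[["A_GE"]], SM = pars[["A_SM"]],
                       SS = pars[["A_SS"]])[lev]
    w <- pars["w"] + c(GW = 0, GE = pars[["w_GE"]], SM = pars[["w_SM"]],
                       SS = pars[["w_SS"]])[lev]
    unname(w + (A - w) / (1 + exp((pars[["m"]] - d$day) / pars[["s"]])))
  }
  d2 <- d
  d2$lfmc <- mu + cc * (d$lfmc - mu)
  pars2 <- pars
  pars2["sd_A"] <- cc * pars["sd_A"]
  pars2["sigma"] <- cc * pars["sigma"]
  nll1 <- lfmc_negloglik(d, spec, pars)
  nll2 <- lfmc_negloglik(d2, spec, pars2)
  expect_equal(nll2, nll1 + nrow(d) * log(cc), tolerance = 1e-8)
})

test_that("missing parameters and unknown labels are rejected", {
  d <- fixture_data()
  expect_error(lfmc_negloglik(d, lfmc_final_model(), c(A = 1)),
               class = "fuelmoist_invalid_parameter")
  d_bad <- d
  d_bad$leaf_type <- as.character(d_bad$leaf_type)
  d_bad$leaf_type[1] <- "ZZ"
  expect_error(lfmc_negloglik(d_bad, lfmc_final_model(), c(A = 1)),
               class = "fuelmoist_labeling_error")
})
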