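test_that("a perfect fit leaves zero residuals", {
  tr <- lfmc_truth(sd_A = 0, sigma_base = 1e-6)
  d <- simulate_lfmc(lfmc_design(), tr, seed = 2, n_lost = 0)
  spec <- lfmc_model(fixed = c(A = "leaf_type", w = "leaf_type",
                               m = "common", s = "common"),
                     variance = "constant")
  fit <- fit_lfmc(d, spec)
  res <- lfmc_residuals(fit)
  expect_lt(max(abs(res$.resid)), 1e-4)
  # independence structure: normalized equals pearson
  expect_identical(res$.normalized, res$.pearson)
})

test_that("varIdent fits standardise all strata to unit spread", {
  res <- lfmc_residuals(fixture_fit())
  sds <- res |>
    dplyr::group_by(leaf_type) |>
    dplyr::summarise(s = sd(.pearson), .groups = "drop")
  expect_equal(nrow(sds), 4)
  expect_true(all(sds$s > 0.8 & sds$s < 1.2))
})

test_that("fitting the generating AR(1) structure whitens the residuals", {
  tr <- lfmc_truth(rho = 0.6)
  spec <- lfmc_model(fixed = c(A = "leaf_type", w = "leaf_type",
                               m = "common", s = "common"),
                     random = "A", variance = "varident",
                     correlation = c(p = 1, q = 0))
  lag1 <- c()
  for (i in 1:10) {
    d <- simulate_lfmc(lfmc_design(), tr, seed = 500 + i)
    fit <- fit_lfmc(d, spec)
    sm <- residual_summaries(lfmc_residuals(fit))
    lag1 <- c(lag1, mean(sm$autocorrelation$lag1, na.rm = TRUE))
  }
  # mean lag-1 autocorrelation of normalized residuals is centred at zero
  # (short-series estimators are slightly negatively biased; 3 MC SEs of
  # the replicate mean around the small-sample expectation -1/(n-1))
  mc_se <- sd(lag1) / sqrt(length(lag1))
  expect_lt(abs(mean(lag1) - (-1 / 6)), max(3 * mc_se, 0.1))
  # whitening removed most of the generated 0.6 correlation
  expect_lt(mean(lag1), 0.2)
})

test_that("residual summaries quantify spread, trend and autocorrelation", {
  set.seed(9)
  n <- 400
  base <- tibble::tibble(
    leaf_type = factor(rep(c("GW", "GE", "SM", "SS"), each = n / 4),
                       levels = c("GW", "GE", "SM", "SS")),
    series = rep(sprintf("s%02d", 1:40), each = 10),
    date_rank = rep(1:10, 40),
    .fitted = rnorm(n, 100, 20))
  iid <- base
  iid$.pearson <- rnorm(n)
  iid$.normalized <- iid$.pearson
  sm <- residual_summaries(iid)
  expect_true(all(abs(sm$by_stratum$sd_pearson - 1) < 0.2))
  expect_lt(abs(sm$trend), 0.15)
  expect_equal(nrow(sm$qq), n)
  expect_equal(sm$qq$theoretical, qnorm(ppoints(n)))

  # doubled spread in one stratum shows up as a doubled SD ratio
  dbl <- base
  dbl$.pearson <- rnorm(n) * ifelse(base$leaf_type == "SM", 2, 1)
  dbl$.normalized <- dbl$.pearson
  sm2 <- residual_summaries(dbl)
  ratio <- sm2$by_stratum$sd_pearson[sm2$by_stratum$leaf_type == "SM"] /
    sm2$by_stratum$sd_pearson[sm2$by_stratum$leaf_type == "GW"]
  expect_equal(ratio, 2, tolerance = 0.25)

  # single observation per series: autocorrelations are missing
  single <- tibble::tibble(
    leaf_type = factor("GW", levels = c("GW", "GE", "SM", "SS")),
    series = c("a", "b"), date_rank = c(1, 1),
    .fitted = c(1, 2), .pearson = c(0.5, -0.5),
    .normalized = c(0.5, -0.5))
  sm3 <- residual_summaries(single)
  expect_true(all(is.na(sm3$autocorrelation$lag1)))
  expect_error(residual_summaries(iid[0, ]),
               class = "fuelmoist_empty_input")
})

test_that("descriptive intraclass correlation reflects the random effect", {
  fit <- fixture_fit()
  icc <- lfmc_icc(fit, n_pairs = 5e3, seed = 4)
  expect_gt(icc, 0)
  expect_lt(icc, 1)
  # without random effects the within-plot correlation is zero
  fit0 <- fit_lfmc(fixture_data(),
                   lfmc_model(fixed = c(A = "leaf_type", w = "leaf_type",
                                        m = "common", s = "common"),
                              variance = "varident"))
  expect_identical(lfmc_icc(fit0), 0)
})

test_that("autoplot returns plot objects for each panel type", {
  fit <- fixture_fit()
  expect_s3_class(autoplot(fit, type = "fit"), "ggplot")
  expect_s3_class(autoplot(fit, type = "rate"), "ggplot")
  p <- autoplot(fit, type = "residuals")
  expect_true(inherits(p, "ggplot") || inherits(p, "patchwork"))
})
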