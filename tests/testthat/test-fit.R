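test_that("noiseless data recovers the generating fixed effects", {
  tr <- lfmc_truth(sd_A = 0, sigma_base = 1e-6)
  d <- simulate_lfmc(lfmc_design(), tr, seed = 1, n_lost = 0)
  spec <- lfmc_model(fixed = c(A = "leaf_type", w = "leaf_type",
                               m = "common", s = "common"),
                     variance = "constant")
  fit <- fit_lfmc(d, spec)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  truth <- c(A = 54.3, A_GE = 30.9, A_SM = 223.4, A_SS = 240.3,
             w = 29.1, w_GE = -20.7, w_SM = 31.7, w_SS = 26.7,
             m = 30.9, s = -16.1)
  expect_lt(max(abs(est[names(truth)] - truth) / abs(truth)), 1e-6)
})

test_that("the fitted final model matches an independent nlme fit", {
  skip_if_not_installed("nlme")
  d <- fixture_data()
  fit <- fixture_fit()
  expect_true(fit$converged)

  d2 <- as.data.frame(d)
  d2$plot_id <- paste(d2$site, d2$plot, sep = ":")
  d2$leaf_type <- factor(as.character(d2$leaf_type),
                         levels = c("GW", "GE", "SM", "SS"))
  st <- setNames(fit$estimates$estimate[1:10], fit$estimates$term[1:10])
  nf <- nlme::nlme(lfmc ~ w + (A - w) / (1 + exp((m - day) / s)),
                   fixed = list(A ~ leaf_type, w ~ leaf_type, m ~ 1, s ~ 1),
                   random = A ~ 1 | plot_id,
                   weights = nlme::varIdent(form = ~1 | leaf_type),
                   data = d2, method = "ML", start = unname(st),
                   control = nlme::nlmeControl(maxIter = 200,
                                               msMaxIter = 200))
  # same optimum (we allow tiny optimizer differences, and require that our
  # engine's likelihood is not worse)
  expect_equal(fit$logLik, as.numeric(logLik(nf)), tolerance = 1e-4)
  expect_gte(fit$logLik, as.numeric(logLik(nf)) - 0.05)
  # fixed effects agree well within a fraction of their standard errors
  se <- fit$estimates$std.error[1:10]
  expect_true(all(abs(st - nlme::fixef(nf)) < 0.5 * se))
  # random-effect and residual SDs agree (nlme references its varIdent at a
  # different stratum; compare the GW-referenced SD)
  # the likelihood is flat in sd_A (6 plots), so optimizers can halt a few
  # percent apart along that direction
  sd_a_nlme <- as.numeric(nlme::VarCorr(nf)[1, 2])
  expect_equal(unname(fit$estimates$estimate[11]), sd_a_nlme,
               tolerance = 0.05)
})

test_that("AIC identity and parameter counting hold", {
  fit <- fixture_fit()
  expect_equal(fit$k, 15)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$k)
  expect_equal(count_parameters(lfmc_final_model()), 15)
  # hand counts for other structures
  expect_equal(count_parameters(lfmc_model()), 4 * 4 + 0 + 3 + 0 + 1)
  expect_equal(count_parameters(
    lfmc_model(mean = "constant", variance = "constant")), 2)
  m2 <- lfmc_model(fixed = c(A = "leaf_type", w = "leaf_type",
                             m = "leaf_type", s = "leaf_type"),
                   plot_fixed = c("A", "w"), variance = "constant")
  expect_equal(count_parameters(m2), 27)
  m3 <- lfmc_model(mean = "linear",
                   fixed = c(a = "leaf_type", b = "leaf_type"),
                   random = "a", variance = "varident",
                   correlation = c(p = 1, q = 1))
  expect_equal(count_parameters(m3), 15)
  g <- glance(fit)
  expect_equal(g$df, 15)
  expect_equal(g$nobs, 247)
})

test_that("estimates are invariant to row permutation and plot relabeling", {
  d <- fixture_data()
  fit1 <- fixture_fit()
  set.seed(3)
  d_perm <- d[sample.int(nrow(d)), ]
  fit2 <- fit_lfmc(d_perm, lfmc_final_model())
  expect_lt(max(abs(fit1$estimates$estimate - fit2$estimates$estimate)),
            1e-8)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-10)
  # relabel plots (3 -> 9) without changing the grouping
  d_rel <- d
  d_rel$plot <- ifelse(d_rel$plot == 3, 9, d_rel$plot)
  fit3 <- fit_lfmc(d_rel, lfmc_final_model())
  expect_lt(max(abs(fit1$estimates$estimate - fit3$estimates$estimate)),
            1e-8)
})

test_that("prediction levels behave as the model structure dictates", {
  fit <- fixture_fit()
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  # population prediction at t = m for GW is the midpoint of the asymptotes
  nd <- tibble::tibble(leaf_type = "GW", day = est[["m"]])
  expect_equal(predict(fit, nd),
               (est[["A"]] + est[["w"]]) / 2, ignore_attr = TRUE)
  # plot-level predictions differ from population only through A
  nd2 <- tibble::tibble(site = "W", plot = 1, leaf_type = "GW",
                        day = c(0, 30, 89))
  pop <- predict(fit, nd2)
  pl <- predict(fit, nd2, level = "plot")
  b <- fit$ranef$mode[fit$ranef$plot_id == "W:1"]
  P <- 1 / (1 + exp((est[["m"]] - nd2$day) / est[["s"]]))
  expect_equal(pl - pop, b * P, ignore_attr = TRUE, tolerance = 1e-8)
  # a model with no random effects predicts identically at both levels
  spec0 <- lfmc_model(fixed = c(A = "leaf_type", w = "leaf_type",
                                m = "common", s = "common"),
                      variance = "varident")
  fit0 <- fit_lfmc(fixture_data(), spec0)
  expect_equal(predict(fit0, nd2), predict(fit0, nd2, level = "plot"))
  # unknown plot at plot level
  nd_bad <- tibble::tibble(site = "W", plot = 99, leaf_type = "GW", day = 1)
  expect_error(predict(fit, nd_bad, level = "plot"),
               class = "fuelmoist_labeling_error")
})

test_that("drying speed matches closed form and finite differences", {
  fit <- fixture_fit()
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  nd <- tibble::tibble(leaf_type = "SM", day = est[["m"]])
  A_sm <- est[["A"]] + est[["A_SM"]]
  w_sm <- est[["w"]] + est[["w_SM"]]
  expect_equal(lfmc_drying_speed(fit, nd),
               (A_sm - w_sm) / (4 * est[["s"]]), ignore_attr = TRUE)
  # negative everywhere for declining fitted curves
  grid <- tidyr::expand_grid(leaf_type = c("GW", "GE", "SM", "SS"),
                             day = seq(0, 89, by = 1))
  expect_true(all(lfmc_drying_speed(fit, grid) < 0))
  # finite differences of predict
  h <- 1e-4
  g1 <- grid
  g1$day <- g1$day + h
  g0 <- grid
  g0$day <- g0$day - h
  fd <- (predict(fit, g1) - predict(fit, g0)) / (2 * h)
  expect_equal(lfmc_drying_speed(fit, grid), fd, tolerance = 1e-6)
  # unsupported for non-logistic means
  m5 <- fit_lfmc(fixture_data(),
                 lfmc_model(mean = "constant", variance = "constant"))
  expect_error(lfmc_drying_speed(m5),
               class = "fuelmoist_unsupported_operation")
})

test_that("augment returns calibrated residual columns", {
  fit <- fixture_fit()
  aug <- augment(fit)
  expect_equal(nrow(aug), 247)
  expect_equal(aug$.resid, aug$lfmc - aug$.fitted)
  expect_equal(aug$.pearson, aug$.resid / aug$.sd)
  # rows come back in the input order
  expect_equal(aug$day, fixture_data()$day)
})
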