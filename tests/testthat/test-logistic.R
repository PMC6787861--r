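test_that("logistic curve evaluates correctly at anchor points", {
  # midpoint identity
  expect_identical(lfmc_logistic(30, A = 100, w = 20, m = 30, s = -16), 60)
  # direct scalar evaluation of the curve
  expect_equal(lfmc_logistic(10, A = 100, w = 20, m = 30, s = -16),
               20 + 80 / (1 + exp((30 - 10) / (-16))))
  expect_equal(round(lfmc_logistic(10, A = 100, w = 20, m = 30, s = -16), 3),
               82.184)
  # asymptotic limits with the fitted grass-W parameters
  expect_equal(lfmc_logistic(1e6, A = 54.3, w = 29.1, m = 30.9, s = -16.1),
               29.1, tolerance = 1e-12)
  expect_equal(lfmc_logistic(-1e6, A = 54.3, w = 29.1, m = 30.9, s = -16.1),
               54.3, tolerance = 1e-12)
  # vectorised and strictly monotone (declining for s < 0, A > w)
  y <- lfmc_logistic(seq(0, 90, by = 1), A = 100, w = 20, m = 30, s = -16)
  expect_length(y, 91)
  expect_true(all(diff(y) < 0))
})

test_that("invalid logistic parameters are rejected", {
  expect_error(lfmc_logistic(1, A = 100, w = 20, m = 30, s = 0),
               class = "fuelmoist_invalid_parameter")
  expect_error(lfmc_logistic(1, A = NaN, w = 20, m = 30, s = -16),
               class = "fuelmoist_invalid_parameter")
  expect_error(lfmc_logistic(Inf, A = 100, w = 20, m = 30, s = -16),
               class = "fuelmoist_invalid_parameter")
  expect_error(lfmc_logistic_rate(1, A = 100, w = 20, m = 30, s = 0),
               class = "fuelmoist_invalid_parameter")
})

test_that("drying rate matches its closed forms and finite differences", {
  # peak drying speed at the inflection: (A - w) / (4 s)
  expect_equal(lfmc_logistic_rate(30, A = 100, w = 20, m = 30, s = -16),
               -1.25)
  # flat at the asymptotes
  expect_equal(lfmc_logistic_rate(30 + 1e4 * 16, 100, 20, 30, -16), 0,
               tolerance = 1e-12)
  expect_equal(lfmc_logistic_rate(30 - 1e4 * 16, 100, 20, 30, -16), 0,
               tolerance = 1e-12)
  # symmetry about the inflection
  dl <- seq(0.5, 40, by = 0.5)
  expect_equal(lfmc_logistic_rate(30 + dl, 100, 20, 30, -16),
               lfmc_logistic_rate(30 - dl, 100, 20, 30, -16))
  # negative everywhere for a declining curve
  expect_true(all(lfmc_logistic_rate(seq(-50, 150, 1), 100, 20, 30, -16) < 0))

  # agreement with central finite differences over random parameter draws
  set.seed(1)
  for (i in 1:100) {
    A <- runif(1, 40, 300)
    w <- runif(1, 5, 35)
    m <- runif(1, 10, 60)
    s <- -runif(1, 5, 30)
    t0 <- runif(1, 0, 90)
    h <- 1e-6
    fd <- (lfmc_logistic(t0 + h, A, w, m, s) -
             lfmc_logistic(t0 - h, A, w, m, s)) / (2 * h)
    an <- lfmc_logistic_rate(t0, A, w, m, s)
    expect_equal(an, fd, tolerance = 1e-6)
  }
})

test_that("self-start recovers true parameters through a least-squares refit", {
  t <- seq(0, 90, length.out = 50)
  y <- lfmc_logistic(t, A = 100, w = 20, m = 30, s = -16)
  st <- lfmc_self_start(t = t, y = y)
  expect_true(all(is.finite(unlist(st))))
  expect_lt(st$s, 0)
  # scaleOffset makes the relative-offset criterion usable on noiseless data
  nls_fit <- nls(y ~ w + (A - w) / (1 + exp((m - t) / s)),
                 start = as.list(st),
                 control = nls.control(maxiter = 200, scaleOffset = 1))
  cf <- coef(nls_fit)
  expect_equal(unname(cf["A"]), 100, tolerance = 1e-4)
  expect_equal(unname(cf["w"]), 20, tolerance = 1e-4)
  expect_equal(unname(cf["m"]), 30, tolerance = 1e-4)
  expect_equal(unname(cf["s"]), -16, tolerance = 1e-4)
})

test_that("self-start sign convention and degenerate inputs", {
  t <- seq(0, 90, length.out = 30)
  rising <- lfmc_logistic(t, A = 100, w = 20, m = 30, s = 16)
  expect_gt(lfmc_self_start(t = t, y = rising)$s, 0)
  expect_error(lfmc_self_start(t = t, y = rep(50, 30)),
               class = "fuelmoist_degenerate_data")
  expect_error(lfmc_self_start(t = c(0, 1, 2), y = c(1, 2, 3)),
               class = "fuelmoist_insufficient_data")
  expect_error(lfmc_self_start(t = rep(c(0, 1), 5), y = rnorm(10)),
               class = "fuelmoist_insufficient_data")
  # data-frame interface
  d <- tibble::tibble(day = t, lfmc = lfmc_logistic(t, 100, 20, 30, -16))
  expect_s3_class(lfmc_self_start(d), "tbl_df")
})

test_that("least squares started from self-start converges for noisy curves", {
  set.seed(7)
  ok <- 0L
  n_rep <- 100L
  t <- seq(0, 89, length.out = 21)
  for (i in seq_len(n_rep)) {
    A <- runif(1, 60, 300)
    w <- runif(1, 10, 40)
    m <- runif(1, 20, 50)
    s <- -runif(1, 8, 25)
    mu <- lfmc_logistic(t, A, w, m, s)
    y <- mu + rnorm(length(t), 0, 0.05 * diff(range(mu)))
    st <- tryCatch(lfmc_self_start(t = t, y = y), error = function(e) NULL)
    if (is.null(st)) next
    f <- tryCatch(
      nls(y ~ w + (A - w) / (1 + exp((m - t) / s)), start = as.list(st),
          control = nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(f)) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.95)
})
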