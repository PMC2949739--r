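test_that("the drift-recombination expectation has the right values and shape", {
  expect_equal(expected_r2(0, Inf), 10 / 22)
  expect_equal(expected_r2(0, 32), (10 / 22) * (1 + 36 / (32 * 22)))
  expect_lt(expected_r2(1e6, Inf), 1e-4)        # vanishes for n -> infinity
  expect_equal(expected_r2(1e8, 32), 1 / 32, tolerance = 1e-4)  # 1/n floor
  # strictly decreasing in C for a range of sample sizes
  C <- seq(0, 50, length.out = 2000)
  for (n in c(2, 8, 32, Inf))
    expect_true(all(diff(expected_r2(C, n)) < 0))
  # Sved alternative
  expect_equal(expected_r2(c(0, 1, 3), model = "sved"), c(1, 1 / 2, 1 / 4))
  expect_error(expected_r2(-0.1, 10), "domain error")
})

test_that("parametric fit recovers rho from noiseless curve data", {
  n <- 32; rho <- 0.01
  d <- seq(10, 900, by = 10)
  df <- data.frame(distance = d, r2 = expected_r2(rho * d, n))
  fit <- fit_parametric_decay(df, n = n)
  expect_true(fit$converged)
  expect_false(fit$boundary)
  expect_lt(abs(fit$rho_hat - rho), 1e-6)
  # curve values bounded by the C=0 ceiling and decreasing
  expect_true(all(fit$curve$r2 <= expected_r2(0, n) + 1e-12))
  expect_true(all(diff(fit$curve$r2) < 0))
  expect_error(fit_parametric_decay(df[1:2, ], n = n), "insufficient data")
})

test_that("r2 above the model ceiling drives the fit to the boundary", {
  n <- 32
  df <- data.frame(distance = rep(c(50, 100, 200, 400), each = 5), r2 = 0.9)
  fit <- fit_parametric_decay(df, n = n)
  # max attainable expectation ~0.478 < 0.9: boundary or non-convergence,
  # reported rather than raised
  expect_true(!isTRUE(fit$converged) || fit$boundary)
})

test_that("spline decay fit reproduces exact lines and the lm limit", {
  d <- rep(seq(5, 500, by = 5), 2)
  y <- 0.4 - 0.0005 * d
  fit <- fit_nonparametric_decay(data.frame(distance = d, r2 = y))
  pred_on <- approx(fit$curve$distance, fit$curve$r2, xout = c(50, 250, 450))$y
  expect_equal(pred_on, 0.4 - 0.0005 * c(50, 250, 450), tolerance = 1e-6)

  # infinite penalty collapses to ordinary linear regression (closed form)
  set.seed(31)
  d2 <- rep(seq(10, 600, by = 10), 3)
  y2 <- pmax(0, 0.5 * exp(-d2 / 150) + rnorm(length(d2), 0, 0.05))
  fit2 <- fit_nonparametric_decay(data.frame(distance = d2, r2 = y2), sp = Inf)
  ols <- lm(y2 ~ d2)
  grid <- fit2$curve$distance
  expect_equal(fit2$curve$r2,
               unname(coef(ols)[1] + coef(ols)[2] * grid), tolerance = 1e-4)

  # permuting input rows leaves the curve unchanged
  idx <- sample(length(d2))
  fit3 <- fit_nonparametric_decay(data.frame(distance = d2[idx], r2 = y2[idx]))
  fit4 <- fit_nonparametric_decay(data.frame(distance = d2, r2 = y2))
  expect_equal(fit3$curve$r2, fit4$curve$r2, tolerance = 1e-10)

  # no extrapolation beyond the observed distance range
  expect_gte(min(fit4$curve$distance), min(d2))
  expect_lte(max(fit4$curve$distance), max(d2))
  expect_error(fit_nonparametric_decay(
    data.frame(distance = c(1, 1, 2, 2, 3), r2 = 0.1)), "insufficient data")
})

test_that("threshold-crossing distance behaves monotonically and reports not-reached", {
  n <- 32
  d <- seq(1, 800, by = 1)
  mk <- function(rho) {
    df <- data.frame(distance = d, r2 = expected_r2(rho * d, n))
    fit_parametric_decay(df, n = n)
  }
  x_small <- distance_at_threshold(mk(0.005), 0.3)
  x_large <- distance_at_threshold(mk(0.05), 0.3)
  expect_true(x_small$reached && x_large$reached)
  expect_lt(x_large$distance, x_small$distance)
  # threshold 1 is above the C=0 ceiling: crossed at the first grid point
  expect_equal(distance_at_threshold(mk(0.01), 1)$distance, 0)
  # a curve that never decays below the threshold
  flat <- structure(list(method = "parametric",
                         curve = data.frame(distance = d,
                                            r2 = expected_r2(1e-5 * d, n))),
                    class = "decay_fit")
  res <- distance_at_threshold(flat, 0.3)
  expect_false(res$reached)
  expect_true(is.na(res$distance))
})
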