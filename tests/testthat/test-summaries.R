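# exhaustive window scan: reference implementation for the HPD interval
hpd_oracle <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(x[1], x[n])
  bestw <- Inf
  for (i in seq_len(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < bestw - 1e-15) {
      bestw <- w
      best <- c(x[i], x[i + m - 1])
    }
  }
  best
}

test_that("hpd_interval equals the exhaustive window scan", {
  expect_equal(unname(hpd_interval(rep(3, 25))), c(3, 3))
  expect_equal(unname(hpd_interval(1:1000, 0.95)), c(1, 950))
  set.seed(1)
  for (i in 1:40) {
    n <- sample(20:200, 1)
    x <- switch(1 + i %% 3, rnorm(n), rexp(n), sample(1:50, n, TRUE))
    for (mass in c(0.5, 0.9, 0.95)) {
      expect_equal(unname(hpd_interval(x, mass)), hpd_oracle(x, mass))
    }
  }
  z <- rnorm(1e5)
  h <- hpd_interval(z)
  expect_lt(max(abs(h - c(-1.96, 1.96))), 0.05)
  expect_error(hpd_interval(numeric()), "no samples")
  expect_error(hpd_interval(1:10, 1.2), "mass")
})

test_that("phi0_expected reproduces the printed values and its properties", {
  expect_equal(phi0_expected(0.1, 0, 0.01), 0)
  expect_equal(round(phi0_expected(0.1, 0.01, 0.01), 2), 0.33)
  expect_equal(round(phi0_expected(1, 0.01, 0.01), 2), 0.98)
  expect_equal(round(phi0_expected(0.1, 0.02, 0.01), 2), 0.55)
  expect_equal(round(phi0_expected(1, 0.02, 0.01), 2), 1.00)
  expect_error(phi0_expected(0.1, 0.01, 0), "positive")
  # monotone in M and dtau, decreasing in theta, bounded in [0, 1)
  M <- seq(0, 5, length.out = 30)
  expect_true(all(diff(phi0_expected(M, 0.01, 0.01)) > 0))
  dt <- seq(0, 0.1, length.out = 30)
  expect_true(all(diff(phi0_expected(0.5, dt, 0.01)) > 0))
  th <- seq(0.001, 0.1, length.out = 30)
  expect_true(all(diff(phi0_expected(0.5, 0.01, th)) < 0))
  expect_true(all(phi0_expected(runif(100, 0, 10), runif(100), 0.01) <= 1))
  expect_true(all(phi0_expected(runif(100, 0, 2), runif(100, 0, 0.005),
                                1) < 1))
})

test_that("bias_report scores estimates against the truth", {
  set.seed(7)
  tr <- tibble::tibble(tau_r = rnorm(4000, 0.03, 0.002),
                       theta_A = rnorm(4000, 0.012, 0.0005))
  class(tr) <- c("mscoal_trace", class(tr))
  truth <- c(tau_r = 0.03, theta_A = 0.01)
  rep <- bias_report(tr, truth)
  expect_s3_class(rep, "bias_report")
  expect_lt(abs(rep$rel_bias[rep$parameter == "tau_r"]), 0.01)
  expect_true(rep$covered[rep$parameter == "tau_r"])
  expect_equal(rep$rel_bias[rep$parameter == "theta_A"], 0.2,
               tolerance = 0.02)
  expect_false(rep$covered[rep$parameter == "theta_A"])
  expect_error(bias_report(tr, truth, params = "tau_x"), "absent")
  expect_error(bias_report(tr, c(zz = 1)), "no parameter names")
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})

test_that("bias vanishes when sampling at the truth and aggregates average", {
  set.seed(2)
  reports <- lapply(1:5, function(i) {
    tr <- tibble::tibble(tau_r = 0.03 + rnorm(2000, 0, 0.001))
    class(tr) <- c("mscoal_trace", class(tr))
    bias_report(tr, c(tau_r = 0.03))
  })
  agg <- aggregate_bias(reports)
  expect_equal(agg$n_rep, 5)
  expect_lt(abs(agg$rel_bias), 0.005)
  expect_equal(agg$coverage, 1)
})

test_that("calibration rescales tau samples to absolute ages", {
  tr <- tibble::tibble(tau_r = c(0.05, 0.04), tau_s = c(0.025, 0.02))
  # node mode: anchor tau_r at 18.2 Ma -> per-sample scale 364 / 455 Ma
  cal <- calibrate_ages(tr, anchor = "tau_r", anchor_age = 18.2)
  expect_equal(cal$tau_r, c(18.2, 18.2))
  expect_equal(cal$tau_s, c(18.2 * 0.5, 18.2 * 0.5))
  # rate mode: rate 1e-3 per Ma, tau 0.017 -> 17 Ma
  cal2 <- calibrate_ages(tibble::tibble(tau_r = 0.017), rate = 1e-3)
  expect_equal(cal2$tau_r, 17)
  expect_error(calibrate_ages(tibble::tibble(tau_r = c(0, 1)),
                              anchor = "tau_r", anchor_age = 1), "zero")
  expect_error(calibrate_ages(tr, anchor = "tau_r", anchor_age = 1,
                              rate = 1), "not both")
  expect_error(calibrate_ages(tibble::tibble(x = 1), rate = 1), "tau_")
})
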