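make_curve <- function(params, lags = fcs_lag_grid(2e-5, 1)) {
  evaluate_correlation_model(params, lags)
}

test_that("fit recovers noiseless curves to 0.1 percent", {
  p <- fcs_params(5, data.frame(fraction = 1, tau = 1e-3), s = 5)
  f <- fit_correlation(make_curve(p), 1, s_fixed = 5)
  expect_true(f$converged)
  expect_equal(f$params$n_particles, 5, tolerance = 1e-3)
  expect_equal(f$params$components$tau, 1e-3, tolerance = 1e-3)
})

test_that("fit o evaluate is the identity on random noiseless draws", {
  set.seed(2024)
  for (i in 1:25) {
    k <- sample(1:2, 1)
    # well-separated times so components are identifiable
    taus <- sort(10^runif(k, -4.5, -1.5))
    if (k == 2 && taus[2] / taus[1] < 30) taus[2] <- taus[1] * 30
    fr <- if (k == 1) 1 else {
      a <- runif(1, 0.25, 0.75); c(a, 1 - a)
    }
    p <- fcs_params(runif(1, 0.5, 50),
                    data.frame(fraction = fr, tau = taus), s = 5)
    f <- fit_correlation(make_curve(p), k, s_fixed = 5)
    expect_true(f$converged)
    expect_equal(f$params$n_particles, p$n_particles, tolerance = 1e-3)
    expect_equal(f$params$components$tau, taus, tolerance = 1e-3)
    expect_equal(f$params$components$fraction, fr, tolerance = 1e-3)
  }
})

test_that("noisy curves recover N and tau_D within 10 percent (median)", {
  p <- fcs_params(5, data.frame(fraction = 1, tau = 1e-3), s = 5)
  clean <- make_curve(p)
  rec <- t(vapply(1:20, function(s) {
    set.seed(s)
    noisy <- dplyr::mutate(clean, G = G + rnorm(dplyr::n(), sd = 0.005))
    f <- fit_correlation(noisy, 1, s_fixed = 5)
    c(f$params$n_particles, f$params$components$tau)
  }, numeric(2)))
  expect_lt(abs(median(rec[, 1]) - 5) / 5, 0.10)
  expect_lt(abs(median(rec[, 2]) - 1e-3) / 1e-3, 0.10)
})

test_that("one-component fit of two-component data has larger residual", {
  p <- fcs_params(5, data.frame(fraction = c(0.5, 0.5),
                                tau = c(1e-4, 1e-2)), s = 5)
  curve <- make_curve(p)
  f1 <- fit_correlation(curve, 1, s_fixed = 5)
  f2 <- fit_correlation(curve, 2, s_fixed = 5)
  expect_gt(f1$residual_norm, f2$residual_norm)
})

test_that("degenerate and undersized inputs are handled explicitly", {
  flat <- tibble::tibble(lag = fcs_lag_grid(1e-4, 1), G = 0.999)
  expect_warning(f <- fit_correlation(flat, 1, s_fixed = 5),
                 "amplitude-zero")
  expect_equal(f$amplitude, 0)
  expect_true(f$degenerate)
  tiny <- tibble::tibble(lag = c(1e-4, 2e-4, 3e-4), G = c(1.5, 1.4, 1.3))
  expect_error(fit_correlation(tiny, 1), "at least")
})

test_that("free structural parameter is recovered; fixed s is honoured", {
  p <- fcs_params(8, data.frame(fraction = 1, tau = 2e-3), s = 6)
  f_free <- fit_correlation(make_curve(p), 1)
  expect_equal(f_free$params$s, 6, tolerance = 0.02)
  f_fix <- fit_correlation(make_curve(p), 1, s_fixed = 5)
  expect_identical(f_fix$params$s, 5)
})

test_that("tidy and glance summarise a fit", {
  p <- fcs_params(5, data.frame(fraction = 1, tau = 1e-3), s = 5)
  f <- fit_correlation(make_curve(p), 1, s_fixed = 5)
  td <- tidy(f)
  expect_setequal(td$term, c("n_particles", "s", "fraction_1", "tau_1"))
  gl <- glance(f)
  expect_equal(gl$amplitude, 1 / gl$n_particles)
  expect_true(gl$converged)
})

test_that("fitting does not disturb the caller's RNG stream", {
  p <- fcs_params(5, data.frame(fraction = 1, tau = 1e-3), s = 5)
  curve <- make_curve(p)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(fit_correlation(curve, 1, s_fixed = 5))
  expect_identical(runif(1), before)
})
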