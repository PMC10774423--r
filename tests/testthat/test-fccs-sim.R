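test_that("expected diffusion time follows w0^2/(4D) and its scaling", {
  vol <- detection_volume(w0 = 0.25, s = 5)
  expect_equal(expected_tau_d(vol, 25), 6.25e-4)
  expect_equal(expected_tau_d(vol, 50), expected_tau_d(vol, 25) / 2)
})

test_that("a static emitter at the volume centre emits its brightness", {
  sp <- fccs_species("green_only", 1, diffusion = 0, brightness = 123)
  sim <- simulate_fccs_traces(sp, detection_volume(), box_size = 3,
                              duration = 0.01, dt = 1e-4, seed = 5,
                              start_at_center = TRUE)
  expect_equal(sim$traces$green, rep(123, nrow(sim$traces)))
  expect_equal(sim$traces$red, rep(0, nrow(sim$traces)))
})

test_that("preconditions on box size and step size are enforced", {
  sp <- fccs_species("green_only", 5, diffusion = 25)
  expect_error(simulate_fccs_traces(sp, detection_volume(w0 = 0.25),
                                    box_size = 2, duration = 0.1,
                                    dt = 2e-5, seed = 1),
               "box_size")
  expect_error(simulate_fccs_traces(sp, detection_volume(w0 = 0.25),
                                    box_size = 3, duration = 0.1,
                                    dt = 1e-3, seed = 1),
               "green_only")
})

test_that("mean trace intensity matches concentration x brightness", {
  vol <- detection_volume(w0 = 0.25, s = 5)
  sp <- fccs_species("green_only", 60, diffusion = 25, brightness = 200)
  sim <- simulate_fccs_traces(sp, vol, box_size = 3, duration = 2,
                              dt = 2e-5, seed = 11)
  expected <- 60 * 200 * (pi^1.5 * vol$w0^2 * vol$z0 / 27) / (2 * sqrt(2))
  # mean of the 3D Gaussian over the box is Veff/(2 sqrt 2)/Vbox per particle
  # (integral of exp(-2r^2/w^2) = (pi/2)^(3/2) w0^2 z0 = Veff / (2 sqrt 2))
  expect_equal(mean(sim$traces$green), expected, tolerance = 0.10)
})

test_that("seed is recorded and reruns are bit-identical", {
  sp <- fccs_species("dual", 10, diffusion = 25)
  a <- simulate_fccs_traces(sp, detection_volume(), 3, 0.05, 2e-5, seed = 9)
  b <- simulate_fccs_traces(sp, detection_volume(), 3, 0.05, 2e-5, seed = 9)
  expect_identical(a$traces, b$traces)
  expect_equal(a$ground_truth$seed, 9)
})

test_that("fitted particle number scales linearly with species count", {
  vol <- detection_volume()
  ns <- c(10, 20, 40)
  fitted <- vapply(ns, function(cnt) {
    sim <- simulate_fccs_traces(fccs_species("green_only", cnt, 25), vol,
                                box_size = 3, duration = 1, dt = 2e-5,
                                seed = 100 + cnt)
    curve <- estimate_correlation(sim$traces, pairs = "gg")
    fit_correlation(curve, 1, s_fixed = vol$s)$params$n_particles
  }, numeric(1))
  ratios <- fitted / ns
  expect_lt(max(ratios) / min(ratios), 1.6)
  expect_true(all(diff(fitted) > 0))
})

test_that("fitted diffusion time recovers the closed-form expectation", {
  vol <- detection_volume()
  sim <- simulate_fccs_traces(fccs_species("green_only", 40, 25), vol,
                              box_size = 3, duration = 2, dt = 2e-5,
                              seed = 21)
  curve <- estimate_correlation(sim$traces, pairs = "gg")
  f <- fit_correlation(curve, 1, s_fixed = vol$s)
  expect_equal(f$params$components$tau, expected_tau_d(vol, 25),
               tolerance = 0.15)
})

test_that("RCA increases monotonically with the dual-labeled fraction", {
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  mean_rca <- vapply(fracs, function(fr) {
    n_dual <- round(20 * fr)
    mean(fccs_rca_experiment(20 - n_dual, 20 - n_dual, n_dual,
                             seeds = 1:2, duration = 0.4)$rca)
  }, numeric(1))
  expect_identical(order(mean_rca), seq_along(fracs))
  expect_equal(suppressWarnings(cor(mean_rca, fracs, method = "spearman")), 1)
})

test_that("the estimator converges to the diffusion model on a long trace", {
  vol <- detection_volume()
  sim <- simulate_fccs_traces(fccs_species("green_only", 10, 25), vol,
                              box_size = 3, duration = 20, dt = 2e-5,
                              seed = 33)                 # 1e6 samples
  lags <- fcs_lag_grid(2e-5, 2)
  full <- estimate_correlation(sim$traces, pairs = "gg", lags = lags)
  # per-block curves provide a standard error for each lag
  nb <- 10
  n <- nrow(sim$traces)
  len <- n %/% nb
  per_block <- vapply(split(seq_len(nb * len), rep(1:nb, each = len)),
                      function(ix) {
                        estimate_correlation(sim$traces[ix, ], pairs = "gg",
                                             lags = lags)$G
                      }, numeric(length(lags)))
  se <- apply(per_block, 1, sd) / sqrt(nb)
  model <- evaluate_correlation_model(
    fcs_params(sim$ground_truth$n_g,
               data.frame(fraction = 1, tau = expected_tau_d(vol, 25)),
               s = vol$s), lags)$G
  chi2 <- mean(((full$G - model) / se)^2)
  expect_lt(chi2, 2)
})
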