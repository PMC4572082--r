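test_that("the noise-free PSP peaks where the double exponential says", {
  st <- pulse_train(A = 1, NoP = 1, PW = 0.42)
  p <- preset_params("comparison_ddm")
  tstar <- 50 * 1.5 / (50 - 1.5) * log(50 / 1.5)
  expect_equal(tstar, 5.4225, tolerance = 1e-4)
  expect_equal(hm_psp(tstar, st, p), 0.027342, tolerance = 1e-4)
  # the peak really is the maximum on a fine grid
  tt <- seq(0, 100, by = 0.001)
  expect_equal(max(hm_psp(tt, st, p)), hm_psp(tstar, st, p), tolerance = 1e-8)
})

test_that("PSP vanishes below the recruitment kink", {
  st <- pulse_train(A = 0.3, NoP = 2, IPI = 20, PW = 0.42)
  p <- preset_params("comparison_ddm")
  expect_true(all(hm_psp(seq(0, 100, 5), st, p) == 0))
})

test_that("well-separated pulses give two nearly equal PSP peaks", {
  st <- pulse_train(A = 1, NoP = 2, IPI = 150, PW = 0.42)
  p <- preset_params("comparison_ddm")
  tt <- seq(0, 400, by = 0.01)
  x <- hm_psp(tt, st, p)
  pk1 <- max(x[tt < 150])
  pk2 <- max(x[tt >= 150])
  expect_gt(pk2, pk1)
  # the excess is the residual tail of the first transient, ~ exp(-IPI/tau2)
  expect_equal(pk2 / pk1, 1 + exp(-150 / 50), tolerance = 0.01)
})

test_that("closed-form PSP agrees with direct integration of the cascade", {
  skip_if_not_installed("deSolve")
  # oracle: integrate the two cascaded leaky integrators (synapse tau_s,
  # membrane tau2) driven by delta inputs at the onsets
  st <- pulse_train(A = 1.2, NoP = 2, IPI = 30, PW = 0.42)
  p <- preset_params("comparison_ddm")
  scale <- recruitment(fiber_activation(st$A, st$PW, p$tau1), p$alpha1)
  deriv <- function(t, y, parms) {
    list(c(-y[1] / p$tau_s, (-y[2] + y[1]) / p$tau2))
  }
  # impulse of size scale/tau_s injected into the synaptic state per onset
  times1 <- seq(0, 30, by = 0.005)
  sol1 <- deSolve::lsoda(c(scale / p$tau_s, 0), times1, deriv, NULL,
                         rtol = 1e-10, atol = 1e-14)
  y_at_30 <- sol1[nrow(sol1), 2:3]
  times2 <- seq(30, 200, by = 0.005)
  sol2 <- deSolve::lsoda(c(y_at_30[1] + scale / p$tau_s, y_at_30[2]),
                         times2, deriv, NULL, rtol = 1e-10, atol = 1e-14)
  tt <- c(times1, times2[-1])
  oracle <- c(sol1[, 3], sol2[-1, 3])
  ours <- hm_psp(tt, st, p)
  expect_lt(max(abs(ours - oracle)) / max(oracle), 1e-6)
})

test_that("degenerate tau2 = tau_s uses the analytic limit", {
  st <- pulse_train(A = 1, NoP = 1, PW = 0.42)
  p_deg <- ddm_params(0.5, 0.1, tau2 = 1.5, alpha2 = 0.02, sigma = 0, l = 1,
                      tau_s = 1.5)
  p_near <- ddm_params(0.5, 0.1, tau2 = 1.5 * (1 + 1e-7), alpha2 = 0.02,
                       sigma = 0, l = 1, tau_s = 1.5)
  tt <- seq(0, 20, by = 0.1)
  expect_equal(hm_psp(tt, st, p_deg), hm_psp(tt, st, p_near),
               tolerance = 1e-5)
  expect_false(any(is.nan(hm_psp(tt, st, p_deg))))
})

test_that("hazard rate is a sigmoid between 0 and lambdaL", {
  p <- preset_params("threshold_hm")
  expect_equal(hazard_rate(p$alphaL, p), p$lambdaL / 2, tolerance = 1e-12)
  expect_equal(hazard_rate(1e6, p), p$lambdaL, tolerance = 1e-12)
  expect_equal(hazard_rate(0, p), 0.01 / (1 + exp(6)), tolerance = 1e-10)
  expect_equal(hazard_rate(0, p), 2.4726e-5, tolerance = 1e-4)
  x <- seq(-0.01, 0.03, by = 0.001)
  expect_true(all(diff(hazard_rate(x, p)) > 0))
})

test_that("expected spike count integrates the hazard over the trial", {
  p <- preset_params("threshold_hm")
  st0 <- pulse_train(A = 0, NoP = 1, PW = 0.42)
  # zero stimulus: constant integrand with closed form
  expect_equal(expected_spikes(st0, p, T = 500),
               500 * p$lambdaL / (1 + exp(p$alphaL / p$sigmaL)),
               tolerance = 1e-9)
  # lambdaL = 0 kills the count
  p0 <- hm_params(0.06, 0.4, 50, 0.006, 0.001, lambdaL = 0)
  expect_equal(expected_spikes(st0, p0, T = 500), 0)
  # non-decreasing in T
  st <- pulse_train(A = 0.5, NoP = 2, IPI = 50, PW = 0.42)
  lt <- sapply(c(100, 200, 400), function(T) expected_spikes(st, p, T))
  expect_true(all(diff(lt) > 0))
})

test_that("detection probability follows 1 - exp(-lambda_T)", {
  p <- preset_params("threshold_hm")
  st0 <- pulse_train(A = 0, NoP = 1, PW = 0.42)
  res <- hm_detect_prob(st0, p, T = 500)
  expect_equal(res$psi, 0.012287, tolerance = 1e-4)
  expect_equal(res$psi, 1 - exp(-res$lambda_T), tolerance = 1e-12)
  # monotone non-decreasing in amplitude
  stim <- pulse_train(A = seq(0, 2, 0.25), NoP = 1, PW = 0.42,
                      label = as.character(1:9))
  psi <- hm_detect_prob(stim, p, T = 500)$psi
  expect_true(all(diff(psi) >= 0))
})

test_that("both printed forms of the channel combination agree", {
  withr::with_seed(5, {
    for (i in 1:20) {
      lam <- runif(1, 0, 3)
      l <- sample(1:20, 1)
      expect_equal(hm_population_prob(lam, l),
                   population_prob(1 - exp(-lam), l), tolerance = 1e-12)
    }
  })
  expect_equal(hm_population_prob(0.1, 3), 1 - exp(-0.3), tolerance = 1e-12)
})

test_that("the fixed panel quadrature matches adaptive integration", {
  # fitted-regime parameters: moderate slope, where the psychometric curve
  # is genuinely smooth
  p <- hm_params(0.5, 0.1, 50, alphaL = 0.022, sigmaL = 0.0021,
                 lambdaL = 0.402)
  for (i in c(2, 4, 8)) {
    st <- set_amplitude(stim_table2()[i, ], 0.9)
    g <- hm_detect_prob(st, p, T = 500, method = "grid")
    a <- hm_detect_prob(st, p, T = 500, method = "adaptive")
    expect_equal(g$lambda_T, a$lambda_T, tolerance = 1e-6)
  }
})

test_that("the hazard model is at least 10x faster per curve than the DDM", {
  st <- stim_table2()[2, ]
  amps <- seq(0, 2, by = 0.05)
  p_d <- preset_params("comparison_ddm")
  p_h <- hm_params(0.5, 0.1, 50, 0.022, 0.0021, 0.402)
  cfg <- trial_config(N = 200, seed = 1)
  t_d <- system.time(ddm_curve(st, p_d, cfg, amplitudes = amps))[3]
  t_h <- system.time(hm_curve(st, p_h, amplitudes = amps))[3]
  expect_gt(t_d / t_h, 10)
})
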