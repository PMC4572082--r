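test_that("the compiled noise generator is standard normal", {
  z <- nocidetect:::cpp_stream_normals(1e6, 12, 34)
  expect_lt(abs(mean(z)) * sqrt(1e6), 4)
  expect_lt(abs(sd(z) - 1) * sqrt(2e6), 4)
  expect_lt(abs(mean(z^3)), 0.02)
  expect_equal(mean(z^4), 3, tolerance = 0.02)
  # tail mass at 2 and 3 sd against the normal law
  expect_equal(mean(abs(z) > 2), 2 * pnorm(-2), tolerance = 0.03)
  expect_equal(mean(abs(z) > 3), 2 * pnorm(-3), tolerance = 0.1)
  u <- nocidetect:::cpp_stream_uniforms(1e5, 3, 4)
  expect_true(all(u > 0 & u < 1))
  # distinct streams are decorrelated
  z2 <- nocidetect:::cpp_stream_normals(1e6, 12, 35)
  expect_lt(abs(cor(z, z2)), 0.01)
})

test_that("noise-free Euler path matches the closed-form PSP at O(dt)", {
  st <- pulse_train(A = 1, NoP = 2, IPI = 50, PW = 0.42)
  p0 <- ddm_params(0.5, 0.1, 50, 0.02, 0, 1)
  errs <- sapply(c(0.01, 0.005), function(dt) {
    cfg <- trial_config(T = 150, dt = dt, N = 1, seed = 1)
    ens <- ddm_simulate(st, p0, cfg)
    max(abs(ens$x[1, ] - hm_psp(ens$time, st, p0)))
  })
  scale <- max(hm_psp(seq(0, 150, 0.1), st, p0))
  expect_lt(errs[1], 5 * 0.01 * scale)
  # halving dt halves the global error
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.15)
})

test_that("subthreshold drive without noise never spikes", {
  # below the recruitment kink the drive is zero and x stays at 0
  st <- pulse_train(A = 0.4, NoP = 1, PW = 0.42)
  p0 <- ddm_params(0.5, 0.1, 50, 0.02, 0, 1)
  ens <- ddm_simulate(st, p0, fast_config(N = 5))
  expect_true(all(ens$x == 0))
  expect_true(all(ens$crossed == 0))
  # suprathreshold deterministic peak spikes with certainty
  p_low <- ddm_params(0.5, 0.1, 50, 0.01, 0, 1)
  st2 <- pulse_train(A = 1, NoP = 1, PW = 0.42)
  ens2 <- ddm_simulate(st2, p_low, fast_config(N = 5))
  expect_true(all(ens2$crossed == 1))
})

test_that("ensembles are bit-reproducible for a fixed seed", {
  st <- pulse_train(A = 0.8, NoP = 1, PW = 0.42)
  p <- preset_params("comparison_ddm")
  cfg <- fast_config(N = 50)
  a <- ddm_simulate(st, p, cfg)
  b <- ddm_simulate(st, p, cfg)
  expect_identical(a$x, b$x)
  expect_identical(a$crossed, b$crossed)
  crv1 <- ddm_curve(st, p, cfg, amplitudes = seq(0, 2, 0.5))
  crv2 <- ddm_curve(st, p, cfg, amplitudes = seq(0, 2, 0.5))
  expect_identical(crv1$psi, crv2$psi)
})

test_that("spike flags equal threshold crossings of the stored maxima", {
  st <- pulse_train(A = 0.85, NoP = 1, PW = 0.42)
  p <- preset_params("comparison_ddm")
  ens <- ddm_simulate(st, p, fast_config(N = 100))
  expect_equal(ens$crossed, as.integer(ens$xmax >= p$alpha2))
  expect_true(all(ens$x[, 1] == 0))
})

test_that("population combination over independent channels is exact", {
  expect_equal(population_prob(0.5, 1), 0.5)
  expect_equal(population_prob(0.5, 2), 0.75)
  expect_equal(population_prob(0.0123, 8), 1 - (1 - 0.0123)^8, tolerance = 1e-12)
  expect_equal(population_prob(0.0123, 8), 0.094267, tolerance = 1e-5)
  # non-decreasing in l, bounded in [0, 1]
  ps <- population_prob(0.3, 1:20)
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_error(population_prob(1.2, 1), "psi_single")
})

test_that("Clopper-Pearson interval matches the exact binomial test", {
  ci <- clopper_pearson(100, 200)
  oracle <- binom.test(100, 200)$conf.int
  expect_equal(ci$lower, oracle[1], tolerance = 1e-9)
  expect_equal(ci$upper, oracle[2], tolerance = 1e-9)
  expect_equal(ci$lower, qbeta(0.025, 100, 101), tolerance = 1e-12)
  expect_equal(ci$upper, qbeta(0.975, 101, 100), tolerance = 1e-12)
  expect_equal(ci$lower, 0.4286, tolerance = 5e-4)
  expect_equal(ci$upper, 0.5714, tolerance = 5e-4)
  expect_equal(clopper_pearson(0, 200)$lower, 0)
  expect_equal(clopper_pearson(200, 200)$upper, 1)
  expect_error(clopper_pearson(5, 4), "k")
  expect_error(clopper_pearson(1, 10, level = 1.5), "level")
})

test_that("single-channel probability is consistent with a larger ensemble", {
  # just below the noise-free crossing amplitude, so 0 < psi < 1
  st <- pulse_train(A = 0.8, NoP = 2, IPI = 50, PW = 0.42)
  p <- preset_params("comparison_ddm")
  small <- ddm_detect_prob(st, p, trial_config(N = 200, seed = 3))
  big <- ddm_detect_prob(st, p, trial_config(N = 10000, seed = 4))
  expect_gt(small$psi_single, 0)
  expect_lt(small$psi_single, 1)
  se <- sqrt(big$psi_single * (1 - big$psi_single) / 200)
  expect_lt(abs(small$psi_single - big$psi_single), 3 * se)
})

test_that("psychometric curves carry the grid and transform the CI bounds", {
  p <- preset_params("comparison_ddm")
  cfg <- fast_config(N = 50)
  amps <- seq(0, 2, by = 0.25)
  crv <- ddm_curve(stim_table1()[c(1, 3), ], p, cfg, amplitudes = amps)
  expect_equal(nrow(crv), 2 * length(amps))
  expect_true(all(crv$psi >= crv$ci_lo - 1e-12 & crv$psi <= crv$ci_hi + 1e-12))
  expect_true(all(crv$psi >= 0 & crv$psi <= 1))
  # default grid of the study: 201 points from 0 to 2
  expect_length(seq(0, 2, by = 0.01), 201)
  expect_error(ddm_curve(stim_table1()[1, ], p, cfg, amplitudes = c(0.5, 0.2)),
               "increasing")
})

test_that("a huge firing threshold pushes the whole curve to zero", {
  p <- ddm_params(0.5, 0.1, 50, alpha2 = 50, sigma = 0.05, l = 1)
  crv <- ddm_curve(stim_table1()[1, ], p, fast_config(N = 30),
                   amplitudes = seq(0, 2, 0.5))
  expect_true(all(crv$psi == 0))
})

test_that("zero-drive cells are independent by default, shared on request", {
  p <- preset_params("comparison_ddm")
  cfg <- fast_config(N = 100)
  # all three amplitudes are below the kink alpha1/(1-exp(-PW/tau1)) ~ 0.51
  shared <- ddm_curve(stim_table1()[1, ], p, cfg,
                      amplitudes = c(0, 0.1, 0.3), share_subthreshold = TRUE)
  expect_equal(length(unique(shared$k)), 1L)
  indep <- ddm_curve(stim_table1()[1, ], p, cfg, amplitudes = c(0, 0.1, 0.3))
  # independent cells draw from distinct substreams (identical counts for
  # all three would require a 3-way binomial coincidence; allow 2)
  expect_true(length(unique(indep$k)) >= 2L)
})
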