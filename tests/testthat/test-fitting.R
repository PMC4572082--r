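make_hm_curves <- function(params, stim = stim_table1()[c(1, 3), ],
                           amps = seq(0, 2, by = 0.05), T = 500) {
  hm_curve(stim, params, amplitudes = amps, T = T)
}

test_that("the relative fitting error matches hand arithmetic", {
  # two-point grid, single combination: E = ((0-0)^2 + (1-0.9)^2) / (0+1)
  d <- tibble::tibble(model = "DDM", label = "x", NoP = 1L, IPI = NA_real_,
                      PW = 0.42, A = c(0, 1), psi = c(0, 1))
  h <- dplyr::mutate(d, model = "HM", psi = c(0, 0.9))
  expect_equal(fitting_error(d, h), 0.01, tolerance = 1e-12)
  # identical curves give exactly zero
  expect_equal(fitting_error(d, d), 0)
  # asymmetric: the denominator uses the reference curve only
  expect_false(isTRUE(all.equal(fitting_error(d, h), fitting_error(h, d))))
  # mismatched grids are rejected
  h2 <- h; h2$A <- c(0, 1.5)
  expect_error(fitting_error(d, h2), "grids differ")
})

test_that("the fitting error is invariant to combination order", {
  p <- hm_params(0.5, 0.1, 50, 0.022, 0.0021, 0.402)
  d <- make_hm_curves(p)
  h <- make_hm_curves(hm_params(0.5, 0.1, 50, 0.02, 0.003, 0.3))
  e1 <- fitting_error(d, h)
  flip <- function(x) x[order(match(x$label, rev(unique(x$label)))), ]
  e2 <- fitting_error(flip(d), flip(h))
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_gte(e1, 0)
})

test_that("an identically zero reference combination is dropped with a warning", {
  p <- hm_params(0.5, 0.1, 50, 0.022, 0.0021, 0.402)
  d <- make_hm_curves(p)
  d$psi[d$label == "1"] <- 0
  h <- make_hm_curves(p)
  expect_warning(e <- fitting_error(d, h), "dropped")
  # only the surviving combination contributes
  e_rest <- fitting_error(d[d$label == "3", ], h[h$label == "3", ])
  expect_equal(e, e_rest, tolerance = 1e-12)
})

test_that("self-fit recovers known hazard parameters within 1%", {
  truth <- hm_params(0.5, 0.1, 50, alphaL = 0.022, sigmaL = 0.0021,
                     lambdaL = 0.402)
  d <- make_hm_curves(truth, stim = stim_table1()[c(1, 3), ],
                      amps = seq(0, 2, by = 0.05))
  fit <- fit_hm(d, shared = c(alpha1 = 0.5, tau1 = 0.1, tau2 = 50),
                tau_s = 1.5, T = 500, n_starts = 6, seed = 2)
  expect_lt(fit$error, 1e-6)
  expect_equal(fit$params$alphaL, truth$alphaL, tolerance = 0.01)
  expect_equal(fit$params$sigmaL, truth$sigmaL, tolerance = 0.01)
  expect_equal(fit$params$lambdaL, truth$lambdaL, tolerance = 0.01)
  expect_true(fit$converged)
  # reported error equals the error recomputed from the returned curves
  expect_equal(fit$error, fitting_error(fit$curve_d, fit$curve_h),
               tolerance = 1e-10)
})

test_that("the fit is deterministic given curves and seed", {
  truth <- hm_params(0.5, 0.1, 50, 0.022, 0.0021, 0.402)
  d <- make_hm_curves(truth, stim = stim_table1()[1, ],
                      amps = seq(0, 2, by = 0.1))
  f1 <- fit_hm(d, shared = c(alpha1 = 0.5, tau1 = 0.1, tau2 = 50),
               n_starts = 3, seed = 9)
  f2 <- fit_hm(d, shared = c(alpha1 = 0.5, tau1 = 0.1, tau2 = 50),
               n_starts = 3, seed = 9)
  expect_identical(f1$params$alphaL, f2$params$alphaL)
  expect_identical(f1$error, f2$error)
})

test_that("tidy and glance summarise a fit", {
  truth <- hm_params(0.5, 0.1, 50, 0.022, 0.0021, 0.402)
  d <- make_hm_curves(truth, stim = stim_table1()[1, ],
                      amps = seq(0, 2, by = 0.1))
  fit <- fit_hm(d, shared = c(alpha1 = 0.5, tau1 = 0.1, tau2 = 50),
                n_starts = 2, seed = 1)
  td <- tidy(fit)
  expect_equal(td$term, c("alphaL", "sigmaL", "lambdaL"))
  expect_true(all(td$estimate > 0))
  gl <- glance(fit)
  expect_true(gl$error >= 0)
})

test_that("admissible parameter samples respect the box and the endpoints", {
  cfg <- trial_config(T = 500, dt = 0.02, N = 50, seed = 31)
  stim <- stim_table1()[c(1, 3), ]
  th <- sample_admissible_theta(3, stimuli = stim, config = cfg)
  b <- table3_bounds()
  for (p in c("alpha1", "tau1", "tau2", "alpha2", "sigma", "l")) {
    expect_true(all(th[[p]] >= b$lower[b$parameter == p] &
                      th[[p]] <= b$upper[b$parameter == p]))
  }
  expect_true(all(th$l == round(th$l)))
  expect_true(attr(th, "rejections") >= 0)
  # the accepted samples satisfy the endpoint restrictions when re-checked
  # with the same N and dt
  for (i in 1:3) {
    pars <- ddm_params(th$alpha1[i], th$tau1[i], th$tau2[i], th$alpha2[i],
                       th$sigma[i], th$l[i])
    cfg_i <- trial_config(T = cfg$T, dt = cfg$dt, N = cfg$N,
                          seed = derive_seed(cfg$seed, 123 + i))
    crv <- ddm_curve(stim, pars, cfg_i, amplitudes = c(0, 2))
    psi0 <- max(crv$psi[crv$A == 0])
    psi2 <- min(crv$psi[crv$A == 2])
    # independent re-simulation: allow binomial slack around the cutoffs
    expect_lt(psi0, 0.35 + 3 * sqrt(0.35 * 0.65 / cfg$N))
    expect_gt(psi2, 0.65 - 3 * sqrt(0.35 * 0.65 / cfg$N))
  }
})

test_that("a small Monte Carlo study produces a valid error distribution", {
  cfg <- trial_config(T = 500, dt = 0.02, N = 50, seed = 17)
  study <- mc_fit_study(n_samples = 2, stimuli = stim_table1()[c(1, 3), ],
                        config = cfg, amplitudes = seq(0, 2, by = 0.1),
                        fit_starts = 3)
  expect_s3_class(study, "mc_study")
  expect_equal(nrow(study$samples), 2L)
  expect_true(all(study$errors >= 0))
  # F_E is a valid CDF: non-decreasing from 0 to 1
  knots <- sort(study$errors)
  expect_true(all(diff(study$F_E(knots)) >= 0))
  expect_equal(study$F_E(max(knots)), 1)
  expect_equal(study$F_E(min(knots) - 1e-9), 0)
  gl <- glance(study)
  expect_equal(gl$n_accepted, 2L)
  expect_true(is.finite(gl$median_error))
})
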