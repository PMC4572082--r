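#' Relative fitting error between two sets of psychometric curves
#'
#' Sum over stimulus combinations of the squared curve difference
#' normalised by the squared reference curve:
#' `E = sum_j sum_i (PsiD_j(A_i) - PsiH_j(A_i))^2 / sum_i PsiD_j(A_i)^2`.
#' The denominator uses the reference (drift-diffusion) curve only, so the
#' measure is asymmetric. Combinations whose reference curve is identically
#' zero on the grid are dropped with a warning (0/0 guard).
#'
#' @param curve_d Reference curves (an `nd_curve` tibble, typically from
#'   [ddm_curve()]).
#' @param curve_h Comparison curves on the same combinations and amplitude
#'   grid (typically from [hm_curve()]).
#' @return The scalar error `E >= 0`.
#' @export
#' @examples
#' d <- hm_curve(stim_table1()[1, ], preset_params("threshold_hm"),
#'               amplitudes = seq(0, 2, 0.1))
#' fitting_error(d, d)
fitting_error <- function(curve_d, curve_h) {
  labs <- unique(curve_d$label)
  if (!setequal(labs, unique(curve_h$label))) {
    abort("curves must cover the same stimulus combinations")
  }
  E <- 0
  for (lb in labs) {
    d <- curve_d[curve_d$label == lb, ]
    h <- curve_h[curve_h$label == lb, ]
    if (nrow(d) != nrow(h) || any(abs(d$A - h$A) > 1e-9)) {
      abort(paste0("amplitude grids differ for combination ", lb))
    }
    den <- sum(d$psi^2)
    if (den == 0) {
      warn(paste0("combination ", lb,
                  " has an identically zero reference curve; dropped"))
      next
    }
    E <- E + sum((d$psi - h$psi)^2) / den
  }
  E
}

# Precompute everything the fit objective needs from a reference curve set:
# per combination the quadrature rule, drive scales and reference psi.
fit_terms <- function(curve_d, shared, tau_s, T) {
  labs <- unique(curve_d$label)
  terms <- list()
  for (lb in labs) {
    d <- curve_d[curve_d$label == lb, ]
    st <- pulse_train(A = NA_real_, NoP = d$NoP[1], IPI = d$IPI[1],
                      PW = d$PW[1], label = lb)
    q <- hm_quad(st, T, shared[["tau2"]], tau_s)
    scales <- recruitment(
      fiber_activation(d$A, d$PW[1], shared[["tau1"]]), shared[["alpha1"]])
    den <- sum(d$psi^2)
    if (den == 0) {
      warn(paste0("combination ", lb,
                  " has an identically zero reference curve; dropped from fit"))
      next
    }
    terms[[lb]] <- list(X = outer(scales, q$g), w = q$w, psi = d$psi, den = den)
  }
  if (length(terms) == 0) abort("no usable combinations to fit")
  terms
}

fit_objective <- function(logpar, terms) {
  alphaL <- exp(logpar[1]); sigmaL <- exp(logpar[2]); lambdaL <- exp(logpar[3])
  E <- 0
  for (tm in terms) {
    lam <- as.vector(plogis((tm$X - alphaL) / sigmaL) %*% tm$w) * lambdaL
    E <- E + sum((tm$psi - (1 - exp(-lam)))^2) / tm$den
  }
  E
}

# data-driven initial guess: put the hazard threshold at the PSP peak of
# the reference half-detection amplitude, a 10% relative slope, and a rate
# that makes roughly one expected spike near threshold
fit_start_heuristic <- function(curve_d, terms, shared, tau_s) {
  d1 <- curve_d[curve_d$label == names(terms)[1], ]
  a50 <- tryCatch(curve_level(d1$A, d1$psi, 0.5), error = function(e) NA_real_)
  if (is.na(a50)) a50 <- d1$A[which.min(abs(d1$psi - 0.5))]
  scale <- recruitment(fiber_activation(a50, d1$PW[1], shared[["tau1"]]),
                       shared[["alpha1"]])
  tau2 <- shared[["tau2"]]
  tstar <- tau2 * tau_s / (tau2 - tau_s) * log(tau2 / tau_s)
  peak <- max(scale * psp_shape(tstar, 0, tau2, tau_s), 1e-4)
  c(log(peak), log(0.1 * peak), log(log(2) / (0.2 * tau2)))
}

#' Fit the hazard model's central parameters to reference curves
#'
#' Jointly estimates `(alphaL, sigmaL, lambdaL)` by minimising
#' [fitting_error()] against drift-diffusion psychometric curves across all
#' stimulus combinations simultaneously. The peripheral and membrane
#' parameters `alpha1`, `tau1`, `tau2` (and `tau_s`) are shared between the
#' models and taken from the curves' generating parameters. Optimisation is
#' multi-start Nelder-Mead over the log-transformed parameters (positivity
#' by construction): a data-driven start plus stratified log-uniform
#' starts, the best of which are refined to a tight tolerance. Given the
#' curves and `seed`, the result is deterministic.
#'
#' @param curve_d Reference curves from [ddm_curve()] (or any `nd_curve`
#'   with the same columns).
#' @param shared Named numeric vector with `alpha1`, `tau1`, `tau2`;
#'   defaults to the curves' `params` attribute.
#' @param tau_s Synaptic decay constant (ms); default from the curves'
#'   parameters.
#' @param T Trial interval (ms); default from the curves' configuration.
#' @param n_starts Number of optimizer starts (`>= 1`).
#' @param seed Integer seed for the start placement.
#' @return An object of class `hm_fit` with elements `params` (the fitted
#'   [hm_params()]), `error` (minimised `E`), `trace` (per-start tibble),
#'   `converged`, `curve_d` and the fitted curves `curve_h` evaluated on
#'   the same grid. Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' stim <- stim_table1()[c(1, 3), ]
#' truth <- preset_params("threshold_hm")
#' d <- hm_curve(stim, truth, amplitudes = seq(0, 2, 0.05))
#' fit <- fit_hm(d, shared = c(alpha1 = 0.06, tau1 = 0.4, tau2 = 50),
#'               n_starts = 4)
#' glance(fit)
fit_hm <- function(curve_d, shared = NULL, tau_s = NULL, T = NULL,
                   n_starts = 8, seed = 1L) {
  pars <- attr(curve_d, "params")
  cfg <- attr(curve_d, "config")
  if (is.null(shared)) {
    if (is.null(pars)) abort("supply `shared` (alpha1, tau1, tau2): the curves carry no parameters")
    shared <- c(alpha1 = pars$alpha1, tau1 = pars$tau1, tau2 = pars$tau2)
  }
  if (!all(c("alpha1", "tau1", "tau2") %in% names(shared))) {
    abort("`shared` must name alpha1, tau1 and tau2")
  }
  tau_s <- tau_s %||% (if (!is.null(pars)) pars$tau_s else 1.5)
  T <- T %||% (if (!is.null(cfg)) cfg$T else 500)

  terms <- fit_terms(curve_d, shared, tau_s, T)

  lo <- log(c(1e-4, 1e-5, 1e-3))
  hi <- log(c(1, 0.2, 10))
  starts <- matrix(fit_start_heuristic(curve_d, terms, shared, tau_s),
                   nrow = 1)
  if (n_starts > 1) {
    extra <- withr::with_seed(derive_seed(seed, 811), {
      n1 <- n_starts - 1
      u <- vapply(1:3, function(j) (sample(n1) - runif(n1)) / n1,
                  numeric(n1))
      u <- matrix(u, nrow = n1)
      sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
    })
    starts <- rbind(starts, extra)
  }

  stage1 <- lapply(seq_len(nrow(starts)), function(i) {
    optim(starts[i, ], fit_objective, terms = terms, method = "Nelder-Mead",
          control = list(maxit = 400, reltol = 1e-9))
  })
  vals <- vapply(stage1, `[[`, numeric(1), "value")
  refine_idx <- head(order(vals), 2L)
  refined <- lapply(stage1[refine_idx], function(fit) {
    optim(fit$par, fit_objective, terms = terms, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-13))
  })
  pre <- refined[[which.min(vapply(refined, `[[`, numeric(1), "value"))]]
  # fresh simplex around the optimum guards against premature collapse
  best <- optim(pre$par, fit_objective, terms = terms, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-13))
  if (pre$value < best$value) best <- pre

  fitted <- hm_params(
    alpha1 = shared[["alpha1"]], tau1 = shared[["tau1"]],
    tau2 = shared[["tau2"]], alphaL = exp(best$par[1]),
    sigmaL = exp(best$par[2]), lambdaL = exp(best$par[3]), tau_s = tau_s
  )
  templates <- dplyr::distinct(
    as_tibble(curve_d)[, c("label", "NoP", "IPI", "PW")])
  templates$A <- NA_real_
  curve_h <- hm_curve(validate_stimuli(templates), fitted,
                      amplitudes = sort(unique(curve_d$A)), T = T)
  trace <- tibble(
    start = seq_len(nrow(starts)),
    value = vals,
    iterations = vapply(stage1, function(f) unname(f$counts[1]), numeric(1)),
    refined = seq_len(nrow(starts)) %in% refine_idx
  )
  structure(
    list(params = fitted, error = best$value, trace = trace,
         converged = best$convergence == 0, n_starts = n_starts,
         shared = shared, T = T, curve_d = curve_d, curve_h = curve_h),
    class = "hm_fit"
  )
}

#' @export
print.hm_fit <- function(x, ...) {
  cat("<hm_fit> E =", signif(x$error, 4),
      " alphaL =", signif(x$params$alphaL, 4),
      " sigmaL =", signif(x$params$sigmaL, 4),
      " lambdaL =", signif(x$params$lambdaL, 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @method tidy hm_fit
#' @export
tidy.hm_fit <- function(x, ...) {
  tibble(
    term = c("alphaL", "sigmaL", "lambdaL"),
    estimate = c(x$params$alphaL, x$params$sigmaL, x$params$lambdaL),
    unit = c("A/s", "A/s", "kHz")
  )
}

#' @method glance hm_fit
#' @export
glance.hm_fit <- function(x, ...) {
  tibble(error = x$error, converged = x$converged, n_starts = x$n_starts)
}

#' Sample admissible drift-diffusion parameter vectors
#'
#' Draws parameter vectors uniformly from the study box ([table3_bounds()];
#' `l` uniform over its integer range) and keeps only those whose simulated
#' psychometric endpoints are experimentally plausible: the detection
#' probability must stay below `limits[1]` at zero amplitude and exceed
#' `limits[2]` at the top amplitude for every stimulus combination.
#' Rejected draws are redrawn; the endpoint probabilities are estimated
#' with the same `N` and `dt` that the study run itself uses.
#'
#' @param n Number of accepted samples to return.
#' @param bounds Bounds tibble as from [table3_bounds()].
#' @param stimuli Stimulus templates the study fits (for the endpoint
#'   checks).
#' @param config A [trial_config()]; its `seed` drives both the draws and
#'   the endpoint simulations.
#' @param a_max Top amplitude of the grid (mA).
#' @param limits Length-2 vector: admissible `Psi(0) < limits[1]` and
#'   `Psi(a_max) > limits[2]`.
#' @param max_reject Error out after this many consecutive rejections.
#' @return A tibble of accepted parameter vectors (columns `alpha1`,
#'   `tau1`, `tau2`, `alpha2`, `sigma`, `l`) with the total rejection count
#'   in attribute `rejections`.
#' @export
sample_admissible_theta <- function(n = 1, bounds = table3_bounds(),
                                    stimuli = stim_table2(),
                                    config = trial_config(),
                                    a_max = 2, limits = c(0.35, 0.65),
                                    max_reject = 1000L) {
  b <- bounds
  rownames_b <- b$parameter
  get_b <- function(p) c(b$lower[b$parameter == p], b$upper[b$parameter == p])
  stopifnot(all(c("alpha1", "tau1", "tau2", "alpha2", "sigma", "l") %in% rownames_b))
  out <- vector("list", n)
  rejections <- 0L
  candidate <- 0L
  for (i in seq_len(n)) {
    streak <- 0L
    repeat {
      candidate <- candidate + 1L
      th <- withr::with_seed(derive_seed(config$seed, candidate), {
        draw <- function(p) runif(1, get_b(p)[1], get_b(p)[2])
        lr <- get_b("l")
        list(alpha1 = draw("alpha1"), tau1 = draw("tau1"), tau2 = draw("tau2"),
             alpha2 = draw("alpha2"), sigma = draw("sigma"),
             l = sample(seq(lr[1], lr[2]), 1))
      })
      pars <- ddm_params(th$alpha1, th$tau1, th$tau2, th$alpha2, th$sigma, th$l)
      cfg_i <- trial_config(T = config$T, dt = config$dt, N = config$N,
                            seed = derive_seed(config$seed, 500000L + candidate))
      if (theta_admissible(pars, stimuli, cfg_i, a_max, limits)) {
        out[[i]] <- as_tibble(th)
        break
      }
      rejections <- rejections + 1L
      streak <- streak + 1L
      if (streak >= max_reject) {
        abort(paste0(max_reject, " consecutive rejections while sampling",
                     " admissible parameters"))
      }
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "rejections") <- rejections
  res
}

theta_admissible <- function(pars, stimuli, config, a_max, limits) {
  # Psi at A = 0: zero recruited drive, identical for every combination
  st0 <- stimuli[1, ]
  shape0 <- synaptic_drive_grid(st0, config$T, config$dt, pars$tau_s)
  k0 <- ddm_crossings(shape0, 0, st0$PW, pars, config, stream = 0L)
  psi0 <- population_prob(k0 / config$N, pars$l)
  if (!(psi0 < limits[1])) return(FALSE)
  for (i in seq_len(nrow(stimuli))) {
    st <- stimuli[i, ]
    shape <- synaptic_drive_grid(st, config$T, config$dt, pars$tau_s)
    k <- ddm_crossings(shape, a_max, st$PW, pars, config, stream = i * 1000L)
    if (!(population_prob(k / config$N, pars$l) > limits[2])) return(FALSE)
  }
  TRUE
}

#' Monte Carlo study of the hazard-model fitting error
#'
#' Repeats the whole model-comparison pipeline over random admissible
#' drift-diffusion parameter vectors: sample a vector from the study box,
#' simulate its psychometric curves for every stimulus combination, fit
#' `(alphaL, sigmaL, lambdaL)` of the hazard model, and record the fitting
#' error. The empirical distribution `F_E` of the errors summarises how
#' well the hazard model emulates the drift-diffusion model across the
#' parameter space. Each sample runs on its own seed substream, so any
#' single sample can be reproduced in isolation.
#'
#' @param n_samples Number of accepted samples (the study size).
#' @param bounds Parameter box, as from [table3_bounds()].
#' @param stimuli Stimulus templates fitted per sample.
#' @param config A [trial_config()] used for all simulations.
#' @param amplitudes Amplitude grid for curves and fits.
#' @param fit_starts Optimizer starts per fit (passed to [fit_hm()]).
#' @return An object of class `mc_study`: list with `samples` (one row per
#'   accepted sample: the drawn parameters, fitted values, `error` and
#'   `converged`), `rejections`, and the error ECDF `F_E`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
mc_fit_study <- function(n_samples = 500, bounds = table3_bounds(),
                         stimuli = stim_table2(), config = trial_config(),
                         amplitudes = seq(0, 2, by = 0.01), fit_starts = 6) {
  a_max <- max(amplitudes)
  theta <- sample_admissible_theta(n_samples, bounds, stimuli, config,
                                   a_max = a_max)
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    th <- theta[i, ]
    pars <- ddm_params(th$alpha1, th$tau1, th$tau2, th$alpha2, th$sigma, th$l)
    cfg_i <- trial_config(T = config$T, dt = config$dt, N = config$N,
                          seed = derive_seed(config$seed, i))
    row <- dplyr::mutate(th, sample = i, .before = 1)
    res <- tryCatch({
      crv <- ddm_curve(stimuli, pars, cfg_i, amplitudes = amplitudes)
      fit <- fit_hm(crv, n_starts = fit_starts, seed = derive_seed(config$seed, 900000L + i))
      dplyr::mutate(row, error = fit$error, alphaL = fit$params$alphaL,
                    sigmaL = fit$params$sigmaL, lambdaL = fit$params$lambdaL,
                    converged = fit$converged, note = NA_character_)
    }, error = function(e) {
      dplyr::mutate(row, error = NA_real_, alphaL = NA_real_,
                    sigmaL = NA_real_, lambdaL = NA_real_, converged = FALSE,
                    note = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  samples <- dplyr::bind_rows(rows)
  errs <- sort(samples$error[!is.na(samples$error)])
  structure(
    list(samples = samples, rejections = attr(theta, "rejections"),
         errors = errs, F_E = stats::ecdf(errs), config = config,
         amplitudes = amplitudes),
    class = "mc_study"
  )
}

#' @export
print.mc_study <- function(x, ...) {
  cat("<mc_study>", nrow(x$samples), "accepted samples (",
      x$rejections, "rejections ), median E =",
      signif(stats::median(x$errors), 4), "\n")
  invisible(x)
}

#' @method tidy mc_study
#' @export
tidy.mc_study <- function(x, ...) as_tibble(x$samples)

#' @method glance mc_study
#' @export
glance.mc_study <- function(x, ...) {
  tibble(
    n_accepted = nrow(x$samples), n_rejected = x$rejections,
    n_failed = sum(is.na(x$samples$error)),
    median_error = stats::median(x$errors),
    q90_error = unname(stats::quantile(x$errors, 0.9))
  )
}
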