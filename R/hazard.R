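# Unit-drive noise-free PSP shape: for each onset o,
#   (exp(-(t-o)/tau2) - exp(-(t-o)/tau_s)) / (tau2 - tau_s) for t >= o,
# i.e. the response of the cascaded synapse + membrane filter to one pulse
# of unit recruited drive. When tau2 ~ tau_s (relative gap < 1e-9) the
# removable singularity is replaced by the limit ((t-o)/tau^2) exp(-(t-o)/tau).
psp_shape <- function(t, onsets, tau2, tau_s) {
  out <- numeric(length(t))
  degenerate <- abs(tau2 - tau_s) < 1e-9 * tau2
  for (o in onsets) {
    on <- t >= o - 1e-12
    dtau <- t[on] - o
    out[on] <- out[on] + if (degenerate) {
      (dtau / tau2^2) * exp(-dtau / tau2)
    } else {
      (exp(-dtau / tau2) - exp(-dtau / tau_s)) / (tau2 - tau_s)
    }
  }
  out
}

#' Noise-free postsynaptic potential of the lumped model
#'
#' Closed-form solution of the cascaded synaptic and membrane leaky
#' integrators driven by a pulse train: each pulse contributes a
#' double-exponential transient scaled by the recruited drive
#' `[f_A - alpha1]_+`. This is the deterministic backbone shared by both
#' models: the drift of the DDM and the input to the hazard rate.
#'
#' @param t Time points in ms (vectorised, `>= 0`).
#' @param stim A one-row stimulus tibble with amplitude set.
#' @param params A [ddm_params()] or [hm_params()] object (only `alpha1`,
#'   `tau1`, `tau2`, `tau_s` are used).
#' @return The scaled noise-free PSP `x0(t)` in A/s.
#' @export
#' @examples
#' stim <- pulse_train(A = 1, NoP = 1, PW = 0.42)
#' hm_psp(c(1, 5.42, 50), stim, preset_params("comparison_ddm"))
hm_psp <- function(t, stim, params) {
  stim <- validate_stimuli(stim)
  if (nrow(stim) != 1L) abort("hm_psp() takes a single stimulus row")
  if (is.na(stim$A)) abort("stimulus amplitude A must be set")
  if (any(t < 0)) abort("t must be >= 0")
  scale <- drive_scale(stim$A, stim$PW, params)
  scale * psp_shape(t, stim_onsets(stim), params$tau2, params$tau_s)
}

#' Sigmoidal hazard rate of the escape-noise model
#'
#' Instantaneous firing rate of the secondary-neuron population as a
#' sigmoidal function of the noise-free PSP:
#' `lambda = lambdaL / (1 + exp(-(x0 - alphaL) / sigmaL))`. The rate is
#' `lambdaL / 2` at `x0 = alphaL` and saturates at the population ceiling
#' `lambdaL`; even at `x0 = 0` there is a small spontaneous rate.
#'
#' @param x0 Noise-free PSP in A/s (vectorised).
#' @param params An [hm_params()] object.
#' @return Hazard rate in kHz, in `(0, lambdaL)`.
#' @export
#' @examples
#' hazard_rate(c(0, 0.006, 1), preset_params("threshold_hm"))
hazard_rate <- function(x0, params) {
  stopifnot(inherits(params, "hm_params"))
  params$lambdaL * plogis((x0 - params$alphaL) / params$sigmaL)
}

#' Expected number of spikes within a trial
#'
#' Integrates the hazard rate over the trial window `[0, T]` by adaptive
#' quadrature, split at the pulse onsets where the integrand has kinks.
#'
#' @param stim A one-row stimulus tibble with amplitude set.
#' @param params An [hm_params()] object.
#' @param T Trial interval in ms.
#' @param rel_tol Relative tolerance passed to [stats::integrate()].
#' @return The dimensionless expected spike count `lambda_T >= 0`.
#' @export
#' @examples
#' stim <- pulse_train(A = 1, NoP = 2, IPI = 50, PW = 0.42)
#' expected_spikes(stim, preset_params("demo_hm"))
expected_spikes <- function(stim, params, T = 500, rel_tol = 1e-10) {
  stopifnot(inherits(params, "hm_params"))
  stim <- validate_stimuli(stim)
  if (!(is.numeric(T) && length(T) == 1L && T > 0)) abort("T must be > 0")
  if (params$lambdaL == 0) return(0)
  onsets <- stim_onsets(stim)
  # split at onsets, then grade each segment behind its onset: at strong
  # drive the rate rises almost step-like on the tau_s scale, and the
  # adaptive rule needs the feature isolated in a short panel
  offs <- c(0, 0.5, 2, 8, 32, 128)
  breaks <- c(0, T, as.vector(outer(offs, onsets[onsets < T], "+")))
  breaks <- sort(unique(pmin(pmax(breaks, 0), T)))
  f <- function(t) hazard_rate(hm_psp(t, stim, params), params)
  total <- 0
  for (s in seq_len(length(breaks) - 1L)) {
    res <- tryCatch(
      integrate(f, breaks[s], breaks[s + 1L], rel.tol = rel_tol,
                subdivisions = 500L),
      error = function(e) {
        abort(paste0("hazard-rate integration failed on [", breaks[s], ", ",
                     breaks[s + 1L], "] ms: ", conditionMessage(e)))
      }
    )
    total <- total + res$value
  }
  total
}

#' Detection probability of the hazard model
#'
#' The probability of at least one spike of the inhomogeneous Poisson
#' process over the trial: `Psi_H = 1 - exp(-lambda_T)`. The population
#' size is already lumped into `lambdaL`, so no extra channel combination
#' is applied. Monotone non-decreasing in amplitude, `lambdaL` and `T`.
#'
#' @param stimuli A stimulus tibble with amplitudes set.
#' @param params An [hm_params()] object.
#' @param T Trial interval in ms.
#' @param method `"adaptive"` integrates the hazard rate with
#'   [stats::integrate()]; `"grid"` uses the fixed graded Gauss-Legendre
#'   panel rule shared with [hm_curve()] and the fitting routines.
#' @return A tibble with columns `label`, `A`, `lambda_T`, `psi`.
#' @export
#' @examples
#' stim <- pulse_train(A = c(0, 0.35), NoP = 2, IPI = 50, PW = 0.42,
#'                     label = c("zero", "near-threshold"))
#' hm_detect_prob(stim, preset_params("threshold_hm"))
hm_detect_prob <- function(stimuli, params, T = 500,
                           method = c("adaptive", "grid")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "hm_params"))
  stimuli <- validate_stimuli(stimuli)
  if (any(is.na(stimuli$A))) abort("all stimulus amplitudes must be set")
  lam <- vapply(seq_len(nrow(stimuli)), function(i) {
    st <- stimuli[i, ]
    if (method == "adaptive") {
      expected_spikes(st, params, T)
    } else {
      q <- hm_quad(st, T, params$tau2, params$tau_s)
      scale <- drive_scale(st$A, st$PW, params)
      sum(q$w * hazard_rate(scale * q$g, params))
    }
  }, numeric(1))
  tibble(label = stimuli$label, A = stimuli$A, lambda_T = lam,
         psi = 1 - exp(-lam))
}

#' Single-channel form of the hazard-model detection probability
#'
#' For a single channel with expected spike count `lambda_T` the spike
#' probability is `1 - exp(-lambda_T)`; combining `l` independent channels
#' via [population_prob()] gives `1 - exp(-l * lambda_T)` exactly, which is
#' why the population size can be absorbed into the lumped rate `lambdaL`.
#'
#' @param lambda_T Single-channel expected spike count (vectorised,
#'   `>= 0`).
#' @param l Number of independent channels (`>= 1`).
#' @return Population detection probability `1 - exp(-l * lambda_T)`.
#' @export
#' @examples
#' hm_population_prob(0.1, 3)
#' population_prob(1 - exp(-0.1), 3) # identical
hm_population_prob <- function(lambda_T, l = 1) {
  if (any(lambda_T < 0)) abort("lambda_T must be >= 0")
  if (any(l < 1)) abort("l must be >= 1")
  1 - exp(-l * lambda_T)
}

# Graded Gauss-Legendre panel quadrature over [0, T] for one stimulus.
# Panel boundaries cluster behind each pulse onset (the integrand rises on
# the synaptic time scale tau_s and decays on tau2); between clusters the
# integrand is smooth and wide panels suffice. Returns node times, weights
# and the unit-drive PSP shape g at the nodes, so that for any amplitude
# lambda_T ~= sum(w * hazard_rate(scale * g)).
hm_quad <- function(stim, T, tau2, tau_s) {
  gl <- gl_nodes()
  onsets <- stim_onsets(stim)
  offs <- c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 128, 256, 384)
  brk <- c(0, T, as.vector(outer(offs, onsets, "+")))
  brk <- sort(unique(pmin(pmax(brk, 0), T)))
  a <- brk[-length(brk)]
  b <- brk[-1]
  keep <- (b - a) > 1e-12
  a <- a[keep]; b <- b[keep]
  width <- b - a
  nodes <- rep(a, each = length(gl$x)) + as.vector(outer(gl$x, width))
  wts <- as.vector(outer(gl$w, width))
  list(t = nodes, w = wts, g = psp_shape(nodes, onsets, tau2, tau_s))
}

gl_nodes <- function() {
  if (is.null(the$gl9)) {
    the$gl9 <- pracma::gaussLegendre(9, 0, 1)
  }
  the$gl9
}

#' Analytic psychometric curves of the hazard model
#'
#' Evaluates the hazard-model detection probability over an amplitude grid
#' for each stimulus template. The trial integral of the hazard rate is
#' computed with a fixed graded Gauss-Legendre panel rule whose nodes
#' depend only on the temporal parameters, so the whole amplitude grid is
#' evaluated in one vectorised sweep; this is the same rule the fitting
#' routines optimise over.
#'
#' @param stimuli Amplitude-free stimulus templates.
#' @param params An [hm_params()] object.
#' @param amplitudes Strictly increasing non-negative amplitude grid (mA).
#' @param T Trial interval in ms.
#' @return An `nd_curve` tibble with the same columns as [ddm_curve()]
#'   (`k`, `n`, `psi_single` and the CI bounds are `NA`: the curve is
#'   analytic, not simulated).
#' @export
#' @examples
#' hm_curve(stim_table1(), preset_params("threshold_hm"),
#'          amplitudes = seq(0, 2, by = 0.1))
hm_curve <- function(stimuli, params, amplitudes = seq(0, 2, by = 0.01),
                     T = 500) {
  stopifnot(inherits(params, "hm_params"))
  stimuli <- validate_stimuli(stimuli)
  if (any(diff(amplitudes) <= 0) || any(amplitudes < 0)) {
    abort("amplitudes must be a strictly increasing non-negative grid")
  }
  out <- vector("list", nrow(stimuli))
  for (i in seq_len(nrow(stimuli))) {
    st <- stimuli[i, ]
    q <- hm_quad(st, T, params$tau2, params$tau_s)
    scales <- drive_scale(amplitudes, st$PW, params)
    lam <- hm_lambda_T_matrix(scales, q, params)
    out[[i]] <- tibble(
      model = "HM", label = st$label, NoP = st$NoP, IPI = st$IPI, PW = st$PW,
      A = amplitudes, k = NA_integer_, n = NA_integer_,
      psi_single = NA_real_, psi = 1 - exp(-lam),
      ci_lo = NA_real_, ci_hi = NA_real_
    )
  }
  new_nd_curve(dplyr::bind_rows(out), params = params, level = NA_real_)
}

# vectorised lambda_T over a drive-scale vector for one quadrature rule
hm_lambda_T_matrix <- function(scales, q, params) {
  X <- outer(scales, q$g)
  as.vector(plogis((X - params$alphaL) / params$sigmaL) %*% q$w) * params$lambdaL
}
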