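#' Lumped drift-diffusion model parameters
#'
#' The six lumped parameters of the stochastic drift-diffusion model (DDM):
#' peripheral activation threshold `alpha1` (mA) and fiber time constant
#' `tau1` (ms); central membrane time constant `tau2` (ms), scaled firing
#' threshold `alpha2` (A/s), scaled white-noise strength `sigma` (A/s) and
#' the number of independent signal channels `l`. The synaptic decay
#' constant `tau_s` is fixed at 1.5 ms by default.
#'
#' Units are the package-wide convention: time in ms, current in mA, the
#' lumped postsynaptic variable and `(alpha2, sigma)` in A/s (= mA/ms), so
#' no conversion factors appear anywhere in the dynamics.
#'
#' @param alpha1 Peripheral activation threshold (mA, `> 0`).
#' @param tau1 Afferent-fiber time constant (ms, `> 0`).
#' @param tau2 Secondary-neuron time constant (ms, `> 0`).
#' @param alpha2 Scaled firing threshold (A/s, `> 0`).
#' @param sigma Scaled noise strength (A/s, `> 0`).
#' @param l Number of independent signal channels (positive integer).
#' @param tau_s Synaptic decay constant (ms, `> 0`).
#' @return An object of class `ddm_params`.
#' @export
#' @examples
#' ddm_params(alpha1 = 0.5, tau1 = 0.1, tau2 = 50, alpha2 = 0.02, sigma = 0.05, l = 1)
ddm_params <- function(alpha1, tau1, tau2, alpha2, sigma, l = 1L, tau_s = 1.5) {
  check_pos(alpha1, "alpha1"); check_pos(tau1, "tau1"); check_pos(tau2, "tau2")
  check_pos(alpha2, "alpha2"); check_pos(sigma, "sigma", allow_zero = TRUE)
  check_pos(tau_s, "tau_s")
  if (!(is.numeric(l) && length(l) == 1L && l >= 1 && l == round(l))) {
    abort("l must be a positive integer")
  }
  structure(
    list(alpha1 = alpha1, tau1 = tau1, tau2 = tau2, alpha2 = alpha2,
         sigma = sigma, l = as.integer(l), tau_s = tau_s),
    class = c("ddm_params", "nd_params")
  )
}

#' Lumped hazard model parameters
#'
#' The six lumped parameters of the hazard (escape-noise) model (HM):
#' `alpha1` (mA) and `tau1` (ms) shared with the DDM, `tau2` (ms), the
#' lumped activation threshold `alphaL` (A/s), the lumped slope `sigmaL`
#' (A/s) and the population firing rate `lambdaL` (kHz = 1/ms). The
#' population size never appears separately: it is lumped into `lambdaL`.
#'
#' @inheritParams ddm_params
#' @param alphaL Lumped activation threshold of secondary neurons (A/s).
#' @param sigmaL Lumped slope of the sigmoidal hazard (A/s, `> 0`).
#' @param lambdaL Population firing rate ceiling (kHz, `>= 0`).
#' @return An object of class `hm_params`.
#' @export
#' @examples
#' hm_params(alpha1 = 0.06, tau1 = 0.4, tau2 = 50,
#'           alphaL = 0.006, sigmaL = 0.001, lambdaL = 0.01)
hm_params <- function(alpha1, tau1, tau2, alphaL, sigmaL, lambdaL, tau_s = 1.5) {
  check_pos(alpha1, "alpha1"); check_pos(tau1, "tau1"); check_pos(tau2, "tau2")
  check_pos(alphaL, "alphaL"); check_pos(sigmaL, "sigmaL")
  check_pos(lambdaL, "lambdaL", allow_zero = TRUE); check_pos(tau_s, "tau_s")
  structure(
    list(alpha1 = alpha1, tau1 = tau1, tau2 = tau2, alphaL = alphaL,
         sigmaL = sigmaL, lambdaL = lambdaL, tau_s = tau_s),
    class = c("hm_params", "nd_params")
  )
}

check_pos <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (x > 0 || (allow_zero && x == 0))
  if (!ok) abort(paste0(name, " must be a single ",
                        if (allow_zero) "non-negative" else "positive",
                        " number"))
  invisible(x)
}

#' @export
print.nd_params <- function(x, ...) {
  kind <- if (inherits(x, "ddm_params")) "ddm_params" else "hm_params"
  cat("<", kind, ">\n", sep = "")
  vals <- unlist(x)
  cat(paste0("  ", format(names(vals), width = 8), " ", format(vals)), sep = "\n")
  invisible(x)
}

#' @method tidy nd_params
#' @export
tidy.nd_params <- function(x, ...) {
  tibble(term = names(unlist(x)), estimate = unname(unlist(x)))
}

#' Parameter-space bounds for the Monte Carlo study
#'
#' The uniform sampling box for the DDM parameters used in the Monte Carlo
#' fitting study. `l` is sampled uniformly over the integers in its range.
#' The defaults keep model detection thresholds in the experimentally
#' plausible range.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
#' @examples
#' table3_bounds()
table3_bounds <- function() {
  tibble(
    parameter = c("alpha1", "tau1", "tau2", "alpha2", "sigma", "l"),
    lower = c(0.05, 0.01, 5, 0.01, 0.02, 1),
    upper = c(1.00, 0.50, 200, 0.30, 0.20, 20)
  )
}

#' Named preset parameter sets
#'
#' Parameter sets used throughout the package's examples and studies:
#'
#' * `"comparison_ddm"` — the DDM set whose psychometric curves the hazard
#'   model is fitted to in the model-comparison study
#'   (`alpha1 = 0.5` mA, `tau1 = 0.1` ms, `tau2 = 50` ms, `alpha2 = 0.02`,
#'   `sigma = 0.05` A/s, `l = 1`).
#' * `"threshold_ddm"`, `"threshold_hm"` — the DDM/HM sets whose detection
#'   thresholds match the human-subject observations
#'   (`theta_D = (0.06, 0.4, 50, 0.031, 0.09, 8)`,
#'   `theta_H = (0.06, 0.4, 50, 0.006, 0.001, 0.01)`).
#' * `"demo_hm"` — an illustrative HM set for plotting the noise-free
#'   postsynaptic potential, hazard rate and expected spike count
#'   (`alphaL = 0.01`, `sigmaL = 0.001` A/s, `lambdaL = 0.01` kHz with the
#'   `"comparison_ddm"` shared parameters).
#'
#' @param name One of `"comparison_ddm"`, `"threshold_ddm"`,
#'   `"threshold_hm"`, `"demo_hm"`.
#' @return A `ddm_params` or `hm_params` object.
#' @export
#' @examples
#' preset_params("comparison_ddm")
preset_params <- function(name = c("comparison_ddm", "threshold_ddm",
                                   "threshold_hm", "demo_hm")) {
  name <- match.arg(name)
  switch(name,
    comparison_ddm = ddm_params(0.5, 0.1, 50, 0.02, 0.05, 1L),
    threshold_ddm = ddm_params(0.06, 0.4, 50, 0.031, 0.09, 8L),
    threshold_hm = hm_params(0.06, 0.4, 50, 0.006, 0.001, 0.01),
    demo_hm = hm_params(0.5, 0.1, 50, 0.01, 0.001, 0.01)
  )
}
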