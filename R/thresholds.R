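# linear interpolation at the first upward crossing of `level`
curve_level <- function(A, psi, level) {
  if (psi[1] >= level) return(A[1])
  idx <- which(psi[-1] >= level & psi[-length(psi)] < level)
  if (length(idx) == 0) {
    abort(paste0("curve never reaches the level ", level,
                 " on the amplitude grid"))
  }
  i <- idx[1]
  A[i] + (level - psi[i]) * (A[i + 1] - A[i]) / (psi[i + 1] - psi[i])
}

# hazard-model detection probability at a single amplitude (adaptive)
psi_hm_at <- function(A, template, params, T) {
  st <- template
  st$A <- A
  1 - exp(-expected_spikes(validate_stimuli(st), params, T))
}

#' Does the hazard model admit a detection threshold?
#'
#' The amplitude at half detection probability only exists when spontaneous
#' activity alone stays below 0.5, i.e.
#' `T * lambdaL < ln(2) * (1 + exp(alphaL / sigmaL))`.
#'
#' @param params An [hm_params()] object.
#' @param T Trial interval in ms.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' hm_threshold_exists(preset_params("threshold_hm"), T = 500)
hm_threshold_exists <- function(params, T = 500) {
  stopifnot(inherits(params, "hm_params"))
  T * params$lambdaL < log(2) * (1 + exp(params$alphaL / params$sigmaL))
}

#' Detection thresholds of the hazard model
#'
#' Solves `Psi_H(A50) = 0.5` for each stimulus template by bracketing and
#' root refinement. The psychophysical function is monotone in amplitude,
#' so the threshold is unique whenever it exists; existence is checked
#' first via [hm_threshold_exists()] and a missing threshold (spontaneous
#' activity already above 0.5, or the curve never reaching 0.5 on the
#' search range) raises an error.
#'
#' @param stimuli Amplitude-free stimulus templates.
#' @param params An [hm_params()] object.
#' @param T Trial interval in ms.
#' @param level Target detection probability (default 0.5).
#' @param a_max Initial upper search bracket in mA, expanded geometrically
#'   up to 16x before giving up.
#' @param tol Root tolerance in mA.
#' @return A tibble with columns `label`, `A50`, `psi` (the re-evaluated
#'   detection probability at the root).
#' @export
#' @examples
#' hm_threshold(stim_table1(), preset_params("threshold_hm"))
hm_threshold <- function(stimuli, params, T = 500, level = 0.5, a_max = 10,
                         tol = 1e-9) {
  stopifnot(inherits(params, "hm_params"))
  stimuli <- validate_stimuli(stimuli)
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  if (level == 0.5 && !hm_threshold_exists(params, T)) {
    abort(paste0("no threshold: T * lambdaL = ", T * params$lambdaL,
                 " >= ln(2) * (1 + exp(alphaL/sigmaL)); spontaneous",
                 " activity alone reaches the detection level"))
  }
  res <- lapply(seq_len(nrow(stimuli)), function(i) {
    st <- stimuli[i, ]
    f <- function(A) psi_hm_at(A, st, params, T) - level
    if (f(0) >= 0) {
      abort(paste0("no threshold for combination ", st$label,
                   ": detection probability at A = 0 already >= ", level))
    }
    hi <- a_max
    while (f(hi) < 0 && hi < a_max * 16) hi <- hi * 2
    if (f(hi) < 0) {
      abort(paste0("no threshold for combination ", st$label,
                   ": detection probability stays below ", level,
                   " up to A = ", hi, " mA"))
    }
    root <- uniroot(f, c(0, hi), tol = tol)
    tibble(label = st$label, A50 = root$root,
           psi = psi_hm_at(root$root, st, params, T))
  })
  dplyr::bind_rows(res)
}

#' Detection thresholds from a simulated psychometric curve
#'
#' The drift-diffusion model has no closed-form psychophysical function, so
#' its threshold is read off a simulated curve by linear interpolation at
#' the first upward crossing of the target level. For noisy curves an
#' isotonic-regression pre-smoothing can be enabled.
#'
#' @param curve An `nd_curve` tibble (one or more combinations).
#' @param level Target detection probability (default 0.5).
#' @param smooth Apply isotonic regression to each curve before
#'   interpolating.
#' @return A tibble with columns `label`, `A50`.
#' @export
#' @examples
#' crv <- hm_curve(stim_table1()[1, ], preset_params("threshold_hm"),
#'                 amplitudes = seq(0, 2, 0.02))
#' ddm_threshold(crv)
ddm_threshold <- function(curve, level = 0.5, smooth = FALSE) {
  res <- lapply(unique(curve$label), function(lb) {
    d <- curve[curve$label == lb, ]
    psi <- d$psi
    if (smooth) psi <- isoreg(d$A, psi)$yf
    tibble(label = lb, A50 = curve_level(d$A, psi, level))
  })
  dplyr::bind_rows(res)
}

#' Two-pulse detection threshold in the independent-pulse limit
#'
#' For widely separated pulses each pulse is detected independently, so the
#' two-pulse threshold converges to the amplitude where the single-pulse
#' detection probability equals `1 - sqrt(2)/2`
#' (then `1 - (sqrt(2)/2)^2 = 0.5` for the pair). For the hazard model the
#' single-pulse curve is evaluated analytically on the single-pulse
#' observation window `T`; the limit is exact when the two-pulse trial uses
#' a window of `2 * T` (each pulse owns half of it), which is how the
#' companion sweeps are set up. For the drift-diffusion model pass the
#' simulated single-pulse curve instead of `params`.
#'
#' @param stim_single A one-row amplitude-free single-pulse template
#'   (hazard-model route).
#' @param params An [hm_params()] object (hazard-model route).
#' @param T Single-pulse observation window in ms.
#' @param curve A simulated single-pulse `nd_curve` (drift-diffusion
#'   route); when given, `stim_single`/`params` are ignored.
#' @param smooth Isotonic pre-smoothing for the curve route.
#' @return The asymptotic threshold `A_2_50` in mA.
#' @export
#' @examples
#' two_pulse_asymptote(stim_table1()[1, ], preset_params("threshold_hm"),
#'                     T = 500)
two_pulse_asymptote <- function(stim_single = NULL, params = NULL, T = 500,
                                curve = NULL, smooth = FALSE) {
  level <- 1 - sqrt(2) / 2
  if (!is.null(curve)) {
    if (length(unique(curve$label)) != 1L || any(curve$NoP != 1L)) {
      abort("`curve` must hold a single single-pulse combination")
    }
    return(ddm_threshold(curve, level = level, smooth = smooth)$A50)
  }
  stopifnot(inherits(params, "hm_params"))
  stim_single <- validate_stimuli(stim_single)
  if (nrow(stim_single) != 1L || stim_single$NoP != 1L) {
    abort("stim_single must be one single-pulse template")
  }
  hm_threshold(stim_single, params, T = T, level = level)$A50
}

#' Two-pulse threshold as a function of the inter-pulse interval
#'
#' Sweeps the hazard-model detection threshold of a double pulse across an
#' IPI grid. With the threshold-study parameters the curve is non-monotone:
#' temporal summation of the postsynaptic potential gives an interior
#' minimising IPI, after which the threshold climbs towards the
#' independent-pulse asymptote ([two_pulse_asymptote()]).
#'
#' @param params An [hm_params()] object.
#' @param ipi Strictly positive IPI grid in ms.
#' @param PW Pulse width in ms.
#' @param T Two-pulse trial interval in ms; defaults to
#'   `2 * (max(ipi) + 100)` so that every swept stimulus fits and the
#'   large-IPI limit matches the asymptote computed on a window of `T / 2`.
#' @return A tibble with columns `IPI`, `A50`.
#' @export
#' @examples
#' threshold_vs_ipi(preset_params("threshold_hm"), ipi = c(5, 20, 80),
#'                  T = 400)
threshold_vs_ipi <- function(params, ipi, PW = 0.42, T = NULL) {
  if (any(ipi <= 0)) abort("ipi values must be > 0")
  T <- T %||% (2 * (max(ipi) + 100))
  res <- lapply(ipi, function(x) {
    st <- pulse_train(A = NA_real_, NoP = 2L, IPI = x, PW = PW,
                      label = as.character(x))
    tibble(IPI = x, A50 = hm_threshold(st, params, T = T)$A50)
  })
  dplyr::bind_rows(res)
}

#' Detection probability versus inter-pulse interval at fixed amplitude
#'
#' Fixes the amplitude of a double pulse and sweeps the detection
#' probability across an IPI grid, for either model. Near-coincident pulses
#' summate temporally; widely separated pulses fall back to probability
#' summation, producing a non-monotone profile with an interior maximum for
#' the threshold-study parameter sets.
#'
#' @param A Amplitude in mA.
#' @param params [hm_params()] (for `model = "hm"`) or [ddm_params()] (for
#'   `model = "ddm"`).
#' @param ipi Strictly positive IPI grid in ms.
#' @param PW Pulse width in ms.
#' @param T Trial interval in ms; defaults as in [threshold_vs_ipi()].
#' @param model `"hm"` or `"ddm"`.
#' @param config A [trial_config()] for the drift-diffusion route (its `T`
#'   is overridden by `T`).
#' @return A tibble with columns `IPI`, `psi`.
#' @export
#' @examples
#' prob_vs_ipi(0.35, preset_params("threshold_hm"), ipi = c(5, 25, 100),
#'             T = 400)
prob_vs_ipi <- function(A, params, ipi, PW = 0.42, T = NULL,
                        model = c("hm", "ddm"), config = trial_config()) {
  model <- match.arg(model)
  if (any(ipi <= 0)) abort("ipi values must be > 0")
  if (!(is.numeric(A) && length(A) == 1L && A >= 0)) abort("A must be a single amplitude >= 0")
  T <- T %||% (2 * (max(ipi) + 100))
  res <- lapply(seq_along(ipi), function(i) {
    st <- pulse_train(A = A, NoP = 2L, IPI = ipi[i], PW = PW,
                      label = as.character(ipi[i]))
    psi <- if (model == "hm") {
      stopifnot(inherits(params, "hm_params"))
      psi_hm_at(A, st, params, T)
    } else {
      stopifnot(inherits(params, "ddm_params"))
      cfg <- trial_config(T = T, dt = config$dt, N = config$N,
                          seed = config$seed)
      shape <- synaptic_drive_grid(st, cfg$T, cfg$dt, params$tau_s)
      k <- ddm_crossings(shape, A, PW, params, cfg, stream = i * 1000L)
      population_prob(k / cfg$N, params$l)
    }
    tibble(IPI = ipi[i], psi = psi)
  })
  dplyr::bind_rows(res)
}
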