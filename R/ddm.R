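# Unit synaptic drive (EPSC shape) on the Euler grid t = 0, dt, ..., (M-1)dt:
# (1/tau_s) sum_k exp(-(t - o_k)/tau_s) H(t - o_k). The full lumped EPSC is
# this shape times the recruited drive [f_A - alpha1]_+.
synaptic_drive_grid <- function(stim, T, dt, tau_s) {
  M <- as.integer(round(T / dt))
  tt <- (seq_len(M) - 1) * dt
  shape <- numeric(M)
  for (o in stim_onsets(stim)) {
    on <- tt >= o - 1e-12
    shape[on] <- shape[on] + exp(-(tt[on] - o) / tau_s) / tau_s
  }
  shape
}

# recruited drive scalar for one stimulus row at amplitude A
drive_scale <- function(A, PW, params) {
  recruitment(fiber_activation(A, PW, params$tau1), params$alpha1)
}

#' Simulate an ensemble of drift-diffusion paths
#'
#' Runs `N` Euler-Maruyama realizations of the lumped secondary-neuron SDE
#' `tau2 dx = (-x + Ip(t)) dt + sigma dW`, `x(0) = 0`, with fixed timestep
#' `dt` on `[0, T]`, where `Ip(t)` is the recruited synaptic drive of the
#' pulse train. A realization spikes when `x` reaches the scaled firing
#' threshold `alpha2` anywhere on the grid. With the default `T = 500` ms
#' and `dt = 0.01` ms the full path matrix for `N = 200` holds 10^7 values;
#' use `thin` to subsample the stored grid (spike flags and path maxima are
#' always computed at full resolution).
#'
#' @param stim A one-row stimulus tibble with a finite amplitude `A`.
#' @param params A [ddm_params()] object.
#' @param config A [trial_config()]; its `seed` fixes the realization.
#' @param thin Store every `thin`-th grid point of each path.
#' @param stream Integer substream index (advanced use; distinct streams
#'   give independent ensembles under the same root seed).
#' @return An object of class `ddm_paths`: a list with the stored time grid
#'   `time`, the `N x length(time)` path matrix `x`, the per-realization
#'   spike flags `crossed`, full-resolution maxima `xmax`, and the inputs.
#' @export
#' @examples
#' stim <- pulse_train(A = 1, NoP = 2, IPI = 50, PW = 0.42)
#' cfg <- trial_config(T = 200, N = 20, seed = 7)
#' ens <- ddm_simulate(stim, preset_params("comparison_ddm"), cfg, thin = 100)
#' mean(ens$crossed)
ddm_simulate <- function(stim, params, config = trial_config(), thin = 1L,
                         stream = 1L) {
  stopifnot(inherits(params, "ddm_params"), inherits(config, "trial_config"))
  stim <- validate_stimuli(stim)
  if (nrow(stim) != 1L) abort("ddm_simulate() takes a single stimulus row")
  if (is.na(stim$A)) abort("stimulus amplitude A must be set")
  if (config$dt > stim$PW) abort("dt must not exceed the pulse width PW")
  check_stimulus_fits(stim, config$T)

  shape <- synaptic_drive_grid(stim, config$T, config$dt, params$tau_s)
  scale <- drive_scale(stim$A, stim$PW, params)
  res <- cpp_ddm_ensemble(shape, scale, params$tau2, params$sigma,
                          params$alpha2, config$dt, config$N,
                          config$seed, as.integer(stream),
                          return_paths = TRUE, thin = as.integer(thin))
  keep <- seq(0L, length(shape), by = as.integer(thin))
  structure(
    list(time = keep * config$dt, x = res$paths, crossed = res$crossed,
         xmax = res$xmax, stim = stim, params = params, config = config),
    class = "ddm_paths"
  )
}

#' @export
print.ddm_paths <- function(x, ...) {
  cat("<ddm_paths>", nrow(x$x), "realizations,", length(x$time),
      "stored grid points, spike fraction", mean(x$crossed), "\n")
  invisible(x)
}

#' @method tidy ddm_paths
#' @export
tidy.ddm_paths <- function(x, ...) {
  n <- nrow(x$x)
  m <- length(x$time)
  vals <- as.vector(x$x)
  flags <- rep(as.logical(x$crossed), times = m)
  tibble(
    realization = rep(seq_len(n), times = m),
    time = rep(x$time, each = n),
    x = vals,
    crossed = flags
  )
}

#' Population detection probability from a single-channel probability
#'
#' With `l` signal channels receiving identical input but independent
#' noise, the probability that at least one channel spikes is
#' `1 - (1 - psi_single)^l`. The combination is exact under the
#' independence assumption, so the package never simulates the `l` channels
#' separately.
#'
#' @param psi_single Single-channel detection probability in `[0, 1]`
#'   (vectorised).
#' @param l Number of independent channels (`>= 1`).
#' @return Population detection probability in `[0, 1]`.
#' @export
#' @examples
#' population_prob(0.5, 2)
population_prob <- function(psi_single, l) {
  if (any(psi_single < 0 | psi_single > 1)) abort("psi_single must be in [0, 1]")
  if (any(l < 1)) abort("l must be >= 1")
  1 - (1 - psi_single)^l
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact binomial interval for `k` successes in
#' `n` trials: lower bound 0 when `k = 0`, upper bound 1 when `k = n`.
#'
#' @param k Number of successes (vectorised, `0 <= k <= n`).
#' @param n Number of trials.
#' @param level Confidence level in `(0, 1)`.
#' @return A tibble with columns `lower` and `upper`.
#' @export
#' @examples
#' clopper_pearson(100, 200)
clopper_pearson <- function(k, n, level = 0.95) {
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1)) {
    abort("level must be in (0, 1)")
  }
  if (any(k < 0 | k > n | k != round(k) | n < 1)) {
    abort("need 0 <= k <= n with integer k and n >= 1")
  }
  a <- (1 - level) / 2
  lower <- ifelse(k == 0, 0, qbeta(a, k, n - k + 1))
  upper <- ifelse(k == n, 1, qbeta(1 - a, k + 1, n - k))
  tibble(lower = lower, upper = upper)
}

# single-channel spike count for one (stimulus, amplitude) cell
ddm_crossings <- function(shape, A, PW, params, config, stream) {
  scale <- drive_scale(A, PW, params)
  res <- cpp_ddm_ensemble(shape, scale, params$tau2, params$sigma,
                          params$alpha2, config$dt, config$N,
                          config$seed, as.integer(stream),
                          return_paths = FALSE, thin = 1L)
  sum(res$crossed)
}

#' Detection probabilities of the drift-diffusion model
#'
#' Estimates the single-channel spike probability as the fraction of `N`
#' Euler-Maruyama realizations that reach the firing threshold, and the
#' population detection probability via [population_prob()]. Amplitudes are
#' taken from the `A` column of `stimuli`.
#'
#' @param stimuli A stimulus tibble with amplitudes set.
#' @param params A [ddm_params()] object.
#' @param config A [trial_config()].
#' @param level Confidence level for the exact binomial interval.
#' @return A tibble with one row per stimulus: `label`, `A`, `k`, `n`,
#'   `psi_single`, `psi`, `ci_lo`, `ci_hi` (interval on `psi`).
#' @export
#' @examples
#' stim <- pulse_train(A = 1, NoP = 1, PW = 0.42)
#' ddm_detect_prob(stim, preset_params("comparison_ddm"),
#'                 trial_config(T = 200, N = 50, seed = 3))
ddm_detect_prob <- function(stimuli, params, config = trial_config(),
                            level = 0.95) {
  stopifnot(inherits(params, "ddm_params"), inherits(config, "trial_config"))
  stimuli <- validate_stimuli(stimuli)
  if (any(is.na(stimuli$A))) abort("all stimulus amplitudes must be set")
  check_stimulus_fits(stimuli, config$T)
  k <- integer(nrow(stimuli))
  for (i in seq_len(nrow(stimuli))) {
    shape <- synaptic_drive_grid(stimuli[i, ], config$T, config$dt, params$tau_s)
    k[i] <- ddm_crossings(shape, stimuli$A[i], stimuli$PW[i], params, config,
                          stream = i * 100000L)
  }
  psi_single <- k / config$N
  ci <- clopper_pearson(k, config$N, level)
  tibble(
    label = stimuli$label, A = stimuli$A, k = k, n = config$N,
    psi_single = psi_single, psi = population_prob(psi_single, params$l),
    ci_lo = population_prob(ci$lower, params$l),
    ci_hi = population_prob(ci$upper, params$l)
  )
}

#' Monte Carlo psychometric curves of the drift-diffusion model
#'
#' Simulates the detection probability of each stimulus template over a
#' grid of amplitudes (default 0 to 2 mA in steps of 0.01, i.e. 201
#' points). Each (combination, amplitude) cell uses an independent RNG
#' substream derived from `config$seed`, so curves are reproducible and
#' order-independent. Below the recruitment kink
#' `A < alpha1 / (1 - exp(-PW/tau1))` the synaptic drive is identically
#' zero; `share_subthreshold = TRUE` reuses a single zero-drive ensemble
#' for all such cells. That saves the flat left tail of every curve but
#' leaves the spontaneous-detection level estimated from one ensemble
#' instead of many independent ones, which inflates the variance of
#' fitted baseline-sensitive parameters (notably the population rate), so
#' the default keeps every cell independent.
#'
#' @param stimuli Amplitude-free stimulus templates (the `A` column is
#'   ignored), e.g. [stim_table2()].
#' @param params A [ddm_params()] object.
#' @param config A [trial_config()].
#' @param amplitudes Strictly increasing non-negative amplitude grid (mA).
#' @param level Confidence level for the Clopper-Pearson intervals.
#' @param share_subthreshold Reuse one zero-drive ensemble for all cells
#'   with zero recruited drive.
#' @return A `psychometric curve` tibble of class `nd_curve` with columns
#'   `model`, `label`, `NoP`, `IPI`, `PW`, `A`, `k`, `n`, `psi_single`,
#'   `psi`, `ci_lo`, `ci_hi`; the generating `params` and `config` are kept
#'   as attributes.
#' @export
#' @examples
#' crv <- ddm_curve(stim_table1()[1, ], preset_params("comparison_ddm"),
#'                  trial_config(T = 300, N = 50, seed = 11),
#'                  amplitudes = seq(0, 2, by = 0.25))
#' crv
ddm_curve <- function(stimuli, params, config = trial_config(),
                      amplitudes = seq(0, 2, by = 0.01), level = 0.95,
                      share_subthreshold = FALSE) {
  stopifnot(inherits(params, "ddm_params"), inherits(config, "trial_config"))
  stimuli <- validate_stimuli(stimuli)
  check_stimulus_fits(stimuli, config$T)
  if (any(diff(amplitudes) <= 0) || any(amplitudes < 0)) {
    abort("amplitudes must be a strictly increasing non-negative grid")
  }
  if (config$dt > min(stimuli$PW)) abort("dt must not exceed the pulse width PW")

  n_amp <- length(amplitudes)
  shared_k <- NA_integer_
  out <- vector("list", nrow(stimuli))
  for (i in seq_len(nrow(stimuli))) {
    st <- stimuli[i, ]
    shape <- synaptic_drive_grid(st, config$T, config$dt, params$tau_s)
    scales <- drive_scale(amplitudes, st$PW, params)
    k <- integer(n_amp)
    for (j in seq_len(n_amp)) {
      if (share_subthreshold && scales[j] == 0) {
        if (is.na(shared_k)) {
          shared_k <- ddm_crossings(shape, 0, st$PW, params, config, stream = 0L)
        }
        k[j] <- shared_k
      } else {
        k[j] <- ddm_crossings(shape, amplitudes[j], st$PW, params, config,
                              stream = i * 100000L + j)
      }
    }
    psi_single <- k / config$N
    ci <- clopper_pearson(k, config$N, level)
    out[[i]] <- tibble(
      model = "DDM", label = st$label, NoP = st$NoP, IPI = st$IPI, PW = st$PW,
      A = amplitudes, k = k, n = config$N, psi_single = psi_single,
      psi = population_prob(psi_single, params$l),
      ci_lo = population_prob(ci$lower, params$l),
      ci_hi = population_prob(ci$upper, params$l)
    )
  }
  new_nd_curve(dplyr::bind_rows(out), params = params, config = config,
               level = level)
}

new_nd_curve <- function(df, params = NULL, config = NULL, level = NA_real_) {
  structure(df, class = c("nd_curve", class(tibble())),
            params = params, config = config, level = level)
}
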