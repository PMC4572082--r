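#' Construct square-wave pulse-train stimuli
#'
#' An electrocutaneous stimulus is a cathodic square-wave pulse train
#' described by four parameters: the current amplitude `A` (mA, magnitude),
#' the number of pulses `NoP`, the onset-to-onset inter-pulse interval `IPI`
#' (ms) and the pulse width `PW` (ms). Pulse onsets fall at
#' `t = k * IPI`, `k = 0, ..., NoP - 1`. For a single pulse the IPI is
#' undefined and stored as `NA`.
#'
#' @param A Amplitude in mA (magnitude of the cathodic pulse, `>= 0`).
#'   `NA` marks an amplitude-free template, e.g. for psychometric curves.
#' @param NoP Number of pulses (positive integer).
#' @param IPI Inter-pulse interval in ms; required (and `> 0`) when
#'   `NoP >= 2`, ignored otherwise.
#' @param PW Pulse width in ms (`> 0`).
#' @param label Optional character label per stimulus; defaults to row
#'   numbers.
#' @return A tibble with columns `label`, `A`, `NoP`, `IPI`, `PW`, one row
#'   per stimulus.
#' @export
#' @examples
#' pulse_train(A = 0.5, NoP = 2, IPI = 10, PW = 0.42)
#' pulse_train(A = NA, NoP = 1, PW = 0.84, label = "single-wide")
pulse_train <- function(A, NoP, IPI = NA_real_, PW, label = NULL) {
  out <- tibble(
    A = as.numeric(A), NoP = as.integer(NoP),
    IPI = as.numeric(IPI), PW = as.numeric(PW)
  )
  out$label <- if (is.null(label)) as.character(seq_len(nrow(out))) else as.character(label)
  out <- out[, c("label", "A", "NoP", "IPI", "PW")]
  validate_stimuli(out)
}

#' @rdname pulse_train
#' @param stimuli A stimulus tibble as returned by [pulse_train()].
#' @export
validate_stimuli <- function(stimuli) {
  req <- c("A", "NoP", "IPI", "PW")
  missing_cols <- setdiff(req, names(stimuli))
  if (length(missing_cols) > 0) {
    abort(paste0("stimulus table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  with(stimuli, {
    if (any(!is.na(A) & A < 0)) abort("amplitude A must be >= 0")
    if (any(is.na(PW) | PW <= 0)) abort("pulse width PW must be > 0")
    if (any(is.na(NoP) | NoP < 1)) abort("NoP must be a positive integer")
    multi <- NoP >= 2
    if (any(multi & (is.na(IPI) | IPI <= 0))) {
      abort("IPI must be given and > 0 when NoP >= 2")
    }
  })
  # IPI is undefined for a single pulse; store it as absent
  stimuli$IPI[stimuli$NoP < 2] <- NA_real_
  stimuli
}

#' The four temporal-parameter combinations of the threshold experiment
#'
#' Amplitude-free templates for the four stimulus combinations used when
#' relating model thresholds to the human-subject data: a narrow single
#' pulse, a wide single pulse, and two double pulses at short and long IPI.
#'
#' @return A tibble of four amplitude-free pulse-train templates with labels
#'   `"1"`-`"4"` and `(NoP, IPI, PW)` equal to `(1, -, 0.42)`,
#'   `(1, -, 0.84)`, `(2, 10, 0.42)` and `(2, 50, 0.42)`.
#' @export
#' @examples
#' stim_table1()
stim_table1 <- function() {
  pulse_train(
    A = NA_real_,
    NoP = c(1L, 1L, 2L, 2L),
    IPI = c(NA, NA, 10, 50),
    PW = c(0.42, 0.84, 0.42, 0.42),
    label = as.character(1:4)
  )
}

#' The eight temporal-parameter combinations of the model-comparison study
#'
#' Amplitude-free templates A-H used when fitting the hazard model to
#' drift-diffusion psychometric curves: three single pulses with PW 0.21,
#' 0.42 and 0.84 ms, and five double pulses (PW 0.42 ms) with IPI 10, 20,
#' 50, 100 and 150 ms.
#'
#' @return A tibble of eight amplitude-free pulse-train templates labelled
#'   `"A"`-`"H"`.
#' @export
#' @examples
#' stim_table2()
stim_table2 <- function() {
  pulse_train(
    A = NA_real_,
    NoP = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
    IPI = c(NA, NA, NA, 10, 20, 50, 100, 150),
    PW = c(0.21, 0.42, 0.84, rep(0.42, 5)),
    label = LETTERS[1:8]
  )
}

#' Set the amplitude of stimulus templates
#'
#' @param stimuli A stimulus tibble.
#' @param A Amplitude in mA (length 1 or `nrow(stimuli)`).
#' @return The stimulus tibble with amplitudes filled in.
#' @export
set_amplitude <- function(stimuli, A) {
  stimuli$A <- as.numeric(A)
  validate_stimuli(stimuli)
}

#' Trial and integration configuration
#'
#' Holds the trial interval, the Euler-Maruyama timestep, the ensemble size
#' for drift-diffusion simulations, and the root RNG seed. Defaults follow
#' the study conditions: a 500 ms trial, a 0.01 ms fixed timestep and
#' N = 200 realizations per probability estimate.
#'
#' @param T Trial interval in ms.
#' @param dt Integration timestep in ms.
#' @param N Number of realizations per detection-probability estimate.
#' @param seed Integer root RNG seed.
#' @return An object of class `trial_config`.
#' @export
#' @examples
#' trial_config()
#' trial_config(T = 1000, N = 1000, seed = 42)
trial_config <- function(T = 500, dt = 0.01, N = 200, seed = 1L) {
  stopifnot(is.numeric(T), length(T) == 1L, is.numeric(dt), length(dt) == 1L)
  if (!(T > 0)) abort("trial interval T must be > 0")
  if (!(dt > 0)) abort("timestep dt must be > 0")
  if (!(is.numeric(N) && length(N) == 1L && N >= 1)) abort("N must be >= 1")
  structure(
    list(T = as.numeric(T), dt = as.numeric(dt), N = as.integer(N),
         seed = as.integer(seed)),
    class = "trial_config"
  )
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config> T =", x$T, "ms, dt =", x$dt, "ms, N =", x$N,
      "realizations, seed =", x$seed, "\n")
  invisible(x)
}

# pulse onset times (ms) for one stimulus row
stim_onsets <- function(stim) {
  NoP <- stim$NoP[[1]]
  if (NoP < 2) return(0)
  (0:(NoP - 1)) * stim$IPI[[1]]
}

# check that every stimulus fits inside the trial window
check_stimulus_fits <- function(stimuli, T) {
  len <- (stimuli$NoP - 1) * ifelse(is.na(stimuli$IPI), 0, stimuli$IPI) + stimuli$PW
  bad <- len >= T
  if (any(bad)) {
    abort(paste0(
      "stimulus (label ", paste(stimuli$label[bad], collapse = ", "),
      ") does not fit inside the trial interval T = ", T, " ms"
    ))
  }
  invisible(TRUE)
}
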