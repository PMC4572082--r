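#' Load a study configuration from YAML or JSON
#'
#' Reads a configuration file describing stimuli, the trial/integration
#' settings, model parameters and the amplitude grid, applies the package
#' defaults (`T = 500` ms, `dt = 0.01` ms, `N = 200`, `tau_s = 1.5` ms,
#' grid 0 to 2 mA in steps of 0.01), and validates every block. Recognised
#' top-level keys:
#'
#' * `stimuli`: `"table1"`, `"table2"`, or a list of blocks with fields
#'   `NoP`, `PW` and optionally `A`, `IPI`, `label`.
#' * `trial`: fields `T`, `dt`, `N`, `seed`.
#' * `ddm`: fields `alpha1`, `tau1`, `tau2`, `alpha2`, `sigma`, `l`,
#'   optional `tau_s`.
#' * `hm`: fields `alpha1`, `tau1`, `tau2`, `alphaL`, `sigmaL`, `lambdaL`,
#'   optional `tau_s`.
#' * `grid`: fields `from`, `to`, `by` (amplitudes in mA).
#'
#' Units follow the package convention (ms, mA, A/s, kHz).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `nd_config` with elements `stimuli` (tibble),
#'   `trial` ([trial_config()]), `ddm`, `hm` (parameter objects or `NULL`)
#'   and `amplitudes`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("stimuli", "trial", "ddm", "hm", "grid")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }

  stimuli <- parse_stimuli_block(raw$stimuli)
  trial <- parse_trial_block(raw$trial)
  ddm <- if (!is.null(raw$ddm)) parse_params_block(raw$ddm, "ddm") else NULL
  hm <- if (!is.null(raw$hm)) parse_params_block(raw$hm, "hm") else NULL
  amplitudes <- parse_grid_block(raw$grid)

  structure(list(stimuli = stimuli, trial = trial, ddm = ddm, hm = hm,
                 amplitudes = amplitudes),
            class = "nd_config")
}

parse_stimuli_block <- function(block) {
  if (is.null(block)) abort("config field missing: stimuli")
  if (is.character(block) && length(block) == 1L) {
    return(switch(block,
                  table1 = stim_table1(),
                  table2 = stim_table2(),
                  abort(paste0("stimuli: unknown preset '", block,
                               "' (use 'table1' or 'table2')"))))
  }
  rows <- lapply(seq_along(block), function(i) {
    s <- block[[i]]
    for (f in c("NoP", "PW")) {
      if (is.null(s[[f]])) {
        abort(paste0("config field missing: stimuli[", i, "].", f))
      }
    }
    pulse_train(
      A = s$A %||% NA_real_, NoP = s$NoP, IPI = s$IPI %||% NA_real_,
      PW = s$PW, label = s$label %||% as.character(i)
    )
  })
  dplyr::bind_rows(rows)
}

parse_trial_block <- function(block) {
  block <- block %||% list()
  extra <- setdiff(names(block), c("T", "dt", "N", "seed"))
  if (length(extra) > 0) {
    abort(paste0("unknown trial field(s): ", paste(extra, collapse = ", ")))
  }
  trial_config(T = block$T %||% 500, dt = block$dt %||% 0.01,
               N = block$N %||% 200, seed = block$seed %||% 1L)
}

parse_params_block <- function(block, kind) {
  need <- if (kind == "ddm") {
    c("alpha1", "tau1", "tau2", "alpha2", "sigma", "l")
  } else {
    c("alpha1", "tau1", "tau2", "alphaL", "sigmaL", "lambdaL")
  }
  for (f in need) {
    if (is.null(block[[f]])) abort(paste0("config field missing: ", kind, ".", f))
  }
  extra <- setdiff(names(block), c(need, "tau_s"))
  if (length(extra) > 0) {
    abort(paste0("unknown ", kind, " field(s): ", paste(extra, collapse = ", ")))
  }
  args <- c(block[need], list(tau_s = block$tau_s %||% 1.5))
  do.call(if (kind == "ddm") ddm_params else hm_params, args)
}

parse_grid_block <- function(block) {
  block <- block %||% list()
  extra <- setdiff(names(block), c("from", "to", "by"))
  if (length(extra) > 0) {
    abort(paste0("unknown grid field(s): ", paste(extra, collapse = ", ")))
  }
  seq(block$from %||% 0, block$to %||% 2, by = block$by %||% 0.01)
}

#' Write a configuration back to YAML
#'
#' Inverse of [load_config()]; preset stimulus tables round-trip unchanged.
#'
#' @param config An `nd_config` list (or a list with the same elements).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stim <- lapply(seq_len(nrow(config$stimuli)), function(i) {
    s <- as.list(config$stimuli[i, ])
    s <- s[!vapply(s, is.na, logical(1))]
    s$NoP <- as.integer(s$NoP)
    s
  })
  out <- list(
    stimuli = stim,
    trial = list(T = config$trial$T, dt = config$trial$dt,
                 N = config$trial$N, seed = config$trial$seed)
  )
  if (!is.null(config$ddm)) out$ddm <- unclass(config$ddm)
  if (!is.null(config$hm)) out$hm <- unclass(config$hm)
  amps <- config$amplitudes
  if (!is.null(amps)) {
    out$grid <- list(from = min(amps), to = max(amps),
                     by = if (length(amps) > 1) amps[2] - amps[1] else 1)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write tabular results with full precision
#'
#' CSV writers for psychometric curves, threshold tables and Monte Carlo
#' study tables. Columns are written in a fixed order at full double
#' precision, so a fixed-seed run reproduces the file byte for byte.
#'
#' @param x The result object (an `nd_curve` tibble, a thresholds tibble,
#'   or an `mc_study`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  cols <- c("model", "label", "NoP", "IPI", "PW", "A", "k", "n",
            "psi_single", "psi", "ci_lo", "ci_hi")
  readr::write_csv(as_tibble(x)[, intersect(cols, names(x))], path)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          model = "c", label = "c", NoP = "i", k = "i",
                          n = "i", .default = "d"))
  new_nd_curve(df)
}

#' @rdname write_curve_csv
#' @export
write_thresholds_csv <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
write_study_csv <- function(x, path) {
  df <- if (inherits(x, "mc_study")) x$samples else as_tibble(x)
  readr::write_csv(df, path)
  invisible(path)
}

#' Write a run manifest next to an output file
#'
#' Records the command, the fully resolved configuration, the root seed,
#' the package version and the output paths, so that a fixed-seed run can
#' be replayed bit-identically from the manifest alone.
#'
#' @param path Manifest path (conventionally `<output>.manifest.json`).
#' @param command Command or function name that produced the outputs.
#' @param config The resolved configuration (any list; parameter objects
#'   are flattened).
#' @param seed Root seed of the run.
#' @param outputs Character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, outputs) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  manifest <- list(
    command = command,
    config = strip(config),
    seed = seed,
    package = "nocidetect",
    version = as.character(utils::packageVersion("nocidetect")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
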