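#' Full parameterization of a synthetic plate
#'
#' Bundles the plate layout with the per-electrode generative parameters.
#' Every electrode starts from the shared defaults; `overrides` may
#' replace any component for a whole well (name `"A1"`) or a single
#' electrode (name `"A1_E2"`). `amplitude_cv` adds log-normal
#' electrode-to-electrode coupling-amplitude variability, emulating the
#' variable cell-electrode coupling seen on real plates.
#'
#' @param n_wells Number of wells (24, 48 and 96 use the standard row and
#'   column layouts).
#' @param electrodes_per_well Electrodes per well.
#' @param sampling_rate_hz Sampling rate (Hz), default 12500.
#' @param duration_s Recording duration (s).
#' @param start_time_s Absolute start time (s) of the recording.
#' @param shape,schedule,coupling,eads,noise,restitution Default
#'   per-electrode parameters ([ap_shape()], [beat_schedule()],
#'   [coupling_params()], [ead_injection()], [noise_params()],
#'   [restitution_map()] or `NULL`).
#' @param amplitude_cv Coefficient of variation (fraction) of the
#'   per-electrode amplitude jitter (0 disables it).
#' @param overrides Named list of component replacements, see above; each
#'   entry is itself a named list with any of the component names
#'   `shape`, `schedule`, `coupling`, `eads`, `noise`, `restitution`.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_wells = 24, electrodes_per_well = 2,
                              sampling_rate_hz = 12500, duration_s = 30,
                              start_time_s = 0,
                              shape = ap_shape(),
                              schedule = beat_schedule(),
                              coupling = coupling_params(),
                              eads = ead_injection(),
                              noise = noise_params(),
                              restitution = NULL,
                              amplitude_cv = 0,
                              overrides = list()) {
  stopifnot(n_wells >= 1, electrodes_per_well >= 1, sampling_rate_hz > 0,
            duration_s > 0, amplitude_cv >= 0)
  structure(list(n_wells = n_wells,
                 electrodes_per_well = electrodes_per_well,
                 sampling_rate_hz = sampling_rate_hz,
                 duration_s = duration_s, start_time_s = start_time_s,
                 shape = shape, schedule = schedule, coupling = coupling,
                 eads = eads, noise = noise, restitution = restitution,
                 amplitude_cv = amplitude_cv, overrides = overrides),
            class = "sim_config")
}

#' Standard well labels for a plate format
#' @param n_wells Number of wells.
#' @return Character vector like `c("A1", "A2", ...)`.
#' @export
well_labels <- function(n_wells) {
  n_cols <- switch(as.character(n_wells),
                   "24" = 6L, "48" = 8L, "96" = 12L,
                   min(n_wells, 6L))
  n_rows <- ceiling(n_wells / n_cols)
  labs <- as.vector(t(outer(LETTERS[seq_len(n_rows)], seq_len(n_cols),
                            paste0)))
  labs[seq_len(n_wells)]
}

#' Synthesize a whole plate with ground truth
#'
#' Generates one voltage trace per electrode under the configuration and
#' returns the recording together with a per-beat ground-truth table.
#' The result is bit-identical for identical configuration and seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed for all randomness.
#' @return List with `recording` (an [mea_recording()]) and `truth`, a
#'   data frame with columns `well`, `electrode`, `class`, plus the
#'   per-beat columns of [synthesize_electrode_trace()].
#' @export
synthesize_plate <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  wells <- well_labels(config$n_wells)
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  ids <- character(0)
  traces <- list()
  truth <- list()
  for (w in wells) {
    for (e in seq_len(config$electrodes_per_well)) {
      id <- sprintf("W%s_E%d", w, e)
      par <- list(shape = config$shape, schedule = config$schedule,
                  coupling = config$coupling, eads = config$eads,
                  noise = config$noise, restitution = config$restitution)
      for (key in c(w, paste0(w, "_E", e))) {
        ov <- config$overrides[[key]]
        if (!is.null(ov)) par[names(ov)] <- ov
      }
      if (config$amplitude_cv > 0) {
        sdl <- sqrt(log(1 + config$amplitude_cv^2))
        par$coupling$amplitude_uV <- par$coupling$amplitude_uV *
          stats::rlnorm(1, -sdl^2 / 2, sdl)
      }
      res <- synthesize_electrode_trace(
        par$shape, par$schedule, par$coupling, par$eads, par$noise,
        par$restitution, sampling_rate_hz = fs,
        duration_s = config$duration_s,
        start_time_s = config$start_time_s)
      traces[[id]] <- res$trace
      if (nrow(res$beats) > 0) {
        truth[[id]] <- data.frame(well = w, electrode = e,
                                  class = par$coupling$mode, res$beats)
      }
      ids <- c(ids, id)
    }
  }
  if (anyDuplicated(ids)) stop("duplicate electrode IDs")
  mat <- do.call(cbind, traces)
  colnames(mat) <- ids
  rec <- mea_recording(mat, fs, config$start_time_s)
  truth_df <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
              else data.frame()
  list(recording = rec, truth = truth_df)
}

# ---- config serialization (YAML) ------------------------------------------

plain <- function(x) {
  if (is.null(x)) return(NULL)
  out <- unclass(x)
  lapply(out, function(el) if (is.list(el)) plain(el) else el)
}

#' Write / read a simulation configuration as YAML
#'
#' Field names in the file mirror the constructor arguments exactly.
#'
#' @param config A [simulation_config()].
#' @param path YAML file path.
#' @export
write_simulation_config <- function(config, path) {
  doc <- plain(config)
  doc$overrides <- lapply(config$overrides, function(ov) lapply(ov, plain))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

rebuild_component <- function(name, val) {
  if (is.null(val)) return(NULL)
  ctor <- switch(name, shape = ap_shape, schedule = beat_schedule,
                 coupling = coupling_params, eads = ead_injection,
                 noise = noise_params, restitution = restitution_map)
  do.call(ctor, val)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  doc <- yaml::read_yaml(path)
  comps <- c("shape", "schedule", "coupling", "eads", "noise", "restitution")
  args <- doc[setdiff(names(doc), c(comps, "overrides"))]
  for (cn in comps) args[[cn]] <- rebuild_component(cn, doc[[cn]])
  args$overrides <- lapply(doc$overrides, function(ov) {
    stats::setNames(lapply(names(ov), function(cn)
      rebuild_component(cn, ov[[cn]])), names(ov))
  })
  do.call(simulation_config, args)
}
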