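#' Multiwell MEA recording container
#'
#' Holds equal-length voltage traces (uV) for a set of electrodes sampled
#' at a common rate. Electrode IDs follow the grammar
#' `W<row><col>_E<n>` (regular expression `^W([A-H])(\\d+)_E(\\d+)$`),
#' e.g. `WA1_E3` for electrode 3 of well A1.
#'
#' @param data Numeric matrix, samples x electrodes, with electrode IDs as
#'   column names.
#' @param sampling_rate_hz Sampling rate (Hz, > 0).
#' @param start_time_s Absolute start time of the recording (s).
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(data, sampling_rate_hz, start_time_s = 0) {
  stopifnot(is.matrix(data), is.numeric(data), sampling_rate_hz > 0)
  if (is.null(colnames(data))) stop("electrode IDs (column names) required")
  if (anyDuplicated(colnames(data))) stop("duplicate electrode IDs")
  bad <- !grepl("^W[A-H][0-9]+_E[0-9]+$", colnames(data))
  if (any(bad)) {
    stop("malformed electrode IDs: ",
         paste(colnames(data)[bad], collapse = ", "))
  }
  structure(list(data = data, sampling_rate_hz = sampling_rate_hz,
                 start_time_s = start_time_s),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("mea_recording: %d electrodes x %d samples at %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$sampling_rate_hz,
              nrow(x$data) / x$sampling_rate_hz))
  invisible(x)
}

#' Wells present in a recording
#' @param recording An [mea_recording()].
#' @return Character vector of well labels (e.g. `"A1"`), in column order.
#' @export
recording_wells <- function(recording) {
  unique(sub("^W([A-H][0-9]+)_E[0-9]+$", "\\1", colnames(recording$data)))
}

#' Electrode traces of one well
#' @param recording An [mea_recording()].
#' @param well Well label, e.g. `"A1"`.
#' @return Matrix of traces (samples x electrodes) for that well, ordered
#'   by electrode index.
#' @export
well_traces <- function(recording, well) {
  ids <- colnames(recording$data)
  sel <- ids[sub("^W([A-H][0-9]+)_E[0-9]+$", "\\1", ids) == well]
  if (length(sel) == 0) stop("no electrodes mapped to well ", well)
  idx <- as.integer(sub("^W[A-H][0-9]+_E([0-9]+)$", "\\1", sel))
  recording$data[, sel[order(idx)], drop = FALSE]
}

#' Write / read a recording as CSV plus JSON sidecar
#'
#' The CSV holds a `time_s` column plus one uV column per electrode; the
#' JSON sidecar (same basename, extension `.json`) holds the sampling
#' rate, start time and units. The round trip is lossless to the printed
#' precision (15 significant digits).
#'
#' @param recording An [mea_recording()].
#' @param path CSV file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an [mea_recording()].
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "mea_recording"))
  t_s <- recording$start_time_s +
    (seq_len(nrow(recording$data)) - 1) / recording$sampling_rate_hz
  df <- data.frame(time_s = t_s, recording$data, check.names = FALSE)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(sampling_rate_hz = recording$sampling_rate_hz,
               start_time_s = recording$start_time_s,
               units = "uV",
               electrodes = colnames(recording$data))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' @rdname write_recording
#' @param path CSV file path written by [write_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path)) {
    stop("missing sampling-rate metadata sidecar: ", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate_hz)) {
    stop("sidecar lacks sampling_rate_hz")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("no electrodes in ", path)
  elec <- setdiff(names(df), "time_s")
  for (cn in elec) {
    if (!is.numeric(df[[cn]])) {
      stop("non-numeric samples in column ", cn)
    }
    if (anyNA(df[[cn]])) {
      stop("column ", cn, " has missing samples (ragged columns?)")
    }
  }
  mea_recording(as.matrix(df[elec]),
                sampling_rate_hz = meta$sampling_rate_hz,
                start_time_s = meta$start_time_s %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plate map
#'
#' @param df Data frame with columns `well`, `group` and optionally
#'   `compound`, `dose`, `dose_units`.
#' @return A validated `plate_map` data frame.
#' @export
plate_map <- function(df) {
  stopifnot(is.data.frame(df), all(c("well", "group") %in% names(df)))
  if (anyDuplicated(df$well)) stop("duplicate wells in plate map")
  if (any(is.na(df$group) | df$group == "")) stop("empty group labels")
  for (cn in c("compound", "dose", "dose_units")) {
    if (!cn %in% names(df)) df[[cn]] <- NA
  }
  class(df) <- c("plate_map", "data.frame")
  df
}

#' @rdname plate_map
#' @param path CSV or JSON file holding the plate map.
#' @export
read_plate_map <- function(path) {
  df <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
  plate_map(df)
}

#' @rdname plate_map
#' @param pm A `plate_map`.
#' @export
write_plate_map <- function(pm, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(pm), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(pm, path, row.names = FALSE)
  }
  invisible(path)
}

#' Check a recording against a plate map
#'
#' @param recording An [mea_recording()].
#' @param pm A [plate_map()].
#' @return Character vector of issues; empty when consistent. Reports
#'   electrodes whose well is absent from the plate map, mapped wells with
#'   no electrodes, and duplicate electrode IDs.
#' @export
validate_plate <- function(recording, pm) {
  issues <- character(0)
  ids <- colnames(recording$data)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    issues <- c(issues, paste0("duplicate electrode ID: ", unique(dup)))
  }
  wells <- sub("^W([A-H][0-9]+)_E[0-9]+$", "\\1", ids)
  orphan <- setdiff(unique(wells), pm$well)
  if (length(orphan)) {
    issues <- c(issues, paste0("electrodes in unmapped well: ", orphan))
  }
  empty <- setdiff(pm$well, unique(wells))
  if (length(empty)) {
    issues <- c(issues, paste0("mapped well has no electrodes: ", empty))
  }
  issues
}
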