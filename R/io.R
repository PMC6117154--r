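#' Write and read tracking, stimulus and trace files
#'
#' Tracking CSV: columns `fly_id`, `t_s`, `x_mm` (long format, one row per
#' frame). Stimulus CSV: `stim_id`, `onset_s`, `light_on` (0/1).
#' Electrophysiology traces: two-column CSV (`t_s`, `value`) plus a JSON
#' sidecar (`<file>.json`) holding the sampling rate and light annotations.
#'
#' @param traces List of `activity_trace` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tracking_csv <- function(traces, path) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  parts <- lapply(traces, function(tr) {
    data.frame(fly_id = tr$fly_id, t_s = trace_times(tr), x_mm = tr$x)
  })
  write.csv(do.call(rbind, parts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracking_csv
#' @param tube_length Tube length (mm) used to validate positions.
#' @return For the reader, a list of `activity_trace` objects.
#' @export
read_tracking_csv <- function(path, tube_length = 65) {
  df <- read.csv(path)
  lapply(split(df, df$fly_id), as_activity_trace, tube_length = tube_length)
}

#' @rdname write_tracking_csv
#' @param schedule A `stimulus_schedule`.
#' @export
write_stimulus_csv <- function(schedule, path) {
  out <- data.frame(stim_id = schedule$stim_id, onset_s = schedule$onset_s,
                    light_on = as.integer(schedule$light_on))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracking_csv
#' @export
read_stimulus_csv <- function(path) {
  df <- read.csv(path)
  df$light_on <- df$light_on == 1
  class(df) <- c("stimulus_schedule", "data.frame")
  df
}

#' @rdname write_tracking_csv
#' @param windows Data frame of light intervals (`start_s`, `end_s`) with an
#'   optional `mode` column.
#' @param mode Light mode label used when `windows` lacks a `mode` column.
#' @export
write_light_csv <- function(windows, path, mode = "constant") {
  out <- data.frame(start_s = windows$start_s, end_s = windows$end_s,
                    mode = windows$mode %||% mode)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracking_csv
#' @export
read_light_csv <- function(path) {
  read.csv(path)
}

#' @rdname write_tracking_csv
#' @param trace A `vm_trace` or `lfp_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  sig <- if (inherits(trace, "vm_trace")) trace$vm else trace$signal
  df <- data.frame(t_s = (seq_along(sig) - 1) / trace$fs, value = sig)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = trace$fs,
         kind = if (inherits(trace, "vm_trace")) "vm" else "lfp",
         light = trace$light),
    paste0(path, ".json"), auto_unbox = TRUE, digits = 12)
  invisible(path)
}

#' @rdname write_tracking_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  light <- meta$light
  if (!is.null(light$pulse_onsets)) {
    light$pulse_onsets <- as.numeric(light$pulse_onsets)
  }
  if (identical(meta$kind, "vm")) {
    structure(list(fs = meta$fs, vm = df$value, light = light),
              class = "vm_trace")
  } else {
    lfp_trace(df$value, meta$fs, light = light)
  }
}
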