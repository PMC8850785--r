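# Plain-text trial I/O: CSV signals with JSON metadata sidecars, and
# per-frame CSV grids for pressure stacks.

#' Write a trial series to CSV with a JSON sidecar
#'
#' The signal goes to `<path>.csv` (columns `time_s`, force column(s),
#' `event_flag`) and the metadata (sampling rate, load type, event index,
#' masses, ground truth when simulated) to `<path>.json`.
#'
#' @param trial A `trial_series`.
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  write.csv(trial$data, paste0(path, ".csv"), row.names = FALSE)
  meta <- c(list(sampling_rate_hz = trial$sampling_rate,
                 load_type = trial$load_type,
                 event_index = trial$event_index),
            trial$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial series written by [write_trial_csv()]
#'
#' @param path Path without extension.
#' @return A `trial_series`.
#' @export
read_trial_csv <- function(path) {
  data <- tibble::as_tibble(utils::read.csv(paste0(path, ".csv")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ev <- meta$event_index
  new_trial_series(data, meta$sampling_rate_hz, meta$load_type,
                   event_index = if (is.null(ev) || is.na(ev)) NA else ev,
                   meta = meta[setdiff(names(meta),
                                       c("sampling_rate_hz", "load_type",
                                         "event_index"))])
}

#' Write a pressure stack as per-frame CSV grids
#'
#' Each frame becomes `frame_<k>.csv` in `dir`; the geometry (grid size,
#' sensel area, coverage mask, view labels) and timestamps go to
#' `geometry.json`.
#'
#' @param stack A `pressure_stack`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pressure_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(stack$frames)) {
    utils::write.table(stack$frames[[k]],
                       file.path(dir, sprintf("frame_%04d.csv", k)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  g <- stack$geometry
  jsonlite::write_json(
    list(n_side = g$n_side, sensel_area_cm2 = g$sensel_area_cm2,
         coverage = g$coverage, view = g$view, projection = g$projection,
         times = stack$times, quantized = stack$quantized),
    file.path(dir, "geometry.json"), pretty = TRUE, digits = NA)
  invisible(dir)
}
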