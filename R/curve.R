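#' ROI time-intensity curve
#'
#' The central container of the package: one ROI's mean fluorescence
#' intensity as a function of time, together with the dye injection time.
#' Times are seconds on a uniform grid of spacing `1/frame_rate`; intensities
#' are arbitrary units (raw camera counts after ROI averaging, or simulated
#' values).
#'
#' @param times numeric vector (s), strictly increasing, uniformly spaced.
#' @param intensities numeric vector (a.u.), same length as `times`.
#' @param injection_time dye injection time (s), within `range(times)`.
#' @param roi_name ROI label (e.g. `"D1"`, `"D2"`, `"D3"`).
#' @param state_label hemodynamic state label (e.g. `"T0"`..`"T3"`).
#' @param bit_depth optional camera bit depth; enables saturation QC.
#' @return an object of class `time_intensity_curve` (a list with the above
#'   fields plus `frame_rate`).
#' @export
time_intensity_curve <- function(times, intensities, injection_time,
                                 roi_name = "ROI", state_label = "T0",
                                 bit_depth = NULL) {
  if (length(times) != length(intensities))
    pq_stop("times and intensities must have equal length", "pq_invalid_input")
  if (length(times) < 2L)
    pq_stop("a curve needs at least 2 frames", "pq_invalid_input")
  dt <- diff(times)
  if (any(dt <= 0))
    pq_stop("times must be strictly increasing", "pq_invalid_input")
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    pq_stop("times must be uniformly spaced", "pq_invalid_input")
  if (injection_time < times[1L] || injection_time > times[length(times)])
    pq_stop("injection_time must lie within the recorded time range",
            "pq_invalid_input")
  structure(list(
    times = as.numeric(times), intensities = as.numeric(intensities),
    injection_time = as.numeric(injection_time), roi_name = roi_name,
    state_label = state_label, frame_rate = 1 / mean(dt),
    bit_depth = bit_depth
  ), class = "time_intensity_curve")
}

#' @export
print.time_intensity_curve <- function(x, ...) {
  cat(sprintf(
    "<time_intensity_curve> %s/%s: %d frames @ %.4g fps, t = [%.3g, %.3g] s, injection %.3g s\n",
    x$roi_name, x$state_label, length(x$times), x$frame_rate,
    x$times[1L], x$times[length(x$times)], x$injection_time))
  invisible(x)
}

#' Read / write a time-intensity curve as CSV
#'
#' The on-disk schema is two columns, `time_s` and `intensity`, with a header
#' row, UTF-8 encoding and `.` as decimal separator. Writing uses 17
#' significant digits so the round trip is lossless at double precision.
#' Curve metadata (injection time, ROI name, state, frame rate) travels in a
#' sidecar JSON file `<path>.json`, written automatically and read back when
#' present; `injection_time` passed to `read_curve_csv()` overrides it.
#'
#' @param path CSV file path.
#' @param injection_time injection time (s); required unless present in the
#'   sidecar metadata.
#' @param roi_name,state_label,bit_depth metadata overrides (optional).
#' @param curve a [time_intensity_curve()].
#' @return `read_curve_csv()` returns a [time_intensity_curve()];
#'   `write_curve_csv()` returns `path` invisibly.
#' @export
read_curve_csv <- function(path, injection_time = NULL, roi_name = NULL,
                           state_label = NULL, bit_depth = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L)
    pq_stop(sprintf("%s: need a header and at least one data row", path),
            "pq_parse_error")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "time_s" || header[2L] != "intensity")
    pq_stop(sprintf("%s: expected header 'time_s,intensity', got '%s'",
                    path, lines[1L]), "pq_parse_error")
  n <- length(lines) - 1L
  times <- numeric(n); intens <- numeric(n)
  for (i in seq_len(n)) {
    cells <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]]
    if (length(cells) != 2L)
      pq_stop(sprintf("%s: row %d has %d cells, expected 2", path, i + 1L,
                      length(cells)), "pq_parse_error")
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals))
      pq_stop(sprintf("%s: non-numeric cell in row %d ('%s')", path, i + 1L,
                      lines[i + 1L]), "pq_parse_error")
    times[i] <- vals[1L]; intens[i] <- vals[2L]
  }
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  injection_time <- injection_time %||% meta$injection_time
  if (is.null(injection_time))
    pq_stop(sprintf("%s: injection_time not given and no sidecar metadata", path),
            "pq_config_error")
  time_intensity_curve(
    times, intens, injection_time,
    roi_name = roi_name %||% meta$roi_name %||% "ROI",
    state_label = state_label %||% meta$state_label %||% "T0",
    bit_depth = bit_depth %||% meta$bit_depth
  )
}

#' @rdname read_curve_csv
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "time_intensity_curve"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("time_s,intensity", con)
  writeLines(paste(fmt_num(curve$times), fmt_num(curve$intensities), sep = ","), con)
  meta <- list(injection_time = curve$injection_time, roi_name = curve$roi_name,
               state_label = curve$state_label, frame_rate = curve$frame_rate)
  if (!is.null(curve$bit_depth)) meta$bit_depth <- curve$bit_depth
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
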