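#' Analysis parameters for curve metrics
#'
#' One config block for every tunable of the metric pipeline; operations
#' take their defaults from here and each result records the parameter set
#' it was produced with.
#'
#' @param baseline_window pre-injection baseline window length (s).
#' @param smooth_half_width moving-average half width (frames); 0 disables
#'   smoothing.
#' @param onset_k onset threshold in baseline SDs.
#' @param onset_m consecutive frames required above threshold.
#' @param sd_floor lower bound on the baseline SD used in the threshold
#'   (a.u.); guards noiseless (sd = 0) curves.
#' @param onset_backtrack after the threshold crossing, walk back to the
#'   first frame above the baseline mean; recovers the true arrival on
#'   clean data (see the methods vignette).
#' @param slope_window_s slope regression window (s); converted to an odd
#'   frame count at the curve's frame rate (13 frames at 25 fps).
#' @param slope_window_frames explicit frame count override (`>= 2`);
#'   2 reduces to adjacent-frame finite differences.
#' @param analysis_window post-injection analysis window (s).
#' @param saturation_limit flag fraction: `saturated` is set when more than
#'   this fraction of analysis-window frames sit at the bit-depth ceiling.
#' @return an object of class `fi_params`.
#' @export
fi_params <- function(baseline_window = 5, smooth_half_width = 2,
                      onset_k = 3, onset_m = 5, sd_floor = 0.5,
                      onset_backtrack = TRUE, slope_window_s = 0.5,
                      slope_window_frames = NULL, analysis_window = 60,
                      saturation_limit = 0.01) {
  stopifnot(baseline_window > 0, smooth_half_width >= 0, onset_k > 0,
            onset_m >= 1, sd_floor >= 0, analysis_window > 0)
  if (!is.null(slope_window_frames) && slope_window_frames < 2)
    pq_stop("slope_window_frames must be >= 2", "pq_invalid_input")
  structure(list(
    baseline_window = baseline_window, smooth_half_width = smooth_half_width,
    onset_k = onset_k, onset_m = onset_m, sd_floor = sd_floor,
    onset_backtrack = onset_backtrack, slope_window_s = slope_window_s,
    slope_window_frames = slope_window_frames,
    analysis_window = analysis_window, saturation_limit = saturation_limit
  ), class = "fi_params")
}

resolve_slope_window <- function(params, frame_rate) {
  params$slope_window_frames %||%
    max(2L, 2L * floor(params$slope_window_s * frame_rate / 2) + 1L)
}

#' Pre-injection baseline statistics
#'
#' Mean and sample (n-1) standard deviation of the curve over the window
#' `[injection_time - window_length, injection_time)`. If the requested
#' window starts before the recording, or holds fewer than 5 frames, the
#' available pre-injection span is used and the `short_baseline` flag is
#' set. A curve with no pre-injection frames at all is unusable.
#'
#' @param curve a [time_intensity_curve()].
#' @param window_length window length (s).
#' @return list with `mean`, `sd`, `window` (`c(start, end)`), `n`,
#'   `short_baseline`.
#' @export
baseline_statistics <- function(curve, window_length = 5) {
  t0 <- curve$injection_time
  idx <- which(curve$times >= t0 - window_length & curve$times < t0)
  if (!any(curve$times < t0) )
    pq_stop("no pre-injection frames: injection_time is at the first frame",
            "pq_unusable_curve")
  short <- (t0 - window_length < curve$times[1L] - 1e-9) || length(idx) < 5L
  y <- curve$intensities[idx]
  list(mean = mean(y),
       sd = if (length(y) > 1L) stats::sd(y) else 0,
       window = c(max(t0 - window_length, curve$times[1L]), t0),
       n = length(y), short_baseline = short)
}

#' Centered moving-average smoothing
#'
#' Window of `2 * half_width + 1` frames, truncated at the curve ends so
#' that edge frames average over the available span. `half_width = 0` is
#' the identity.
#'
#' @param curve a [time_intensity_curve()].
#' @param half_width half width in frames, >= 0.
#' @return a smoothed [time_intensity_curve()].
#' @export
smooth_curve <- function(curve, half_width = 2) {
  stopifnot(inherits(curve, "time_intensity_curve"), half_width >= 0)
  if (half_width == 0) return(curve)
  y <- curve$intensities
  n <- length(y)
  cs <- c(0, cumsum(y))
  lo <- pmax(seq_len(n) - half_width, 1L)
  hi <- pmin(seq_len(n) + half_width, n)
  out <- curve
  out$intensities <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out
}

#' Detect bolus onset (first signal increase)
#'
#' Onset is the operational form of "first increase of the fluorescence
#' signal": the first post-injection frame whose intensity exceeds
#' `baseline mean + k * max(baseline sd, sd_floor)` for `m` consecutive
#' frames. With `backtrack = TRUE` (default) the detector then walks back
#' from that crossing to the first frame still above the baseline mean,
#' which removes the threshold-crossing delay on clean curves. A curve that
#' never crosses within the analysis window yields a flagged no-onset
#' result, not an error.
#'
#' @param curve a [time_intensity_curve()] (use the raw, unsmoothed curve).
#' @param baseline output of [baseline_statistics()].
#' @param k threshold multiplier, > 0.
#' @param m consecutive frames required, >= 1.
#' @param sd_floor floor on the baseline SD (a.u.).
#' @param analysis_window search window after injection (s).
#' @param backtrack logical, see above.
#' @return list with `onset_time` (NA if not found) and `no_onset` flag.
#' @export
detect_onset <- function(curve, baseline, k = 3, m = 5, sd_floor = 0.5,
                         analysis_window = 60, backtrack = TRUE) {
  stopifnot(k > 0, m >= 1)
  t0 <- curve$injection_time
  idx <- which(curve$times > t0 & curve$times <= t0 + analysis_window)
  if (length(idx) == 0L) return(list(onset_time = NA_real_, no_onset = TRUE))
  thr <- baseline$mean + k * max(baseline$sd, sd_floor)
  above <- curve$intensities[idx] > thr
  r <- rle(above)
  run_ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= m)
  if (length(hit) == 0L) return(list(onset_time = NA_real_, no_onset = TRUE))
  j <- idx[run_ends[hit[1L]] - r$lengths[hit[1L]] + 1L]
  if (backtrack) {
    while (j > idx[1L] && curve$intensities[j - 1L] > baseline$mean) j <- j - 1L
  }
  list(onset_time = curve$times[j], no_onset = FALSE)
}

#' Background-subtracted peak fluorescence intensity (BSFI)
#'
#' Peak intensity during the first passage of the dye minus the
#' pre-injection baseline mean. "First passage" is operationalized as the
#' bounded post-injection analysis window (default 60 s) with the global
#' maximum therein; a window reaching past the recording is truncated (the
#' `window_truncated` flag is set). Ties between equal maxima resolve to
#' the earliest time.
#'
#' @param curve a [time_intensity_curve()] (typically smoothed).
#' @param baseline output of [baseline_statistics()].
#' @param analysis_window window length after injection (s).
#' @return list with `bsfi`, `peak_time`, `peak_value`, `window_truncated`.
#' @export
compute_bsfi <- function(curve, baseline, analysis_window = 60) {
  t0 <- curve$injection_time
  t_end <- curve$times[length(curve$times)]
  truncated <- t0 + analysis_window > t_end + 1e-9
  idx <- which(curve$times > t0 & curve$times <= t0 + analysis_window)
  if (length(idx) == 0L)
    pq_stop("no frames in the analysis window", "pq_unusable_curve")
  i <- idx[which.max(curve$intensities[idx])]
  list(bsfi = curve$intensities[i] - baseline$mean,
       peak_time = curve$times[i], peak_value = curve$intensities[i],
       window_truncated = truncated)
}

#' Maximal rising slope of fluorescence intensity (SFI)
#'
#' The maximum, over every window of `slope_window` consecutive frames
#' fully inside `[onset_time, peak_time]`, of the least-squares slope of
#' intensity versus time in that window (a.u./s). Ties resolve to the
#' earliest window. A rising segment shorter than the window falls back to
#' the full segment's regression slope and sets the `short_rise` flag.
#'
#' @param curve a [time_intensity_curve()] (typically smoothed).
#' @param onset_time,peak_time segment bounds (s).
#' @param slope_window window length in frames, >= 2.
#' @return list with `sfi`, `sfi_window_start` (s), `short_rise`.
#' @export
compute_sfi <- function(curve, onset_time, peak_time, slope_window = 13L) {
  stopifnot(slope_window >= 2)
  seg <- which(curve$times >= onset_time - 1e-9 & curve$times <= peak_time + 1e-9)
  if (length(seg) < 2L)
    return(list(sfi = NA_real_, sfi_window_start = NA_real_, short_rise = TRUE))
  tt <- curve$times[seg]
  yy <- curve$intensities[seg]
  ls_slope <- function(x, y) {
    xc <- x - mean(x)
    sum(xc * y) / sum(xc * xc)
  }
  if (length(seg) < slope_window) {
    return(list(sfi = ls_slope(tt, yy), sfi_window_start = tt[1L],
                short_rise = TRUE))
  }
  w <- as.integer(slope_window)
  dt <- 1 / curve$frame_rate
  offs <- (seq_len(w) - (w + 1) / 2) * dt   # centered, exact for a uniform grid
  denom <- sum(offs * offs)
  emb <- stats::embed(yy, w)                # row j = yy[j+w-1], ..., yy[j]
  slopes <- as.vector(emb %*% rev(offs)) / denom
  j <- which.max(slopes)
  list(sfi = slopes[j], sfi_window_start = tt[j], short_rise = FALSE)
}

#' TTS ratio to the reference ROI
#'
#' `tts / reference tts`; the reference ROI's own ratio is 1. Undefined
#' (NA, with reason) when either onset is missing or the reference TTS is
#' zero.
#'
#' @param result,reference `fi_metrics_result` objects from
#'   [analyze_curve()].
#' @return list with `tts_ratio` (NA when undefined) and `undefined_ratio`.
#' @export
compute_tts_ratio <- function(result, reference) {
  if (is.na(result$tts) || is.na(reference$tts) || reference$tts <= 0)
    return(list(tts_ratio = NA_real_, undefined_ratio = TRUE))
  list(tts_ratio = result$tts / reference$tts, undefined_ratio = FALSE)
}

#' Full per-curve metric extraction
#'
#' Runs the whole chain on one curve: baseline statistics (raw curve),
#' moving-average smoothing, onset detection (raw curve; see the methods
#' vignette for why), BSFI and SFI on the smoothed curve, saturation QC,
#' and -- when a reference is supplied -- the TTS ratio. The returned
#' result carries the full parameter set as provenance.
#'
#' @param curve a [time_intensity_curve()].
#' @param reference optional reference-ROI curve or `fi_metrics_result`.
#' @param params an [fi_params()].
#' @return an object of class `fi_metrics_result`: `roi_name`,
#'   `state_label`, `bsfi`, `sfi`, `tts`, `onset_time`, `peak_time`,
#'   `peak_value`, `tts_ratio`, `baseline`, `flags` (character vector) and
#'   `params`.
#' @examples
#' acq <- acquisition_config(noise_sd = 0, seed = 1)
#' cv <- simulate_curve(roi_perfusion_spec("D3"), 1, acq)
#' res <- analyze_curve(cv)
#' c(res$bsfi, res$sfi, res$tts)
#' @export
analyze_curve <- function(curve, reference = NULL, params = fi_params()) {
  stopifnot(inherits(curve, "time_intensity_curve"), inherits(params, "fi_params"))
  flags <- character(0)
  baseline <- baseline_statistics(curve, params$baseline_window)
  if (baseline$short_baseline) flags <- c(flags, "short_baseline")
  sm <- smooth_curve(curve, params$smooth_half_width)
  onset <- detect_onset(curve, baseline, k = params$onset_k, m = params$onset_m,
                        sd_floor = params$sd_floor,
                        analysis_window = params$analysis_window,
                        backtrack = params$onset_backtrack)
  if (onset$no_onset) flags <- c(flags, "no_onset")
  pk <- compute_bsfi(sm, baseline, params$analysis_window)
  if (pk$window_truncated) flags <- c(flags, "window_truncated")
  sfi <- NA_real_
  if (!onset$no_onset) {
    sl <- compute_sfi(sm, onset$onset_time, pk$peak_time,
                      resolve_slope_window(params, curve$frame_rate))
    if (sl$short_rise) flags <- c(flags, "short_rise")
    sfi <- sl$sfi
  }
  if (!is.null(curve$bit_depth)) {
    win <- which(curve$times > curve$injection_time &
                 curve$times <= curve$injection_time + params$analysis_window)
    sat_frac <- mean(curve$intensities[win] >= 2^curve$bit_depth - 1)
    if (sat_frac > params$saturation_limit) flags <- c(flags, "saturated")
  }
  res <- structure(list(
    roi_name = curve$roi_name, state_label = curve$state_label,
    bsfi = pk$bsfi, sfi = sfi,
    tts = if (onset$no_onset) NA_real_ else onset$onset_time - curve$injection_time,
    onset_time = onset$onset_time, peak_time = pk$peak_time,
    peak_value = pk$peak_value, tts_ratio = NA_real_,
    baseline = baseline, flags = flags, params = params
  ), class = "fi_metrics_result")
  if (!is.null(reference)) {
    ref_res <- if (inherits(reference, "fi_metrics_result")) reference
               else analyze_curve(reference, params = params)
    rat <- compute_tts_ratio(res, ref_res)
    res$tts_ratio <- rat$tts_ratio
    if (rat$undefined_ratio) res$flags <- c(res$flags, "undefined_ratio")
  }
  res
}

#' @export
print.fi_metrics_result <- function(x, ...) {
  cat(sprintf(
    "<fi_metrics_result> %s/%s: BSFI %.4g a.u., SFI %.4g a.u./s, TTS %.4g s%s%s\n",
    x$roi_name, x$state_label, x$bsfi, x$sfi, x$tts,
    if (!is.na(x$tts_ratio)) sprintf(", TTS ratio %.4g", x$tts_ratio) else "",
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Analyze every curve of an experiment
#'
#' Applies [analyze_curve()] to each ROI and state, computing each state's
#' reference ROI first so that TTS ratios can be formed.
#'
#' @param x a `simulated_experiment` or a nested list
#'   `curves[[roi]][[state]]` of [time_intensity_curve()]s.
#' @param reference_roi name of the reference ROI (default `"D3"`).
#' @param params an [fi_params()].
#' @param animal_id optional id column for the tidy table.
#' @return list with `results` (nested list of `fi_metrics_result`) and
#'   `table` (tidy data.frame: animal_id, roi, state, bsfi, sfi, tts,
#'   tts_ratio, onset_time, peak_time, flags).
#' @export
analyze_experiment <- function(x, reference_roi = "D3", params = fi_params(),
                               animal_id = "A1") {
  curves <- if (inherits(x, "simulated_experiment")) x$curves else x
  if (!reference_roi %in% names(curves))
    pq_stop(sprintf("reference ROI '%s' not among curves", reference_roi),
            "pq_config_error")
  states <- names(curves[[reference_roi]])
  results <- lapply(curves, function(z) stats::setNames(vector("list", length(states)), states))
  rows <- list()
  for (st in states) {
    ref <- analyze_curve(curves[[reference_roi]][[st]], params = params)
    ref$tts_ratio <- if (!is.na(ref$tts) && ref$tts > 0) 1 else NA_real_
    results[[reference_roi]][[st]] <- ref
    for (rn in names(curves)) {
      res <- if (rn == reference_roi) ref else
        analyze_curve(curves[[rn]][[st]], reference = ref, params = params)
      results[[rn]][[st]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = animal_id, roi = rn, state = st,
        bsfi = res$bsfi, sfi = res$sfi, tts = res$tts,
        tts_ratio = res$tts_ratio, onset_time = res$onset_time,
        peak_time = res$peak_time,
        flags = paste(res$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  list(results = results, table = do.call(rbind, rows))
}

#' Write a tidy metrics table as CSV
#'
#' Deterministic, locale-independent formatting (17 significant digits), so
#' repeated runs with the same seed are bit-identical.
#'
#' @param table data.frame as produced by [analyze_experiment()].
#' @param path output CSV.
#' @export
write_metrics_csv <- function(table, path) {
  out <- table
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], fmt_num)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(do.call(paste, c(unname(out), sep = ",")), con)
  invisible(path)
}
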