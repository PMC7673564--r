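#' Dynamic image stack
#'
#' A `T x H x W` sequence of nonnegative integer intensities with its frame
#' rate, bit depth and the acquisition time of frame 0. Frame `k` (0-based)
#' is exposed at `origin_timestamp + k / frame_rate`; this mapping is owned
#' by the stack and never recomputed elsewhere.
#'
#' @param frames integer array `T x H x W`, `T >= 2`.
#' @param frame_rate frames per second, > 0.
#' @param bit_depth 8, 12 or 16; all values must be `<= 2^bit_depth - 1`.
#' @param origin_timestamp time of frame 0 (s).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate, bit_depth = 8,
                        origin_timestamp = 0) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    pq_stop("frames must be a T x H x W array", "pq_invalid_input")
  if (dim(frames)[1L] < 2L)
    pq_stop("a frame stack needs at least 2 frames", "pq_invalid_input")
  if (is.null(frame_rate) || !is.numeric(frame_rate) || frame_rate <= 0)
    pq_stop("frame_rate must be a positive number", "pq_config_error")
  if (!bit_depth %in% c(8, 12, 16))
    pq_stop("bit_depth must be 8, 12 or 16", "pq_invalid_input")
  if (min(frames) < 0 || max(frames) > 2^bit_depth - 1)
    pq_stop("pixel values exceed the bit-depth range", "pq_invalid_input")
  structure(list(frames = frames, frame_rate = frame_rate,
                 bit_depth = bit_depth, origin_timestamp = origin_timestamp),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d, %g fps, %d-bit\n",
              d[1L], d[2L], d[3L], x$frame_rate, x$bit_depth))
  invisible(x)
}

frame_times <- function(stack) {
  stack$origin_timestamp + (seq_len(dim(stack$frames)[1L]) - 1L) / stack$frame_rate
}

#' Read / write a frame stack (multi-page TIFF + JSON sidecar)
#'
#' The pixel data live in a baseline grayscale TIFF; acquisition metadata
#' (frame rate, origin timestamp) live in a sidecar JSON `<path>.json`
#' written by `write_frame_stack()`. On reading, the frame rate must come
#' from the sidecar or the `frame_rate` argument (argument wins); a missing
#' frame rate is a configuration error.
#'
#' @param path TIFF file path.
#' @param frame_rate frames per second; overrides the sidecar.
#' @param origin_timestamp time of frame 0 (s); overrides the sidecar.
#' @param stack a [frame_stack()].
#' @return `read_frame_stack()` returns a [frame_stack()];
#'   `write_frame_stack()` returns `path` invisibly.
#' @export
read_frame_stack <- function(path, frame_rate = NULL, origin_timestamp = NULL) {
  tif <- read_tiff_stack(path)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  fr <- frame_rate %||% meta$frame_rate
  if (is.null(fr))
    pq_stop(sprintf("%s: frame rate not given and no sidecar metadata", path),
            "pq_config_error")
  frame_stack(tif$frames, fr, tif$bit_depth,
              origin_timestamp %||% meta$origin_timestamp %||% 0)
}

#' @rdname read_frame_stack
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  bd <- if (stack$bit_depth == 8) 8 else 16  # 12-bit data travels in 16-bit samples
  write_tiff_stack(stack$frames, path, bit_depth = bd)
  jsonlite::write_json(
    list(frame_rate = stack$frame_rate, bit_depth = stack$bit_depth,
         origin_timestamp = stack$origin_timestamp),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render simulated curves into an image stack
#'
#' Builds a synthetic acquisition for one recording: every pixel of an ROI
#' rectangle follows that ROI's time-intensity curve plus iid Gaussian pixel
#' noise; background pixels sit at a constant dim level plus the same noise.
#' Values are clipped and quantized to the acquisition bit depth. Averaging
#' the ROI pixels back ([extract_roi_curve()]) recovers the input curve
#' within `pixel_noise_sd / sqrt(ROI area)` (exactly, when noiseless).
#'
#' @param curves named list of [time_intensity_curve()]s of equal length,
#'   one per ROI (names are the ROI names).
#' @param geometry named list of rectangles `c(row0, col0, row1, col1)`
#'   (0-based, half-open), one per curve, pairwise disjoint.
#' @param canvas `c(H, W)` canvas size in pixels.
#' @param background constant background level (a.u.).
#' @param pixel_noise_sd iid pixel noise SD (a.u.).
#' @param bit_depth quantization depth.
#' @param reference_roi which ROI is flagged as reference in the returned
#'   definitions.
#' @param seed seed of the pixel-noise stream.
#' @return list with `stack` (a [frame_stack()]) and `rois` (list of
#'   [roi_definition()]).
#' @export
simulate_frame_stack <- function(curves, geometry, canvas = c(32, 48),
                                 background = 5, pixel_noise_sd = 0,
                                 bit_depth = 8, reference_roi = "D3",
                                 seed = 1) {
  stopifnot(is.list(curves), length(curves) >= 1L,
            all(names(curves) %in% names(geometry)))
  h <- canvas[1L]; w <- canvas[2L]
  occupancy <- matrix(FALSE, h, w)
  rois <- list()
  for (rn in names(curves)) {
    r <- geometry[[rn]]
    if (r[1L] < 0 || r[2L] < 0 || r[3L] > h || r[4L] > w || r[3L] <= r[1L] || r[4L] <= r[2L])
      pq_stop(sprintf("ROI '%s' rectangle outside the %d x %d canvas", rn, h, w),
              "pq_config_error")
    rows <- (r[1L] + 1L):r[3L]; cols <- (r[2L] + 1L):r[4L]
    if (any(occupancy[rows, cols]))
      pq_stop(sprintf("ROI '%s' overlaps another ROI", rn), "pq_config_error")
    occupancy[rows, cols] <- TRUE
    rois[[rn]] <- roi_definition(rn, rect = r, is_reference = rn == reference_roi)
  }
  n_t <- length(curves[[1L]]$times)
  for (cv in curves) {
    if (length(cv$times) != n_t)
      pq_stop("all curves must have the same number of frames", "pq_invalid_input")
  }
  frames <- array(background, dim = c(n_t, h, w))
  for (rn in names(curves)) {
    r <- geometry[[rn]]
    rows <- (r[1L] + 1L):r[3L]; cols <- (r[2L] + 1L):r[4L]
    frames[, rows, cols] <- curves[[rn]]$intensities  # recycles along T first
  }
  if (pixel_noise_sd > 0) {
    frames <- frames + with_stream(seed, "frame_stack/pixel_noise",
                                   array(rnorm(length(frames), 0, pixel_noise_sd),
                                         dim = dim(frames)))
  }
  ceiling_val <- 2^bit_depth - 1
  frames[] <- round(pmin(pmax(frames, 0), ceiling_val))
  storage.mode(frames) <- "integer"
  cv1 <- curves[[1L]]
  list(stack = frame_stack(frames, cv1$frame_rate, bit_depth,
                           origin_timestamp = cv1$times[1L]),
       rois = rois)
}
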