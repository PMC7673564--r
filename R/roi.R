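#' ROI definition
#'
#' A named spatial region on the image canvas, given either as a rectangle
#' `c(row0, col0, row1, col1)` -- 0-based, half-open, i.e. rows
#' `[row0, row1)` and columns `[col0, col1)` -- or as a logical `H x W`
#' mask. Exactly one ROI in a set is the reference (the arterial radix the
#' TTS ratio is normalized to).
#'
#' @param name ROI label.
#' @param rect integer vector `c(row0, col0, row1, col1)`, 0-based half-open.
#' @param mask logical `H x W` matrix (alternative to `rect`).
#' @param is_reference logical flag.
#' @return an object of class `roi_definition`.
#' @export
roi_definition <- function(name, rect = NULL, mask = NULL, is_reference = FALSE) {
  if (is.null(rect) == is.null(mask))
    pq_stop("give exactly one of rect or mask", "pq_invalid_input")
  if (!is.null(rect)) {
    if (length(rect) != 4L || rect[3L] <= rect[1L] || rect[4L] <= rect[2L] ||
        any(rect[1:2] < 0))
      pq_stop("rect must be c(row0, col0, row1, col1), 0-based half-open, nonempty",
              "pq_invalid_input")
  } else {
    if (!is.logical(mask) || !is.matrix(mask) || !any(mask))
      pq_stop("mask must be a nonempty logical matrix", "pq_invalid_input")
  }
  structure(list(name = name, rect = rect, mask = mask,
                 is_reference = isTRUE(is_reference)),
            class = "roi_definition")
}

roi_mask_for <- function(roi, h, w) {
  if (!is.null(roi$mask)) {
    if (nrow(roi$mask) != h || ncol(roi$mask) != w)
      pq_stop(sprintf("ROI '%s' mask is %d x %d but frames are %d x %d",
                      roi$name, nrow(roi$mask), ncol(roi$mask), h, w),
              "pq_invalid_input")
    return(roi$mask)
  }
  r <- roi$rect
  if (r[3L] > h || r[4L] > w)
    pq_stop(sprintf("ROI '%s' rectangle out of frame bounds", roi$name),
            "pq_invalid_input")
  m <- matrix(FALSE, h, w)
  m[(r[1L] + 1L):r[3L], (r[2L] + 1L):r[4L]] <- TRUE
  m
}

#' Read / write ROI sets as JSON
#'
#' The on-disk form is an array of objects with fields `name`,
#' `rect` (`[row0, col0, row1, col1]`, 0-based half-open) and
#' `is_reference`. Exactly one ROI must be the reference.
#'
#' @param path JSON file path.
#' @param rois list of [roi_definition()] (rectangle-based).
#' @return `read_roi_json()` returns a named list of [roi_definition()].
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rois <- lapply(raw, function(r) {
    roi_definition(r$name, rect = unlist(r$rect),
                   is_reference = isTRUE(r$is_reference))
  })
  names(rois) <- vapply(rois, `[[`, "", "name")
  n_ref <- sum(vapply(rois, `[[`, FALSE, "is_reference"))
  if (n_ref != 1L)
    pq_stop(sprintf("%s: ROI set must have exactly one reference ROI (found %d)",
                    path, n_ref), "pq_invalid_input")
  rois
}

#' @rdname read_roi_json
#' @export
write_roi_json <- function(rois, path) {
  out <- lapply(rois, function(r) {
    if (is.null(r$rect))
      pq_stop("only rectangle ROIs can be serialized to JSON", "pq_invalid_input")
    list(name = r$name, rect = as.integer(r$rect), is_reference = r$is_reference)
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract an ROI time-intensity curve from an image stack
#'
#' The curve value at frame `k` is the arithmetic mean of the masked pixels
#' of frame `k`; times follow the stack's frame clock. Saturated pixels
#' (at the bit-depth ceiling) are included in the mean, and their per-frame
#' fraction is carried on the curve as the `saturation_fraction` attribute
#' for downstream QC.
#'
#' @param stack a [frame_stack()].
#' @param roi a [roi_definition()]; the mask must fit within the frames.
#' @param injection_time dye injection time (s).
#' @param state_label stored in the resulting curve.
#' @return a [time_intensity_curve()].
#' @export
extract_roi_curve <- function(stack, roi, injection_time, state_label = "T0") {
  stopifnot(inherits(stack, "frame_stack"), inherits(roi, "roi_definition"))
  d <- dim(stack$frames)
  mask <- roi_mask_for(roi, d[2L], d[3L])
  idx <- which(mask)  # column-major over H x W, matching the array layout
  fm <- stack$frames
  dim(fm) <- c(d[1L], d[2L] * d[3L])
  px <- fm[, idx, drop = FALSE]
  means <- rowMeans(px)
  ceiling_val <- 2^stack$bit_depth - 1
  sat <- rowMeans(px == ceiling_val)
  curve <- time_intensity_curve(frame_times(stack), means, injection_time,
                                roi_name = roi$name, state_label = state_label,
                                bit_depth = stack$bit_depth)
  attr(curve, "saturation_fraction") <- sat
  curve
}
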