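#' Gamma-variate bolus parameters
#'
#' Parameter set for the gamma-variate first-pass kernel used by the
#' simulator. The kernel is the standard indicator-dilution form
#' \deqn{f(t) = A \, u^{\alpha} e^{\alpha (1 - u)}, \quad
#'       u = (t - t_0) / t_p,}
#' normalized so that the peak equals exactly `amplitude` at
#' `onset_time + time_to_peak`. A delayed, scaled copy of the same kernel
#' models systemic recirculation (the second, smaller bump of a real curve).
#'
#' @param baseline_level pre-arrival intensity (a.u.), >= 0.
#' @param amplitude peak height above baseline (a.u.), >= 0.
#' @param onset_time bolus arrival time at the ROI (s), >= 0.
#' @param time_to_peak onset-to-peak interval (s), > 0.
#' @param shape gamma-variate sharpness `alpha` (dimensionless), > 0.
#' @param recirculation_fraction amplitude fraction of the recirculation bump,
#'   in `[0, 1)`.
#' @param recirculation_delay delay of the recirculation bump after the
#'   primary onset (s).
#' @return an object of class `bolus_params`.
#' @seealso [gamma_variate()]
#' @export
bolus_params <- function(baseline_level = 10, amplitude = 100,
                         onset_time = 14, time_to_peak = 6, shape = 3,
                         recirculation_fraction = 0.15,
                         recirculation_delay = 30) {
  p <- list(
    baseline_level = baseline_level, amplitude = amplitude,
    onset_time = onset_time, time_to_peak = time_to_peak, shape = shape,
    recirculation_fraction = recirculation_fraction,
    recirculation_delay = recirculation_delay
  )
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), TRUE)))
    pq_stop("all bolus parameters must be finite numeric scalars", "pq_invalid_input")
  if (amplitude < 0) pq_stop("amplitude must be >= 0", "pq_invalid_input")
  if (time_to_peak <= 0) pq_stop("time_to_peak must be > 0", "pq_invalid_input")
  if (shape <= 0) pq_stop("shape must be > 0", "pq_invalid_input")
  if (onset_time < 0) pq_stop("onset_time must be >= 0", "pq_invalid_input")
  if (recirculation_fraction < 0 || recirculation_fraction >= 1)
    pq_stop("recirculation_fraction must be in [0, 1)", "pq_invalid_input")
  structure(p, class = "bolus_params")
}

#' Evaluate a gamma-variate bolus curve
#'
#' Evaluates the noiseless time-intensity curve of a first-pass dye bolus on
#' a time grid: `baseline_level` before arrival, and the peak-normalized
#' gamma-variate kernel (plus its recirculation copy) afterwards.
#'
#' @param t numeric vector of times (s), monotone non-decreasing.
#' @param params a [bolus_params()] object.
#' @return numeric vector of intensities (a.u.), same length as `t`.
#' @examples
#' p <- bolus_params(amplitude = 100, baseline_level = 10, onset_time = 14,
#'                   time_to_peak = 6, recirculation_fraction = 0)
#' gamma_variate(14 + 6, p)  # exactly 110 at the peak
#' @export
gamma_variate <- function(t, params) {
  stopifnot(inherits(params, "bolus_params"))
  if (!is.numeric(t) || anyNA(t))
    pq_stop("t must be numeric without NA", "pq_invalid_input")
  if (is.unsorted(t, strictly = FALSE))
    pq_stop("t must be monotone increasing", "pq_invalid_input")
  kern <- function(tt) {
    u <- (tt - params$onset_time) / params$time_to_peak
    out <- numeric(length(tt))
    pos <- u > 0
    out[pos] <- params$amplitude * u[pos]^params$shape *
      exp(params$shape * (1 - u[pos]))
    out
  }
  y <- params$baseline_level + kern(t)
  if (params$recirculation_fraction > 0)
    y <- y + params$recirculation_fraction * kern(t - params$recirculation_delay)
  y
}
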