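#' ROI perfusion specification for the simulator
#'
#' Describes one ROI of the simulated single-vessel gastric-tube arcade:
#' its regional flow relative to the reference ROI at the arterial radix
#' (D3), the extra bolus transit delay along the arcade, and the residual
#' ICG level pooled in the tissue from earlier injections.
#'
#' @param roi_name `"D1"` (fundus), `"D2"` (corpus) or `"D3"` (prepyloric
#'   reference).
#' @param relative_flow regional flow divided by D3 flow, > 0.
#' @param arrival_delay extra transit delay vs D3 (s); must be 0 for D3.
#' @param pooling_offset residual ICG baseline offset (a.u.), >= 0.
#' @return an object of class `roi_perfusion_spec`.
#' @export
roi_perfusion_spec <- function(roi_name, relative_flow = 1,
                               arrival_delay = 0, pooling_offset = 0) {
  if (!roi_name %in% c("D1", "D2", "D3"))
    pq_stop("roi_name must be one of 'D1', 'D2', 'D3'", "pq_invalid_input")
  if (relative_flow <= 0) pq_stop("relative_flow must be > 0", "pq_invalid_input")
  if (arrival_delay < 0) pq_stop("arrival_delay must be >= 0", "pq_invalid_input")
  if (roi_name == "D3" && arrival_delay != 0)
    pq_stop("arrival_delay must be 0 for the reference ROI D3", "pq_invalid_input")
  if (pooling_offset < 0) pq_stop("pooling_offset must be >= 0", "pq_invalid_input")
  structure(list(roi_name = roi_name, relative_flow = relative_flow,
                 arrival_delay = arrival_delay, pooling_offset = pooling_offset),
            class = "roi_perfusion_spec")
}

#' Acquisition configuration
#'
#' Camera and recording settings of the simulated acquisition. Defaults
#' mirror the in-vivo recordings the simulator emulates: 25 frames per
#' second, 8-bit digitization, 120 s recording with the dye injected at
#' 10 s.
#'
#' @param frame_rate frames per second, > 0.
#' @param duration recording length (s).
#' @param injection_time dye injection time (s), in `[0, duration)`.
#' @param bit_depth 8, 12 or 16.
#' @param noise_sd Gaussian intensity noise SD (a.u.), >= 0. Default 2 a.u.
#'   = 2 % of the reference ROI amplitude.
#' @param seed integer seed for the curve noise stream.
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_rate = 25, duration = 120,
                               injection_time = 10, bit_depth = 8,
                               noise_sd = 2, seed = 1) {
  if (frame_rate <= 0) pq_stop("frame_rate must be > 0", "pq_invalid_input")
  if (injection_time < 0 || injection_time >= duration)
    pq_stop("injection_time must satisfy 0 <= injection_time < duration",
            "pq_invalid_input")
  if (!bit_depth %in% c(8, 12, 16))
    pq_stop("bit_depth must be 8, 12 or 16", "pq_invalid_input")
  if (noise_sd < 0) pq_stop("noise_sd must be >= 0", "pq_invalid_input")
  structure(list(frame_rate = frame_rate, duration = duration,
                 injection_time = injection_time, bit_depth = bit_depth,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Simulator defaults: the stated world
#'
#' One place for every default of the synthetic experiment; operations never
#' hard-code these. The defaults encode the emulated experiment: a
#' single-vessel gastric tube with a proximal-to-distal flow gradient
#' (relative flows D3:D2:D1 = 1:0.8:0.6), bolus transit delays growing
#' distally (D2 +1.5 s, D1 +4 s after the 4 s injection-to-D3 systemic lag),
#' four hemodynamic states T0-T3 (baseline, hypotension, normotension,
#' hypertension; flow scales 1, 0.9, 1, 1.2), absolute D3 flow 1.2 ml/min/g,
#' gamma-variate bolus with amplitude 100 a.u., time-to-peak 6 s and shape 3
#' at unit flow, 15 % recirculation delayed 30 s, and 3 a.u. of residual ICG
#' accumulating per repeated injection.
#'
#' @return a named list of simulator defaults.
#' @export
sim_defaults <- function() {
  list(
    baseline_level = 10,        # a.u., pre-dye camera level in tissue
    amplitude_d3 = 100,         # a.u., peak above baseline at relative flow 1
    time_to_peak_d3 = 6,        # s, onset-to-peak at relative flow 1
    shape = 3,                  # gamma-variate alpha
    systemic_lag = 4,           # s, injection -> D3 arrival
    recirculation_fraction = 0.15,
    recirculation_delay = 30,   # s
    base_flow_d3 = 1.2,         # ml/min/g at state scale 1
    pooling_increment = 3,      # a.u. residual ICG added per prior injection
    state_scales = c(T0 = 1, T1 = 0.9, T2 = 1, T3 = 1.2),
    rois = list(
      D1 = roi_perfusion_spec("D1", relative_flow = 0.6, arrival_delay = 4),
      D2 = roi_perfusion_spec("D2", relative_flow = 0.8, arrival_delay = 1.5),
      D3 = roi_perfusion_spec("D3", relative_flow = 1, arrival_delay = 0)
    )
  )
}

#' Simulate one ROI time-intensity curve
#'
#' Maps regional flow to curve shape by the simulator's model: peak
#' amplitude proportional to flow and time-to-peak inversely proportional to
#' flow, both relative to the D3 reference values; bolus arrival at
#' `injection_time + systemic_lag + arrival_delay`; residual ICG added to
#' the baseline. Gaussian noise of SD `acq$noise_sd` is added, then the
#' signal is clipped to `[0, 2^bit_depth - 1]` and quantized to integers
#' (round-half-even), mimicking the frame grabber.
#'
#' @param spec a [roi_perfusion_spec()].
#' @param state_flow_scale dimensionless flow multiplier of the hemodynamic
#'   state, > 0.
#' @param acq an [acquisition_config()].
#' @param defaults simulator defaults, see [sim_defaults()].
#' @param state_label label stored in the curve.
#' @param quantize set `FALSE` to skip clipping/quantization (noise is still
#'   added); used for continuous-kernel validation.
#' @return a [time_intensity_curve()].
#' @export
simulate_curve <- function(spec, state_flow_scale = 1, acq = acquisition_config(),
                           defaults = sim_defaults(), state_label = "T0",
                           quantize = TRUE) {
  stopifnot(inherits(spec, "roi_perfusion_spec"),
            inherits(acq, "acquisition_config"))
  if (state_flow_scale <= 0)
    pq_stop("state_flow_scale must be > 0", "pq_invalid_input")
  flow <- spec$relative_flow * state_flow_scale
  p <- bolus_params(
    baseline_level = defaults$baseline_level + spec$pooling_offset,
    amplitude = defaults$amplitude_d3 * flow,
    onset_time = acq$injection_time + defaults$systemic_lag + spec$arrival_delay,
    time_to_peak = defaults$time_to_peak_d3 / flow,
    shape = defaults$shape,
    recirculation_fraction = defaults$recirculation_fraction,
    recirculation_delay = defaults$recirculation_delay
  )
  n <- round(acq$duration * acq$frame_rate)
  times <- (seq_len(n) - 1L) / acq$frame_rate
  y <- gamma_variate(times, p)
  if (acq$noise_sd > 0) {
    y <- y + with_stream(acq$seed,
                         paste("curve", spec$roi_name, state_label, sep = "/"),
                         rnorm(n, 0, acq$noise_sd))
  }
  if (quantize) {
    ceiling_val <- 2^acq$bit_depth - 1
    y <- round(pmin(pmax(y, 0), ceiling_val))
  }
  time_intensity_curve(times, y, acq$injection_time,
                       roi_name = spec$roi_name, state_label = state_label,
                       bit_depth = if (quantize) acq$bit_depth else NULL)
}

#' Simulate the full gastric-tube experiment for one animal
#'
#' Produces curves for every ROI in every hemodynamic state, plus the
#' ground-truth regional flows in ml/min/g. Residual ICG accumulates
#' monotonically across successive states (one extra `pooling_increment` per
#' prior injection), emulating repeated dye administration.
#'
#' @param acq an [acquisition_config()]; its `seed` drives all noise.
#' @param defaults simulator configuration, see [sim_defaults()].
#' @param flow_multiplier extra flow multiplier (e.g. per-animal variation).
#' @param quantize passed to [simulate_curve()].
#' @return an object of class `simulated_experiment`: list with `curves`
#'   (nested list `curves[[roi]][[state]]`), `true_flows` (data.frame `roi`,
#'   `state`, `flow_ml_min_g`), `seed`, and `params`.
#' @examples
#' ex <- simulate_experiment(acquisition_config(seed = 7))
#' ex$true_flows
#' @export
simulate_experiment <- function(acq = acquisition_config(),
                                defaults = sim_defaults(),
                                flow_multiplier = 1, quantize = TRUE) {
  stopifnot(inherits(acq, "acquisition_config"))
  rois <- defaults$rois
  if (!"D3" %in% names(rois))
    pq_stop("ROI set must include the reference ROI D3", "pq_config_error")
  states <- names(defaults$state_scales)
  curves <- stats::setNames(vector("list", length(rois)), names(rois))
  tf <- expand.grid(roi = names(rois), state = states,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tf$flow_ml_min_g <- NA_real_
  for (rn in names(rois)) curves[[rn]] <- stats::setNames(vector("list", length(states)), states)
  for (si in seq_along(states)) {
    st <- states[si]
    scale <- defaults$state_scales[[si]] * flow_multiplier
    for (rn in names(rois)) {
      spec0 <- rois[[rn]]
      # residual ICG from the si-1 earlier injections
      spec <- roi_perfusion_spec(
        rn, spec0$relative_flow, spec0$arrival_delay,
        spec0$pooling_offset + (si - 1L) * defaults$pooling_increment
      )
      curves[[rn]][[st]] <- simulate_curve(spec, scale, acq, defaults,
                                           state_label = st, quantize = quantize)
      tf$flow_ml_min_g[tf$roi == rn & tf$state == st] <-
        defaults$base_flow_d3 * spec0$relative_flow * scale
    }
  }
  structure(list(curves = curves, true_flows = tf, seed = acq$seed,
                 params = list(acquisition = acq, defaults = defaults,
                               flow_multiplier = flow_multiplier)),
            class = "simulated_experiment")
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat(sprintf("<simulated_experiment> %d ROIs x %d states, seed %d\n",
              length(x$curves), length(x$curves[[1L]]), x$seed))
  invisible(x)
}
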