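# fixtures built in code; no binary files ship with the package

# a default-world noiseless unquantized curve with known truth
make_clean_curve <- function(relative_flow = 1, arrival_delay = 0,
                             acq = acquisition_config(noise_sd = 0, seed = 1)) {
  simulate_curve(roi_perfusion_spec("D3", relative_flow = relative_flow),
                 1, acq, quantize = FALSE)
}

# random unquantized noisy curve + its generating truth, deterministic per seed
make_random_curve <- function(seed, noise_sd = NULL) {
  par <- withr::with_seed(seed, list(
    amplitude = runif(1, 30, 150),
    time_to_peak = runif(1, 2.5, 8),
    shape = runif(1, 2, 5),
    baseline = runif(1, 5, 30),
    noise_sd = if (is.null(noise_sd)) runif(1, 1.5, 3) else noise_sd
  ))
  fr <- 25
  times <- (0:(45 * fr - 1)) / fr
  injection <- 10
  onset <- injection + 4
  p <- bolus_params(baseline_level = par$baseline, amplitude = par$amplitude,
                    onset_time = onset, time_to_peak = par$time_to_peak,
                    shape = par$shape, recirculation_fraction = 0.15,
                    recirculation_delay = 20)
  y <- gamma_variate(times, p)
  if (par$noise_sd > 0)
    y <- y + withr::with_seed(seed + 7L, rnorm(length(y), 0, par$noise_sd))
  list(curve = time_intensity_curve(times, y, injection, "D3", "T0"),
       truth = c(par, list(onset_time = onset, injection = injection)))
}

# independent SFI oracle: exhaustive scan of every eligible window's
# least-squares regression slope (plain lm.fit, no shared code path)
sfi_bruteforce <- function(curve, onset_time, peak_time, w) {
  seg <- which(curve$times >= onset_time - 1e-9 & curve$times <= peak_time + 1e-9)
  tt <- curve$times[seg]; yy <- curve$intensities[seg]
  n <- length(seg)
  if (n < w) {
    fit <- stats::lm.fit(cbind(1, tt), yy)
    return(unname(fit$coefficients[2L]))
  }
  best <- -Inf
  for (j in seq_len(n - w + 1L)) {
    x <- tt[j:(j + w - 1L)]; y <- yy[j:(j + w - 1L)]
    sl <- unname(stats::lm.fit(cbind(1, x), y)$coefficients[2L])
    if (sl > best) best <- sl
  }
  best
}

# tiny tidy metrics table for the stats module
make_metrics_table <- function(n_animals = 3, areas = c("D1", "D2", "D3"),
                               states = c("T0", "T1"), seed = 1,
                               area_effect = rep(1, length(areas)),
                               state_effect = rep(1, length(states)),
                               sdlog = 0.2, base = 20) {
  g <- expand.grid(animal_id = sprintf("A%d", seq_len(n_animals)),
                   roi = areas, state = states,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- base * area_effect[match(g$roi, areas)] *
    state_effect[match(g$state, states)]
  g$value <- withr::with_seed(seed, rlnorm(nrow(g), log(mu), sdlog))
  g$metric <- "m"
  g
}
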