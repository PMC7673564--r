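#' Fluorescent-microsphere flow by the reference-sample method
#'
#' With a constant-rate arterial reference withdrawal `R_w` (mL/min), the
#' flow to a tissue sample is
#' \deqn{Q_s = \frac{F_s}{F_{ref}} \; R_w,}
#' where `F_s` and `F_ref` are the microsphere signals (sphere counts or
#' spectrofluorometric intensities -- the ratio is the same) of the tissue
#' and reference samples in the same color channel. Per-gram flow divides
#' by the sample weight.
#'
#' @param tissue data.frame with columns `sample_id`, `region`, `weight_g`,
#'   `color`, `signal`.
#' @param reference list or one-row data.frame with `color`, `signal`,
#'   `withdrawal_rate_ml_min`.
#' @return data.frame of flow estimates: `sample_id`, `region`, `weight_g`,
#'   `color`, `signal`, `absolute_flow_ml_min`, `per_gram_flow_ml_min_g`.
#' @examples
#' tissue <- data.frame(sample_id = "s1", region = "D3", weight_g = 3.18,
#'                      color = "blue", signal = 2000)
#' ref <- list(color = "blue", signal = 2000, withdrawal_rate_ml_min = 3.18)
#' flow_per_sample(tissue, ref)  # 1.0 ml/min/g
#' @export
flow_per_sample <- function(tissue, reference) {
  req <- c("sample_id", "region", "weight_g", "color", "signal")
  if (!all(req %in% names(tissue)))
    pq_stop(paste("tissue table must have columns:", paste(req, collapse = ", ")),
            "pq_invalid_input")
  reference <- as.list(reference)
  if (is.null(reference$withdrawal_rate_ml_min) || reference$withdrawal_rate_ml_min <= 0)
    pq_stop("reference withdrawal rate must be > 0", "pq_invalid_input")
  if (is.null(reference$signal) || reference$signal <= 0)
    pq_stop("reference signal must be > 0 (undefined flow otherwise)",
            "pq_undefined_flow")
  if (any(tissue$color != reference$color))
    pq_stop(sprintf("color channel mismatch: tissue has %s, reference is '%s'",
                    paste(unique(tissue$color), collapse = ","), reference$color),
            "pq_invalid_input")
  if (any(tissue$weight_g <= 0))
    pq_stop("sample weights must be > 0", "pq_invalid_input")
  if (any(tissue$signal < 0))
    pq_stop("tissue signals must be >= 0", "pq_invalid_input")
  abs_flow <- tissue$signal / reference$signal * reference$withdrawal_rate_ml_min
  out <- tissue
  out$absolute_flow_ml_min <- abs_flow
  out$per_gram_flow_ml_min_g <- abs_flow / tissue$weight_g
  out
}

#' Per-region flow summary
#'
#' Weight-weighted mean per-gram flow per region,
#' `sum(flow_i * w_i) / sum(w_i)`, together with the unweighted mean and
#' the SD across samples.
#'
#' @param estimates output of [flow_per_sample()], optionally QC-filtered.
#' @return data.frame: `region`, `n`, `flow_weighted_ml_min_g`,
#'   `flow_unweighted_ml_min_g`, `flow_sd`.
#' @export
region_flow <- function(estimates) {
  regions <- sort(unique(estimates$region))
  rows <- lapply(regions, function(rg) {
    e <- estimates[estimates$region == rg, , drop = FALSE]
    data.frame(
      region = rg, n = nrow(e),
      flow_weighted_ml_min_g =
        sum(e$per_gram_flow_ml_min_g * e$weight_g) / sum(e$weight_g),
      flow_unweighted_ml_min_g = mean(e$per_gram_flow_ml_min_g),
      flow_sd = if (nrow(e) > 1L) stats::sd(e$per_gram_flow_ml_min_g) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag low-signal microsphere samples
#'
#' Samples whose signal falls below `min_signal` are flagged; by
#' convention ~400 spheres is the precision floor of the method (sphere
#' loss during digestion/filtering produces low counts). Flagged samples
#' should normally be excluded from [region_flow()]; exclusion is the
#' caller's choice via the returned flag column.
#'
#' @param tissue tissue table (see [flow_per_sample()]).
#' @param min_signal QC threshold (default 400).
#' @return the table with a logical `qc_low_signal` column.
#' @export
qc_sample_counts <- function(tissue, min_signal = 400) {
  tissue$qc_low_signal <- tissue$signal < min_signal
  tissue
}

#' Simulate a microsphere assay from ground-truth flows
#'
#' Expected tissue signal is proportional to `flow * weight` (spheres lodge
#' in proportion to absolute sample flow) and the expected reference signal
#' is proportional to the withdrawal rate with the same constant
#' (`reference_count_scale`, counts per mL/min). Realized counts are drawn
#' Poisson; `noise = "none"` returns the expected (possibly non-integer)
#' signals, which invert exactly through [flow_per_sample()].
#'
#' @param true_flows numeric vector of per-gram flows (ml/min/g), > 0.
#' @param weights sample weights (g), > 0, recycled to `length(true_flows)`.
#' @param withdrawal_rate reference withdrawal rate (mL/min), > 0
#'   (default 3.18).
#' @param reference_count_scale expected counts per mL/min of flow
#'   (default 830, i.e. ~2600 spheres in the reference sample).
#' @param regions region labels per sample.
#' @param color color channel label.
#' @param noise `"poisson"` or `"none"`.
#' @param seed seed for the Poisson draws.
#' @return list of class `microsphere_assay`: `tissue` (table for
#'   [flow_per_sample()]), `reference`, `true_flows`.
#' @export
simulate_microsphere_assay <- function(true_flows, weights = 3.5,
                                       withdrawal_rate = 3.18,
                                       reference_count_scale = 830,
                                       regions = NULL, color = "blue",
                                       noise = c("poisson", "none"),
                                       seed = 1) {
  noise <- match.arg(noise)
  if (withdrawal_rate <= 0)
    pq_stop("withdrawal_rate must be > 0", "pq_invalid_input")
  if (any(true_flows <= 0) || any(weights <= 0))
    pq_stop("flows and weights must be > 0", "pq_invalid_input")
  n <- length(true_flows)
  weights <- rep_len(weights, n)
  regions <- regions %||% rep_len(c("D1", "D2", "D3"), n)
  mu_tissue <- reference_count_scale * true_flows * weights
  mu_ref <- reference_count_scale * withdrawal_rate
  if (noise == "poisson") {
    draws <- with_stream(seed, "microspheres", {
      list(tissue = rpois(n, mu_tissue), ref = rpois(1L, mu_ref))
    })
    sig_tissue <- draws$tissue; sig_ref <- draws$ref
  } else {
    sig_tissue <- mu_tissue; sig_ref <- mu_ref
  }
  structure(list(
    tissue = data.frame(
      sample_id = sprintf("s%02d", seq_len(n)), region = regions,
      weight_g = weights, color = color, signal = sig_tissue,
      stringsAsFactors = FALSE),
    reference = list(color = color, signal = sig_ref,
                     withdrawal_rate_ml_min = withdrawal_rate),
    true_flows = true_flows
  ), class = "microsphere_assay")
}

#' Read / write microsphere tables
#'
#' Tissue CSV columns: `sample_id`, `region`, `weight_g`, `color`,
#' `signal`. Reference CSV columns: `color`, `signal`,
#' `withdrawal_rate_ml_min` (one row per color).
#'
#' @param path CSV file.
#' @param estimates flow table from [flow_per_sample()].
#' @return data.frames / invisibly `path`.
#' @export
read_tissue_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "region", "weight_g", "color", "signal")
  if (!all(req %in% names(df)))
    pq_stop(sprintf("%s: expected columns %s", path, paste(req, collapse = ", ")),
            "pq_parse_error")
  df
}

#' @rdname read_tissue_csv
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("color", "signal", "withdrawal_rate_ml_min")
  if (!all(req %in% names(df)))
    pq_stop(sprintf("%s: expected columns %s", path, paste(req, collapse = ", ")),
            "pq_parse_error")
  df
}

#' @rdname read_tissue_csv
#' @export
write_flow_csv <- function(estimates, path) {
  out <- estimates
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], fmt_num)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(do.call(paste, c(unname(out), sep = ",")), con)
  invisible(path)
}
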