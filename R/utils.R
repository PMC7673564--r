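# internal helpers: classed errors and seed substreams

pq_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "perfquant_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Derive a reproducible seed substream
#'
#' All randomness in the package flows from one root seed. Named substreams
#' keep the stages of a pipeline (per-curve noise, microsphere draws,
#' permutations, bootstrap) independently reproducible: the same
#' `(seed, name)` pair always yields the same stream, and distinct names give
#' unrelated streams.
#'
#' @param seed integer root seed.
#' @param name character stream label.
#' @return an integer seed in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' substream_seed(1, "curve/D1/T0")
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(paste(name, collapse = "/"))) {
    h <- (h * 31 + ch) %% 1000003
  }
  # all operands < 2^31 so the double arithmetic below is exact
  as.integer(((abs(seed) %% 65011) * 33029 + h * 7 + 11) %% 2147483629)
}

# evaluate code under a temporary seed, restoring the caller's RNG state
with_stream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# format numbers for CSV output: round-trippable, locale-independent
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}
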