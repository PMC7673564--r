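#' Reciprocal (inverse) transform
#'
#' The perfusion metrics BSFI, SFI and TTS are right-skewed and
#' heteroscedastic; analyses run on the reciprocal scale `y = 1/x` and
#' summaries are back-transformed. The transform is an involution, so
#' [back_transform()] is the same map; their composition is the identity on
#' positive data.
#'
#' @param values numeric vector, strictly positive.
#' @return transformed values.
#' @export
inverse_transform <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    pq_stop(sprintf("inverse transform needs strictly positive values; offending row(s): %s",
                    paste(utils::head(bad, 5L), collapse = ", ")),
            "pq_transform_error")
  1 / values
}

#' @rdname inverse_transform
#' @export
back_transform <- function(values) inverse_transform(values)

# ---- permutation machinery -------------------------------------------------

# all permutations of 1..s as a (s!) x s matrix
perms_of <- function(s) {
  if (s == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_of(s - 1L)
  out <- matrix(0L, nrow(sub) * s, s)
  r <- 0L
  for (k in seq_len(s)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(s)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), s - 1L)
    r <- r + nrow(sub)
  }
  out
}

# Index matrix of within-block permutations of 1..n: each column permutes
# rows within blocks. Exhaustive when the number of distinct arrangements
# is <= exact_limit (identity included); Monte Carlo with B columns
# otherwise. Returns list(idx, exact).
perm_within_blocks <- function(blocks, B, exact_limit = 1e5) {
  blocks <- as.factor(blocks)
  n <- length(blocks)
  pb <- split(seq_len(n), blocks)
  sizes <- lengths(pb)
  total <- prod(factorial(sizes))
  if (is.finite(total) && total <= exact_limit) {
    perms <- lapply(sizes, perms_of)
    counts <- vapply(perms, nrow, 1L)
    grid_idx <- rep(1L, length(pb))
    idx <- matrix(0L, n, total)
    for (b in seq_len(total)) {
      col <- integer(n)
      for (g in seq_along(pb)) col[pb[[g]]] <- pb[[g]][perms[[g]][grid_idx[g], ]]
      idx[, b] <- col
      # odometer increment over the per-block permutation indices
      for (g in seq_along(grid_idx)) {
        grid_idx[g] <- grid_idx[g] + 1L
        if (grid_idx[g] <= counts[g]) break
        grid_idx[g] <- 1L
      }
    }
    return(list(idx = idx, exact = TRUE))
  }
  idx <- matrix(0L, n, B)
  if (length(unique(sizes)) == 1L && sizes[1L] <= 6L) {
    # uniform block size: vectorized draw of per-block permutation ids
    s <- sizes[1L]
    P <- perms_of(s)
    rows_mat <- do.call(rbind, pb)            # nblock x s
    nb <- nrow(rows_mat)
    ridx <- matrix(sample.int(nrow(P), nb * B, replace = TRUE), nb, B)
    gi <- rep(seq_len(nb), times = s)
    for (b in seq_len(B)) {
      perm <- P[ridx[, b], , drop = FALSE]
      col <- integer(n)
      col[as.vector(rows_mat)] <- rows_mat[cbind(gi, as.vector(perm))]
      idx[, b] <- col
    }
  } else {
    for (b in seq_len(B)) {
      col <- integer(n)
      for (g in pb) col[g] <- g[sample.int(length(g))]
      idx[, b] <- col
    }
  }
  list(idx = idx, exact = FALSE)
}

perm_pvalue <- function(obs, perm_stats, exact) {
  tol <- 1e-8 * max(1, abs(obs))
  hits <- sum(perm_stats >= obs - tol)
  if (exact) hits / length(perm_stats) else (1 + hits) / (1 + length(perm_stats))
}

proj_mat <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

# F-type statistics for columns of Y: (y'My/df1) / (y'Ry/df2), 0 when the
# residual quadratic form vanishes (constant data).
qf_stats <- function(M, R, Y, df1, df2) {
  num <- colSums(Y * (M %*% Y)) / df1
  den <- colSums(Y * (R %*% Y)) / df2
  ifelse(den <= 1e-12 * pmax(1, abs(num)), 0, num / den)
}

# ---- area x time model -----------------------------------------------------

#' Fixed-effects area-by-time model with permutation inference
#'
#' Fits a two-way fixed-effects linear model (categorical area, categorical
#' time, interaction) to the reciprocal-transformed metric and tests the
#' three effects by restricted permutation:
#' * **area** and **area-by-time**: area labels permuted within
#'   animal-by-state blocks (exchangeable under "no area effect");
#' * **time**: state labels permuted within animal-by-area blocks.
#'
#' F statistics compare nested models against the full-model residual.
#' When the number of distinct within-block arrangements does not exceed
#' `exact_limit`, the permutation distribution is enumerated exhaustively
#' and the p-value is the exact proportion (identity included); otherwise
#' `B_perm` Monte-Carlo draws are used with the add-one correction.
#'
#' Marginal means are cell means on the transformed scale, back-transformed
#' by the reciprocal-of-the-mean convention (`mean_of_reciprocals`
#' available via `back_convention`), with percentile-bootstrap intervals
#' over animals.
#'
#' @param table tidy metrics table with columns `animal_id`, `roi`,
#'   `state`, and either a `metric`/`value` pair (long) or a column named
#'   `metric_name` (wide, as written by [analyze_experiment()]).
#' @param metric_name which metric to model (e.g. `"sfi"`).
#' @param B_perm Monte-Carlo permutations (>= 1).
#' @param B_boot bootstrap resamples for the intervals; 0 skips intervals.
#' @param seed root seed of the permutation and bootstrap streams.
#' @param exact_limit exhaustive-enumeration cutoff.
#' @param back_convention `"reciprocal_of_mean"` (default) or
#'   `"mean_of_reciprocals"`.
#' @param transform apply the reciprocal transform (default TRUE).
#' @return object of class `effect_summary`: `means` (data.frame `roi`,
#'   `state`, `estimate`, `lower`, `upper`, `n`), `pvalues` (named vector
#'   `area`, `time`, `area_by_time`), `exact` flags, `metric`, `seed`.
#' @export
area_time_model <- function(table, metric_name, B_perm = 5000, B_boot = 2000,
                            seed = 1, exact_limit = 1e5,
                            back_convention = c("reciprocal_of_mean",
                                                "mean_of_reciprocals"),
                            transform = TRUE) {
  back_convention <- match.arg(back_convention)
  df <- extract_metric(table, metric_name)
  if (length(unique(df$roi)) < 2L || length(unique(df$state)) < 2L)
    pq_stop("need at least 2 areas and 2 states", "pq_invalid_input")
  if (length(unique(df$animal_id)) < 3L)
    pq_stop("need at least 3 animals", "pq_invalid_input")
  key <- interaction(df$animal_id, df$roi, df$state, drop = TRUE)
  if (anyDuplicated(key))
    pq_stop("more than one value per (animal, roi, state) cell", "pq_invalid_input")
  cell <- table(df$roi, df$state)
  if (any(cell == 0L))
    pq_stop("empty (area, state) cell: cannot fit the interaction model",
            "pq_invalid_input")
  if (length(unique(as.vector(cell))) > 1L)
    warning("unbalanced design: (area, state) cells have unequal counts")

  y <- if (transform) inverse_transform(df$value) else df$value
  area <- factor(df$roi); state <- factor(df$state)
  n <- length(y)
  X_full <- stats::model.matrix(~ area * state)
  X_add  <- stats::model.matrix(~ area + state)
  X_area <- stats::model.matrix(~ area)
  X_stat <- stats::model.matrix(~ state)
  P_full <- proj_mat(X_full); P_add <- proj_mat(X_add)
  P_area <- proj_mat(X_area); P_stat <- proj_mat(X_stat)
  a <- nlevels(area); s <- nlevels(state)
  df_area <- a - 1L; df_time <- s - 1L; df_int <- (a - 1L) * (s - 1L)
  df_res <- n - qr(X_full)$rank
  if (df_res < 1L)
    pq_stop("saturated model: need replication (>= 2 animals per cell)",
            "pq_invalid_input")
  R <- diag(n) - P_full
  M_area <- P_add - P_stat
  M_time <- P_add - P_area
  M_int  <- P_full - P_add

  stat1 <- function(M, yy, df1) qf_stats(M, R, matrix(yy, ncol = 1L), df1, df_res)
  obs <- c(area = stat1(M_area, y, df_area),
           time = stat1(M_time, y, df_time),
           area_by_time = stat1(M_int, y, df_int))

  blocks_area <- interaction(df$animal_id, state, drop = TRUE)
  blocks_time <- interaction(df$animal_id, area, drop = TRUE)
  pv <- with_stream(seed, "area_time_model/perm", {
    pa <- perm_within_blocks(blocks_area, B_perm, exact_limit)
    Ya <- matrix(y[pa$idx], n, ncol(pa$idx))
    p_area <- perm_pvalue(obs[["area"]],
                          qf_stats(M_area, R, Ya, df_area, df_res), pa$exact)
    p_int <- perm_pvalue(obs[["area_by_time"]],
                         qf_stats(M_int, R, Ya, df_int, df_res), pa$exact)
    pt <- perm_within_blocks(blocks_time, B_perm, exact_limit)
    Yt <- matrix(y[pt$idx], n, ncol(pt$idx))
    p_time <- perm_pvalue(obs[["time"]],
                          qf_stats(M_time, R, Yt, df_time, df_res), pt$exact)
    list(p = c(area = p_area, time = p_time, area_by_time = p_int),
         exact = c(area = pa$exact, time = pt$exact, area_by_time = pa$exact))
  })

  back <- function(yy) {
    if (back_convention == "reciprocal_of_mean") 1 / mean(yy) else mean(1 / yy)
  }
  cells <- expand.grid(roi = levels(area), state = levels(state),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell_est <- function(dat, yy) {
    vapply(seq_len(nrow(cells)), function(i) {
      sel <- dat$roi == cells$roi[i] & dat$state == cells$state[i]
      if (!any(sel)) NA_real_ else back(yy[sel])
    }, 0)
  }
  est <- cell_est(df, y)
  lower <- upper <- rep(NA_real_, nrow(cells))
  if (B_boot > 0) {
    animals <- unique(df$animal_id)
    boot <- with_stream(seed, "area_time_model/boot", {
      vapply(seq_len(B_boot), function(b) {
        draw <- sample(animals, length(animals), replace = TRUE)
        rows <- unlist(lapply(draw, function(an) which(df$animal_id == an)))
        cell_est(df[rows, , drop = FALSE], y[rows])
      }, numeric(nrow(cells)))
    })
    lower <- apply(boot, 1L, stats::quantile, probs = 0.025, na.rm = TRUE)
    upper <- apply(boot, 1L, stats::quantile, probs = 0.975, na.rm = TRUE)
    # percentile intervals are widened, if needed, to contain the estimate
    lower <- pmin(lower, est); upper <- pmax(upper, est)
  }
  cells$estimate <- est; cells$lower <- lower; cells$upper <- upper
  cells$n <- as.vector(t(cell)[cbind(match(cells$state, colnames(cell)),
                                     match(cells$roi, rownames(cell)))])
  structure(list(metric = metric_name, means = cells, pvalues = pv$p,
                 exact = pv$exact, statistics = obs, B_perm = B_perm,
                 B_boot = B_boot, seed = seed,
                 back_convention = back_convention),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("<effect_summary> metric %s: p(area) = %.4g, p(time) = %.4g, p(area x time) = %.4g\n",
              x$metric, x$pvalues[["area"]], x$pvalues[["time"]],
              x$pvalues[["area_by_time"]]))
  print(x$means, digits = 4)
  invisible(x)
}

extract_metric <- function(table, metric_name) {
  need <- c("animal_id", "roi", "state")
  if (!all(need %in% names(table)))
    pq_stop("metrics table needs columns animal_id, roi, state", "pq_invalid_input")
  if (all(c("metric", "value") %in% names(table))) {
    df <- table[table$metric == metric_name,
                c("animal_id", "roi", "state", "value")]
  } else if (metric_name %in% names(table)) {
    df <- table[, need]
    df$value <- table[[metric_name]]
  } else {
    pq_stop(sprintf("metric '%s' not found in table", metric_name),
            "pq_invalid_input")
  }
  df <- df[!is.na(df$value), , drop = FALSE]
  if (nrow(df) == 0L) pq_stop("no values for the requested metric", "pq_invalid_input")
  df
}

# ---- correlation with microsphere flow ------------------------------------

#' Correlate a fluorescence metric with microsphere flow
#'
#' Rank (Spearman, default) correlation between a per-(animal, roi, state)
#' fluorescence metric and the matching microsphere per-gram flows, with a
#' permutation p-value obtained by permuting the flow vector within animal
#' blocks (two-sided, on `|rho|`). Enumerates exhaustively when feasible.
#'
#' @param metrics tidy metrics table (see [area_time_model()]).
#' @param flows data.frame with `animal_id`, `roi`, `state` and a flow
#'   column.
#' @param metric_name metric column/name (default `"sfi"`).
#' @param flow_col flow column name in `flows`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param B Monte-Carlo permutations.
#' @param seed seed of the permutation stream.
#' @param exact_limit exhaustive-enumeration cutoff.
#' @return list with `rho`, `p_value`, `n`, `method`, `exact`.
#' @export
correlate_metric_with_flow <- function(metrics, flows, metric_name = "sfi",
                                       flow_col = "fm_flow_ml_min_g",
                                       method = c("spearman", "pearson"),
                                       B = 5000, seed = 1, exact_limit = 1e5) {
  method <- match.arg(method)
  mdf <- extract_metric(metrics, metric_name)
  if (!flow_col %in% names(flows))
    pq_stop(sprintf("flow column '%s' not in flows table", flow_col),
            "pq_invalid_input")
  merged <- merge(mdf, flows[, c("animal_id", "roi", "state", flow_col)],
                  by = c("animal_id", "roi", "state"))
  if (nrow(merged) < 3L)
    pq_stop("fewer than 3 matched (animal, roi, state) pairs", "pq_invalid_input")
  if (nrow(merged) < nrow(mdf))
    warning(sprintf("%d metric rows had no matching flow", nrow(mdf) - nrow(merged)))
  x <- merged$value; fl <- merged[[flow_col]]
  rho <- stats::cor(x, fl, method = method)
  res <- with_stream(seed, "correlate/perm", {
    pm <- perm_within_blocks(merged$animal_id, B, exact_limit)
    Fl <- matrix(fl[pm$idx], length(fl), ncol(pm$idx))
    perm_rho <- abs(stats::cor(x, Fl, method = method)[1L, ])
    list(p = perm_pvalue(abs(rho), perm_rho, pm$exact), exact = pm$exact)
  })
  list(rho = rho, p_value = res$p, n = nrow(merged), method = method,
       exact = res$exact)
}

# ---- qualitative orderings -------------------------------------------------

#' Per-state ranking of areas
#'
#' For each metric and hemodynamic state, ranks the areas by their mean
#' value across animals (descending) and reports the fraction of animals
#' whose individual ranking agrees with the overall one.
#'
#' @param table tidy metrics table.
#' @param metric_names metrics to summarize.
#' @return data.frame: `metric`, `state`, `ordering` (e.g. `"D3>D2>D1"`),
#'   `agreement`.
#' @export
summarize_ordering <- function(table, metric_names = c("bsfi", "sfi", "tts_ratio")) {
  rows <- list()
  for (mn in metric_names) {
    df <- extract_metric(table, mn)
    for (st in sort(unique(df$state))) {
      d <- df[df$state == st, , drop = FALSE]
      mu <- tapply(d$value, d$roi, mean)
      ord <- names(sort(mu, decreasing = TRUE))
      per_animal <- tapply(seq_len(nrow(d)), d$animal_id, function(ii) {
        v <- stats::setNames(d$value[ii], d$roi[ii])
        identical(names(sort(v, decreasing = TRUE)), ord)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mn, state = st, ordering = paste(ord, collapse = ">"),
        agreement = mean(unlist(per_animal)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
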