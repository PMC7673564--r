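test_that("reciprocal transform round-trips and rejects nonpositive values", {
  expect_equal(inverse_transform(2), 0.5)
  x <- withr::with_seed(1, runif(50, 0.1, 100))
  expect_equal(back_transform(inverse_transform(x)), x, tolerance = 1e-12)
  expect_error(inverse_transform(c(1, 0, 3)), "2", class = "pq_transform_error")
  expect_error(inverse_transform(-1), class = "pq_transform_error")
})

test_that("identical values give p = 1 and degenerate marginal means", {
  g <- expand.grid(animal_id = c("A1", "A2", "A3"),
                   roi = c("D1", "D2", "D3"), state = c("T0", "T1"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$metric <- "m"; g$value <- 4
  fit <- area_time_model(g, "m", B_perm = 200, B_boot = 100, seed = 1)
  expect_equal(unname(fit$pvalues), rep(1, 3))
  expect_equal(fit$means$estimate, rep(4, 6))
  expect_true(all(fit$means$lower <= fit$means$estimate &
                  fit$means$upper >= fit$means$estimate))
})

test_that("exact permutation p-values match an independent exhaustive oracle", {
  tab <- make_metrics_table(n_animals = 3, areas = c("D1", "D3"),
                            states = c("T0", "T1"), seed = 7,
                            area_effect = c(1, 1.6))
  fit <- area_time_model(tab, "m", B_perm = 10, B_boot = 0, seed = 1)
  expect_true(fit$exact[["area"]])  # 2^6 = 64 arrangements, enumerated

  # oracle: plain lm-based F over every within-(animal,state) swap of the
  # transformed response
  y <- 1 / tab$value
  area <- factor(tab$roi); state <- factor(tab$state)
  rss <- function(form, yy) sum(stats::lm(form, data = data.frame(
    yy = yy, area = area, state = state))$residuals^2)
  f_stats <- function(yy) {
    r_full <- rss(yy ~ area * state, yy); r_add <- rss(yy ~ area + state, yy)
    r_st <- rss(yy ~ state, yy); r_ar <- rss(yy ~ area, yy)
    df_res <- length(yy) - 4L
    c(area = ((r_st - r_add) / 1) / (r_full / df_res),
      time = ((r_ar - r_add) / 1) / (r_full / df_res),
      int = ((r_add - r_full) / 1) / (r_full / df_res))
  }
  blocks <- split(seq_len(nrow(tab)), interaction(tab$animal_id, tab$state))
  swaps <- expand.grid(rep(list(c(FALSE, TRUE)), length(blocks)))
  obs <- f_stats(y)
  perm_area <- apply(swaps, 1L, function(sw) {
    yy <- y
    for (g in which(as.logical(sw))) yy[blocks[[g]]] <- rev(yy[blocks[[g]]])
    f_stats(yy)[["area"]]
  })
  tol <- 1e-8 * max(1, obs[["area"]])
  expect_equal(fit$pvalues[["area"]],
               mean(perm_area >= obs[["area"]] - tol), tolerance = 1e-12)

  blocks_t <- split(seq_len(nrow(tab)), interaction(tab$animal_id, tab$roi))
  perm_time <- apply(swaps, 1L, function(sw) {
    yy <- y
    for (g in which(as.logical(sw))) yy[blocks_t[[g]]] <- rev(yy[blocks_t[[g]]])
    f_stats(yy)[["time"]]
  })
  tol_t <- 1e-8 * max(1, obs[["time"]])
  expect_equal(fit$pvalues[["time"]],
               mean(perm_time >= obs[["time"]] - tol_t), tolerance = 1e-12)
})

test_that("a known multiplicative area effect is detected; absent time effect is not", {
  p_area <- p_time <- numeric(5)
  for (i in 1:5) {
    tab <- make_metrics_table(n_animals = 5, states = c("T0", "T1", "T2"),
                              seed = 100 + i, area_effect = c(1, 1.5, 2.25))
    fit <- area_time_model(tab, "m", B_perm = 999, B_boot = 0, seed = i)
    p_area[i] <- fit$pvalues[["area"]]; p_time[i] <- fit$pvalues[["time"]]
  }
  expect_true(all(p_area < 0.01))
  expect_gt(stats::median(p_time), 0.1)
})

test_that("permutation p-values are reproducible and invariant to row order", {
  tab <- make_metrics_table(n_animals = 3, areas = c("D1", "D3"),
                            states = c("T0", "T1"), seed = 3)
  f1 <- area_time_model(tab, "m", B_perm = 50, B_boot = 0, seed = 9)
  f2 <- area_time_model(tab, "m", B_perm = 50, B_boot = 0, seed = 9)
  expect_identical(f1$pvalues, f2$pvalues)
  shuffled <- tab[withr::with_seed(4, sample(nrow(tab))), ]
  f3 <- area_time_model(shuffled, "m", B_perm = 50, B_boot = 0, seed = 9)
  expect_equal(f3$pvalues, f1$pvalues, tolerance = 1e-12)  # exact enumeration
})

test_that("correlation: monotone limits and exhaustive permutation oracle", {
  base <- expand.grid(animal_id = c("A1", "A2", "A3"),
                      roi = c("D1", "D2", "D3"), state = "T0",
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base$metric <- "sfi"
  base$value <- withr::with_seed(2, runif(9, 10, 50))
  flows <- base[, c("animal_id", "roi", "state")]

  flows$fm_flow_ml_min_g <- base$value * 3 + 1   # perfectly monotone
  expect_equal(correlate_metric_with_flow(base, flows, B = 50, seed = 1)$rho, 1.0)
  flows$fm_flow_ml_min_g <- -base$value
  expect_equal(correlate_metric_with_flow(base, flows, B = 50, seed = 1)$rho, -1.0)

  flows$fm_flow_ml_min_g <- withr::with_seed(5, runif(9, 0.5, 2))
  got <- correlate_metric_with_flow(base, flows, B = 10, seed = 1)
  expect_true(got$exact)  # (3!)^3 = 216 arrangements
  # oracle: enumerate every within-animal permutation of the flow vector
  blocks <- split(seq_len(9), base$animal_id)
  perms <- perfquant:::perms_of(3)
  combos <- expand.grid(a = 1:6, b = 1:6, c = 1:6)
  obs <- abs(cor(base$value, flows$fm_flow_ml_min_g, method = "spearman"))
  rho_perm <- apply(combos, 1L, function(ix) {
    fl <- flows$fm_flow_ml_min_g
    for (g in 1:3) fl[blocks[[g]]] <- flows$fm_flow_ml_min_g[blocks[[g]]][perms[ix[g], ]]
    abs(cor(base$value, fl, method = "spearman"))
  })
  expect_equal(got$p_value, mean(rho_perm >= obs - 1e-8 * max(1, obs)),
               tolerance = 1e-12)
})

test_that("ordering summary reports rankings and animal agreement", {
  g <- expand.grid(animal_id = c("A1", "A2", "A3"),
                   roi = c("D1", "D2", "D3"), state = c("T0", "T1"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$metric <- "sfi"
  g$value <- c(D1 = 1, D2 = 2, D3 = 3)[g$roi] + 0.01 * seq_len(nrow(g))
  # flip one animal's D1/D2 ranking in one state without moving the means
  g$value[g$animal_id == "A2" & g$state == "T1" & g$roi == "D1"] <- 2.5
  s <- summarize_ordering(g, "sfi")
  expect_equal(s$ordering[s$state == "T0"], "D3>D2>D1")
  expect_equal(s$agreement[s$state == "T0"], 1)
  expect_equal(s$agreement[s$state == "T1"], 2 / 3)
})

test_that("model preconditions are enforced", {
  tab <- make_metrics_table(n_animals = 2)
  expect_error(area_time_model(tab, "m"), class = "pq_invalid_input")
  tab3 <- make_metrics_table(n_animals = 3)
  dup <- rbind(tab3, tab3[1L, ])
  expect_error(area_time_model(dup, "m"), class = "pq_invalid_input")
  expect_error(area_time_model(tab3, "nope"), class = "pq_invalid_input")
})
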