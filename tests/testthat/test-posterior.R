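test_that("multivariate-normal draws reproduce the target covariance", {
  V <- matrix(c(2, 0.8, -0.3,
                0.8, 1, 0.2,
                -0.3, 0.2, 0.5), 3, 3)
  beta <- c(1, -2, 0.5)
  B <- 2e4
  draws <- sample_coefficients(list(beta = beta, V = V), B = B, seed = 1)
  S <- stats::cov(draws)
  for (i in 1:3) for (j in 1:3) {
    mc_se <- sqrt((V[i, i] * V[j, j] + V[i, j]^2) / (B - 1))
    expect_lt(abs(S[i, j] - V[i, j]), 3 * mc_se)
  }
  expect_equal(colMeans(draws), beta, tolerance = 3 * sqrt(max(diag(V)) / B) * 3,
               ignore_attr = TRUE)

  # determinism and the degenerate case
  draws2 <- sample_coefficients(list(beta = beta, V = V), B = 100, seed = 9)
  draws3 <- sample_coefficients(list(beta = beta, V = V), B = 100, seed = 9)
  expect_identical(draws2, draws3)
  d0 <- sample_coefficients(list(beta = beta, V = V * 0), B = 10, seed = 1)
  expect_true(all(d0 == rep(beta, each = 10)))
  expect_error(sample_coefficients(list(beta = beta, V = V), B = 1),
               class = "dsmflow_spec_error")
})

test_that("random-walk Metropolis draws stay centred on the mode and are reproducible", {
  fx <- small_fit(seed = 7, family = "poisson")
  d1 <- sample_coefficients(fx$fit, B = 300, seed = 4, sampler = "rw_metropolis")
  d2 <- sample_coefficients(fx$fit, B = 300, seed = 4, sampler = "rw_metropolis")
  expect_identical(d1, d2)
  expect_gt(nrow(unique(as.data.frame(d1))), 50)  # chain moves
  beta <- coef(fx$fit)
  sds <- sqrt(diag(dsm_covariance(fx$fit, "V_beta")))
  expect_true(all(abs(colMeans(d1) - beta) < 5 * sds))
})

test_that("Welford streaming equals batch moments", {
  set.seed(8)
  d <- 7
  chunks <- lapply(1:5, function(i) matrix(rnorm(d * 13, mean = i), d, 13))
  state <- welford_init(d)
  for (ch in chunks) state <- welford_add_batch(state, ch)
  fin <- welford_finalize(state)
  all_obs <- do.call(cbind, chunks)
  expect_equal(fin$mean, rowMeans(all_obs), tolerance = 1e-12)
  expect_equal(fin$variance, apply(all_obs, 1, var), tolerance = 1e-10)

  # one-at-a-time updates and pairwise combination agree with the batch route
  s1 <- welford_init(d)
  for (k in 1:20) s1 <- welford_update(s1, all_obs[, k])
  s2 <- welford_init(d)
  for (k in 21:ncol(all_obs)) s2 <- welford_update(s2, all_obs[, k])
  fin2 <- welford_finalize(welford_combine(s1, s2))
  expect_equal(fin2$mean, fin$mean, tolerance = 1e-12)
  expect_equal(fin2$variance, fin$variance, tolerance = 1e-10)
})

test_that("an intercept-only surface at beta = 0 predicts unit abundance in unit cells", {
  seg <- tibble::tibble(segment_id = sprintf("s%d", 1:20), effort_length = 1,
                        x = runif(20), y = runif(20), count = 1L)
  fit <- fit_dsm(seg, model_spec(family = "poisson"), offset = rep(1, 20))
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-10)
  grid <- tibble::tibble(period = "t1", cell_id = 1:5, cell_area = 1)
  draws <- matrix(0, 4, 1)
  stream <- predict_abundance_draws(fit, grid, draws)
  fin <- welford_finalize(stream$overall)
  expect_equal(fin$mean, rep(1, 5))
  expect_equal(stream$period_totals["t1", ], rep(5, 4), ignore_attr = TRUE)

  # doubling all cell areas doubles every prediction
  grid2 <- dplyr::mutate(grid, cell_area = 2)
  stream2 <- predict_abundance_draws(fit, grid2, draws)
  expect_equal(stream2$period_totals["t1", ], 2 * stream$period_totals["t1", ])
})

test_that("simulation variance of a linear summary matches the quadratic form", {
  fx <- small_fit(seed = 7, family = "poisson")
  fit <- fx$fit
  g1 <- fx$grids[fx$grids$period == "t001", ]
  B <- 1e4
  draws <- sample_coefficients(fit, B = B, seed = 2, rung = "V_beta")
  # identity link makes the cell totals linear in beta, so the draw variance
  # has the exact analytic counterpart a" V a
  stream <- predict_abundance_draws(fit, g1, draws, linkinv = identity)
  v_sim <- var(stream$period_totals["t001", ])
  pe <- predict_eta(fit, g1)
  a <- drop(t(pe$X) %*% g1$cell_area)
  V <- dsm_covariance(fit, "V_beta")
  v_exact <- drop(a %*% V %*% a)
  expect_lt(abs(v_sim / v_exact - 1), 0.05)
  av <- analytic_variance(fit, g1, rung = "V_beta", link = "identity")
  expect_equal(av$variance, v_exact, tolerance = 1e-8)
})

test_that("streamed cell summaries equal batch summaries of retained draws", {
  fx <- small_fit(seed = 7, family = "poisson", n_periods = 6)
  fit <- fx$fit
  draws <- sample_coefficients(fit, B = 40, seed = 3, rung = "V_beta")
  pg <- period_groups_of(fx$grids)
  stream <- predict_abundance_draws(fit, fx$grids, draws, period_groups = pg)

  # batch oracle: retain every draw-period prediction
  periods <- unique(fx$grids$period)
  batch <- lapply(periods, function(tl) {
    gt <- fx$grids[fx$grids$period == tl, ]
    pe <- predict_eta(fit, gt)
    gt$cell_area * exp(pe$X %*% t(draws))
  })
  all_mat <- do.call(cbind, batch)
  map <- summarize_cells(stream, "overall")
  expect_equal(map$mean, unname(rowMeans(all_mat)), tolerance = 1e-10)
  expect_equal(map$se, unname(apply(all_mat, 1, sd)), tolerance = 1e-10)

  # per-month accumulators partition the periods: pooled mean is the
  # n-weighted mean of the group means
  monthly <- summarize_cells(stream, "month")
  pooled <- monthly |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(mean = sum(mean * n) / sum(n), .groups = "drop")
  expect_equal(pooled$mean[match(map$cell_id, pooled$cell_id)], map$mean,
               tolerance = 1e-10)
})

test_that("abundance series: log-normal intervals behave and degenerate draws collapse", {
  fx <- small_fit(seed = 7, family = "poisson", n_periods = 6)
  beta <- coef(fx$fit)
  draws0 <- rbind(beta, beta)  # two identical draws: zero draw variance
  pg <- period_groups_of(fx$grids)
  stream <- predict_abundance_draws(fx$fit, fx$grids, draws0, period_groups = pg)
  ser <- abundance_series(stream, grouping = "overall")
  expect_equal(ser$cv, 0)
  expect_equal(ser$lower, ser$estimate)
  expect_equal(ser$upper, ser$estimate)

  draws <- sample_coefficients(fx$fit, B = 100, seed = 5, rung = "V_beta")
  stream <- predict_abundance_draws(fx$fit, fx$grids, draws, period_groups = pg)
  ser_m <- abundance_series(stream, grouping = "month")
  expect_equal(nrow(ser_m), 2)
  # log-normal skew: upper arm longer than lower arm
  expect_true(all(ser_m$upper - ser_m$estimate > ser_m$estimate - ser_m$lower))
  expect_true(all(ser_m$lower <= ser_m$estimate & ser_m$estimate <= ser_m$upper))

  # direct evaluation of the interval formula
  ci <- lognormal_interval(1000, 0.2)
  expect_equal(ci$lower, exp(log(1000) - 1.96 * sqrt(log(1.04))),
               tolerance = 1e-3)
  expect_equal(ci$upper, exp(log(1000) + 1.96 * sqrt(log(1.04))),
               tolerance = 1e-3)

  # median point statistic is accepted
  ser_med <- abundance_series(stream, grouping = "overall", point = "median")
  expect_true(abs(ser_med$estimate - ser$estimate) / ser$estimate < 0.5)
})

test_that("delta-method CV combination is exact, order-free and offset-aware", {
  s <- tibble::tibble(group = "all", estimate = 1000, se = 100, cv = 0.1,
                      lower = NA_real_, upper = NA_real_)
  class(s) <- c("abundance_series", class(s))
  g0 <- correction_factor("g0", 0.921, 0.023)
  out <- combine_cv(s, g0)
  expect_equal(out$cv, sqrt(0.1^2 + 0.023^2), tolerance = 1e-12)
  # correction already in the offset: the point estimate is untouched
  expect_equal(out$estimate, 1000)
  expect_equal(out$se, out$cv * out$estimate)

  # a correction NOT in the offset scales the point estimate up
  g0_out <- dplyr::mutate(g0, in_offset = FALSE)
  out2 <- combine_cv(s, g0_out)
  expect_equal(out2$estimate, 1000 / 0.921)

  # order of corrections is irrelevant; empty set is the identity
  u <- correction_factor("availability", 0.6, 0.1)
  ab <- combine_cv(s, dplyr::bind_rows(g0, u))
  ba <- combine_cv(s, dplyr::bind_rows(u, g0))
  expect_equal(ab, ba)
  expect_equal(combine_cv(s, NULL), s)

  # coincident corrections and bad estimates are refused
  expect_error(combine_cv(s, dplyr::mutate(g0, coincident = TRUE)),
               class = "dsmflow_spec_error")

  # cell maps combine on mean/se
  map <- tibble::tibble(cell_id = 1:2, mean = c(10, 20), se = c(1, 2))
  mout <- combine_cv(map, g0)
  expect_equal(mout$se, sqrt((c(1, 2) / c(10, 20))^2 + 0.023^2) * c(10, 20))
})

test_that("analytic variance handles edge cases and agrees with simulation", {
  fx <- small_fit(seed = 7, family = "poisson")
  fit <- fx$fit
  # zero weights: zero variance
  w0 <- stats::setNames(rep(0, 3), unique(fx$grids$period))
  expect_equal(analytic_variance(fit, fx$grids, weights = w0)$variance, 0)

  # one period, one cell: reduces to N^2 x" V x for the log link
  g1 <- fx$grids[fx$grids$period == "t001", ][1, ]
  av1 <- analytic_variance(fit, g1, weights = c(t001 = 1), rung = "V_beta")
  pe <- predict_eta(fit, g1)
  N1 <- g1$cell_area * exp(pe$eta)
  V <- dsm_covariance(fit, "V_beta")
  expect_equal(av1$variance, drop(N1^2 * pe$X %*% V %*% t(pe$X)),
               tolerance = 1e-10)

  # log-link simulation oracle at B = 1e4
  draws <- sample_coefficients(fit, B = 1e4, seed = 6, rung = "V_beta")
  stream <- predict_abundance_draws(fit, fx$grids, draws)
  per_draw <- colMeans(stream$period_totals)
  av <- analytic_variance(fit, fx$grids, rung = "V_beta")
  expect_lt(abs(av$variance / var(per_draw) - 1), 0.10)
})
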