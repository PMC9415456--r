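test_that("design builder centres bases and books penalties correctly", {
  set.seed(1)
  dat <- data.frame(x = runif(50))
  spec <- model_spec(smooth_spec("x", k = 10))
  des <- build_design(spec, dat)
  # k = 10 with one sum-to-zero constraint: 9 columns + intercept
  expect_equal(ncol(des$X), 10)
  expect_equal(length(des$penalties), 1)
  expect_equal(dim(des$penalties[[1]]), c(10, 10))
  # intercept row/col of the expanded penalty is zero; smooth block is 9x9
  expect_true(all(des$penalties[[1]][1, ] == 0))
  expect_true(any(des$penalties[[1]][-1, -1] != 0))

  # identical covariate rows give identical design rows
  dat2 <- dat[c(1, 1, 2:30), , drop = FALSE]
  des2 <- build_design(spec, dat2)
  expect_equal(des2$X[1, ], des2$X[2, ])

  # a constant covariate cannot support knots
  expect_error(build_design(spec, data.frame(x = rep(1, 20))),
               class = "dsmflow_basis_error")

  # tensor smooth: two marginal penalties
  dat3 <- data.frame(x = runif(60), y = runif(60))
  des3 <- build_design(model_spec(smooth_spec(c("x", "y"), k = 4)), dat3)
  expect_equal(length(des3$penalties), 2)
})

test_that("an unshrunk penalty annihilates linear functions of the covariate", {
  set.seed(2)
  dat <- data.frame(x = runif(80))
  des <- build_design(model_spec(smooth_spec("x", k = 8, shrinkage = FALSE)), dat)
  # coefficients representing a straight line (in the basis span)
  target <- 2 + 3 * dat$x
  b <- qr.coef(qr(des$X), target)
  expect_equal(drop(des$X %*% b), target, tolerance = 1e-8)
  S <- des$penalties[[1]]
  expect_lt(drop(b %*% S %*% b) / (sum(diag(S)) * sum(b^2)), 1e-10)
})

test_that("unpenalized fit equals the GLM solution; huge shrinkage kills a term", {
  fx <- small_fit(seed = 7, family = "poisson")
  npen <- length(fx$fit$gam$sp)
  fit0 <- fit_dsm(fx$segments, fx$spec, sp = rep(0, npen))
  X <- stats::model.matrix(fit0$gam)
  glm_fit <- suppressWarnings(
    stats::glm.fit(X, fit0$data$count, family = stats::poisson(),
                   offset = fit0$data$.log_offset))
  expect_equal(unname(coef(fit0)), unname(glm_fit$coefficients),
               tolerance = 1e-6)

  # lambda -> infinity on shrinkage smooths drives edf and effect to ~0
  fit_inf <- fit_dsm(fx$segments, fx$spec, sp = rep(1e8, npen))
  edf <- tidy(fit_inf)
  expect_lt(edf$edf[grepl("sst", edf$term)], 0.1)
  sst_cols <- grep("sst", names(coef(fit_inf)))
  expect_lt(max(abs(coef(fit_inf)[sst_cols])), 1e-3)
})

test_that("Poisson fit satisfies the intercept score equation (totals match)", {
  fx <- small_fit(seed = 7, family = "poisson")
  expect_equal(sum(fitted(fx$fit$gam)), sum(fx$segments$count),
               tolerance = 1e-6)
})

test_that("REML criterion at the estimated smoothing parameters is optimal", {
  fx <- small_fit(seed = 7, family = "poisson")
  g <- fx$fit$gam
  for (mult in c(0.5, 2)) {
    alt <- fit_dsm(fx$segments, fx$spec, sp = g$sp * mult)
    expect_lte(g$gcv.ubre, alt$gam$gcv.ubre + 1e-6)
  }
})

test_that("prediction reproduces the in-sample linear predictor and is linear in beta", {
  fx <- small_fit(seed = 7, family = "poisson")
  fit <- fx$fit
  pe <- predict_eta(fit, fit$data)
  expect_equal(pe$eta, unname(fit$gam$linear.predictors - fit$data$.log_offset),
               tolerance = 1e-8)
  # linearity: X (b1 + b2) = X b1 + X b2
  b <- coef(fit)
  e1 <- drop(pe$X %*% b)
  e2 <- drop(pe$X %*% (2 * b))
  expect_equal(e1 + drop(pe$X %*% b), e2, tolerance = 1e-10)
})

test_that("cells beyond the training covariate range are flagged as extrapolating", {
  fx <- small_fit(seed = 7, family = "poisson")
  # a grid built from the training segments is in-range by construction
  g1 <- tibble::tibble(period = "p", cell_id = seq_len(nrow(fx$segments)),
                       cell_area = 1, x = fx$segments$x, y = fx$segments$y,
                       sst = fx$segments$sst)
  g1$sst[1] <- max(fx$segments$sst) + 10  # far outside training support
  pe <- predict_eta(fx$fit, g1)
  expect_true(pe$extrapolated[1])
  expect_false(any(pe$extrapolated[-1]))
  expect_error(predict_eta(fx$fit, g1[, setdiff(names(g1), "sst")]),
               class = "dsmflow_prediction_error")
})

test_that("smoothing-parameter uncertainty only adds variance and matches mgcv's correction in scale", {
  fx <- small_fit(seed = 7, family = "poisson")
  fit <- smoothing_uncertainty(fx$fit)
  Vb <- dsm_covariance(fx$fit, "V_beta")
  Vbl <- dsm_covariance(fit, "V_beta_lambda")
  expect_symmetric_psd(Vbl - Vb, tol = 1e-6)

  # independent route: mgcv's unconditional covariance correction
  Vc <- stats::vcov(fx$fit$gam, unconditional = TRUE)
  add_mine <- sum(diag(Vbl - Vb))
  add_mgcv <- sum(diag(Vc - Vb))
  expect_gt(add_mine, 0)
  expect_gt(add_mgcv, 0)
  expect_gt(add_mine / add_mgcv, 0.1)
  expect_lt(add_mine / add_mgcv, 10)

  # total-abundance SE cannot shrink under the correction
  se_b <- analytic_variance(fx$fit, fx$grids, rung = "V_beta")$se
  se_bl <- analytic_variance(fit, fx$grids, rung = "V_beta_lambda")$se
  expect_gte(se_bl, se_b)

  # user-fixed smoothing parameters: nothing to correct
  fit_fix <- fit_dsm(fx$segments, fx$spec, sp = fx$fit$gam$sp)
  fit_fix <- smoothing_uncertainty(fit_fix)
  expect_equal(dsm_covariance(fit_fix, "V_beta_lambda"),
               dsm_covariance(fit_fix, "V_beta"))
})

test_that("more survey effort reduces error in the fitted surface", {
  mse_of <- function(n_transects, seed) {
    sc <- tiny_scenario(seed = seed, family = "poisson",
                        n_transects = n_transects)
    grids <- simulate_covariate_fields(sc)
    sv <- simulate_survey(sc, grids)
    det <- fit_detection(sv$observations, truncation = sc$truncation,
                         formula = ~beaufort)
    seg <- attach_counts(sv$segments, sv$observations, "individuals",
                         sc$truncation)
    seg <- segment_area(seg, sc$truncation)
    seg <- predict_p_segments(det, seg)
    seg$offset <- seg$area * seg$p
    fit <- fit_dsm(seg, model_spec(smooth_spec(c("x", "y"), k = 5),
                                   smooth_spec("sst", k = 5),
                                   family = "poisson"))
    eta_hat <- predict_eta(fit, seg)$eta
    truth <- true_log_density(sc, seg$x, seg$y, seg$sst)
    mean((eta_hat - truth)^2)
  }
  # average over paired replicates to damp Monte Carlo noise
  lo <- mean(vapply(1:5, function(s) mse_of(6, s), numeric(1)))
  hi <- mean(vapply(1:5, function(s) mse_of(24, s), numeric(1)))
  expect_lt(hi, lo)
})
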