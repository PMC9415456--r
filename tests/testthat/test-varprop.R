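test_that("sensitivity columns match the closed-form derivative for covariate-free detection", {
  set.seed(3)
  obs <- tibble::tibble(segment_id = "s",
                        distance = abs(rnorm(400)) * 1.2)
  obs <- obs[obs$distance <= 2, ]
  det <- fit_detection(obs, truncation = 2)
  seg <- tibble::tibble(segment_id = letters[1:4], effort_length = 1,
                        x = 1:4, y = 0)
  D <- dsmflow:::detection_sensitivity(det, seg)
  # closed form: p(sigma) = sigma sqrt(2 pi) (Phi(w/sigma) - 1/2) / w,
  # d log p / d theta0 = 1 - (w/sigma) phi(w/sigma) / (Phi(w/sigma) - 1/2)
  w <- 2
  sig <- exp(det$theta[1])
  r <- w / sig
  dlogp <- 1 - r * stats::dnorm(r) / (stats::pnorm(r) - 0.5)
  expect_equal(unname(D[, 1]), rep(unname(dlogp), 4), tolerance = 1e-4)
})

test_that("vanishing detection uncertainty reproduces the plain fit", {
  fx <- small_fit(seed = 7, family = "poisson")
  det0 <- fx$det
  det0$V_theta <- diag(1e-12, length(det0$theta))
  vp <- varprop_refit(fx$fit, det0)
  keep <- setdiff(seq_along(coef(vp)), vp$varprop$det_index)
  expect_equal(unname(coef(vp)[keep]), unname(coef(fx$fit)), tolerance = 1e-6)
  expect_equal(unname(vp$varprop$delta_theta), rep(0, length(det0$theta)),
               tolerance = 1e-6)
  V_plain <- dsm_covariance(fx$fit, "V_beta")
  V_prop <- combined_covariance(vp)[keep, keep]
  expect_equal(unname(V_prop), unname(V_plain), tolerance = 1e-6)
})

test_that("propagation orders the covariance ladder and flags large shifts", {
  fx <- small_fit(seed = 7, family = "poisson")
  vp <- varprop_refit(fx$fit, fx$det)
  V_bt <- combined_covariance(vp, include_lambda = FALSE)
  expect_symmetric_psd(V_bt)
  # lambda rung requires the correction first
  expect_error(combined_covariance(vp, include_lambda = TRUE),
               class = "dsmflow_spec_error")
  vp <- smoothing_uncertainty(vp)
  V_blt <- combined_covariance(vp, include_lambda = TRUE)
  expect_symmetric_psd(V_blt)
  expect_gte(sum(diag(V_blt)), sum(diag(V_bt)) - 1e-10)

  # propagated total-abundance SE cannot fall below the plain-GAM SE here
  se_b <- analytic_variance(fx$fit, fx$grids, rung = "V_beta")$se
  se_bt <- analytic_variance(vp, fx$grids, rung = "V_beta_theta")$se
  expect_gte(se_bt, se_b * 0.999)

  rep <- varprop_report(vp)
  expect_equal(nrow(rep), length(fx$det$theta))
  expect_true(is.logical(attr(rep, "shift_flag")))

  # asking a plain fit for a theta rung is an error
  expect_error(dsm_covariance(fx$fit, "V_beta_theta"),
               class = "dsmflow_spec_error")
  expect_error(combined_covariance(fx$fit), class = "dsmflow_spec_error")
})

test_that("constant-p propagation agrees with the delta-method combination", {
  fx <- small_fit(seed = 11, family = "negbin", det_beaufort = NULL)
  vp <- varprop_refit(fx$fit, fx$det)
  cv_gam <- analytic_variance(fx$fit, fx$grids, rung = "V_beta")$cv
  D <- dsmflow:::detection_sensitivity(fx$det, fx$segments)
  cv_p <- abs(D[1, 1]) * sqrt(fx$det$V_theta[1, 1])
  cv_delta <- sqrt(cv_gam^2 + cv_p^2)
  cv_vp <- analytic_variance(vp, fx$grids, rung = "V_beta_theta")$cv
  expect_lt(abs(cv_vp / cv_delta - 1), 0.10)
})

test_that("with spatially structured detectability, propagated SE can undercut the delta method", {
  # detection quality trends with latitude while density is spatially patchy,
  # so detection and spatial model covary; fixed case known to show the effect
  sc <- dsm_scenario(seed = 1, beaufort_trend = 2, det_beaufort = -0.25)
  grids <- simulate_covariate_fields(sc)
  sv <- simulate_survey(sc, grids)
  det <- fit_detection(sv$observations, truncation = sc$truncation,
                       formula = ~beaufort)
  seg <- attach_counts(sv$segments, sv$observations, "individuals", sc$truncation)
  seg <- segment_area(seg, sc$truncation)
  seg <- predict_p_segments(det, seg)
  seg$offset <- seg$area * seg$p
  fit <- fit_dsm(seg, model_spec(smooth_spec(c("x", "y"), k = 5),
                                 smooth_spec("sst", k = 6), family = "negbin"))
  vp <- suppressWarnings(varprop_refit(fit, det))
  cv_gam <- analytic_variance(fit, grids, rung = "V_beta")$cv
  D <- dsmflow:::detection_sensitivity(det, seg)
  dbar <- colMeans(D)
  cv_p <- sqrt(drop(dbar %*% det$V_theta %*% dbar))
  se_delta <- sqrt(cv_gam^2 + cv_p^2)
  se_vp <- analytic_variance(vp, grids, rung = "V_beta_theta")$cv
  expect_lt(se_vp, se_delta)
})

test_that("a detection fit without covariance cannot be propagated", {
  fx <- small_fit(seed = 7, family = "poisson")
  det_bad <- fx$det
  det_bad$V_theta <- NULL
  expect_error(varprop_refit(fx$fit, det_bad), class = "dsmflow_spec_error")
  det_sing <- fx$det
  det_sing$V_theta <- matrix(0, 2, 2)
  expect_error(varprop_refit(fx$fit, det_sing), class = "dsmflow_spec_error")
})
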