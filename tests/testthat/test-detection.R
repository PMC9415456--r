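# distances from a truncated half-normal, used to build synthetic fitting
# problems with known truth
rhn <- function(n, sigma, w) {
  u <- stats::runif(n)
  sigma * stats::qnorm((u * (2 * stats::pnorm(w / sigma) - 1) + 1) / 2)
}

test_that("average detection probability matches a Riemann oracle and is monotone", {
  w <- 1
  panels <- 1e5
  mid <- (seq_len(panels) - 0.5) / panels * w
  for (sig in c(0.2, 0.5, 1, 2, 5)) {
    oracle <- mean(exp(-mid^2 / (2 * sig^2)))
    expect_equal(average_p(log(sig), w = w), oracle, tolerance = 1e-6)
  }
  # sigma = w = 1 known value; flat-detection limit; monotonicity in sigma
  expect_equal(average_p(0, w = 1), 0.8556244, tolerance = 1e-6)
  expect_gt(average_p(log(1e6), w = 1), 1 - 1e-9)
  ps <- vapply(seq(-2, 2, by = 0.25), average_p, numeric(1), w = 1)
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("half-normal MLE recovers a known scale and beats the generating parameter", {
  set.seed(101)
  w <- 5.5
  obs <- tibble::tibble(segment_id = "s1", distance = rhn(2000, 2, w), size = 1)
  fit <- fit_detection(obs, truncation = w)
  se <- sqrt(fit$V_theta[1, 1])
  expect_lt(abs(fit$theta[1] - log(2)), 3 * se)
  # MLE's likelihood is at least that of the true generating parameter
  ll_true <- sum(dsmflow:::hn_logdens(obs$distance, 2, w))
  expect_gte(fit$loglik, ll_true)
  expect_symmetric_psd(fit$V_theta)
})

test_that("scaling distances and truncation by c shifts the scale intercept by log c", {
  set.seed(7)
  w <- 2
  x <- rhn(800, 1.2, w)
  f1 <- fit_detection(tibble::tibble(segment_id = "s", distance = x),
                      truncation = w)
  cc <- 3.7
  f2 <- fit_detection(tibble::tibble(segment_id = "s", distance = cc * x),
                      truncation = cc * w)
  expect_equal(f2$theta[1] - f1$theta[1], log(cc), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(f2$loglik - f1$loglik, -length(x) * log(cc), tolerance = 1e-4)
})

test_that("parameter variance shrinks like 1/n", {
  set.seed(42)
  w <- 2
  mean_var <- function(n) {
    vs <- replicate(20, {
      obs <- tibble::tibble(segment_id = "s", distance = rhn(n, 1.2, w))
      fit_detection(obs, truncation = w)$V_theta[1, 1]
    })
    mean(vs)
  }
  ratio <- mean_var(400) / mean_var(800)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})

test_that("covariate model predicts segment-level p consistently", {
  set.seed(5)
  w <- 2
  n <- 600
  bf <- stats::runif(n, 0, 4)
  sig <- exp(log(1.3) - 0.2 * bf)
  obs <- tibble::tibble(segment_id = sprintf("s%03d", sample(40, n, TRUE)),
                        distance = rhn(n, sig, w), size = 1, beaufort = bf)
  fit <- fit_detection(obs, truncation = w, formula = ~beaufort)
  expect_lt(abs(fit$theta["beaufort"] - (-0.2)), 3 * sqrt(fit$V_theta[2, 2]))

  seg <- tibble::tibble(segment_id = c("a", "b"), effort_length = 1,
                        x = 0:1, y = 0, beaufort = c(0, 3))
  out <- predict_p_segments(fit, seg)
  # negative coefficient: rougher seas, smaller p
  expect_gt(out$p[1], out$p[2])
  # matches average_p evaluated manually per segment
  manual <- average_p(fit, z = seg["beaufort"])
  expect_equal(out$p, manual)

  # covariate-free fit gives a constant p vector
  fit0 <- fit_detection(obs, truncation = w)
  out0 <- predict_p_segments(fit0, seg)
  expect_equal(out0$p[1], out0$p[2])

  # unseen factor level errors with its name
  obs_f <- dplyr::mutate(obs, ship = factor(sample(c("A", "B"), n, TRUE)))
  fit_f <- fit_detection(obs_f, truncation = w, formula = ~ship)
  seg_f <- dplyr::mutate(seg, ship = "C")
  expect_error(predict_p_segments(fit_f, seg_f), "C",
               class = "dsmflow_prediction_error")
})

test_that("degenerate all-zero distances hit the scale boundary", {
  obs <- tibble::tibble(segment_id = "s", distance = rep(0, 50))
  fit <- suppressWarnings(try(fit_detection(obs, truncation = 2), silent = TRUE))
  if (inherits(fit, "det_fn")) {
    expect_true(fit$boundary)
  } else {
    expect_s3_class(attr(fit, "condition"), "dsmflow_fit_error")
  }
})

test_that("detection fits serialize to text and back losslessly", {
  set.seed(9)
  obs <- tibble::tibble(segment_id = "s", distance = rhn(300, 1.2, 2),
                        beaufort = stats::runif(300, 0, 4))
  fit <- fit_detection(obs, truncation = 2, formula = ~beaufort)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_detection_fit(fit, f)
  fit2 <- read_detection_fit(f)
  expect_equal(fit2$theta, fit$theta)
  expect_equal(fit2$V_theta, fit$V_theta, tolerance = 1e-12)
  expect_equal(fit2$truncation, fit$truncation)
  seg <- tibble::tibble(segment_id = "a", effort_length = 1, x = 0, y = 0,
                        beaufort = 2)
  expect_equal(predict_p_segments(fit2, seg)$p, predict_p_segments(fit, seg)$p)
})
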