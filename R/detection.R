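#' Fit a half-normal detection function
#'
#' Fits a half-normal detection function to perpendicular distances by
#' maximizing the likelihood conditional on detection, the standard
#' line-transect formulation. The scale parameter may depend on covariates
#' through a log link, `sigma(z) = exp(theta0 + theta' z)`, so detectability
#' can vary with e.g. sea state or observer platform. The parameter
#' covariance `V_theta` (inverse observed information, Hessian by central
#' finite differences) is retained for downstream variance propagation into
#' the spatial model.
#'
#' The per-observation density is
#' `f(x | z) = g(x; sigma(z)) / int_0^w g(u; sigma(z)) du` with
#' `g(x; sigma) = exp(-x^2 / (2 sigma^2))` and truncation distance `w`.
#'
#' @param obs Observation table (see [read_observations()]); distances beyond
#'   `truncation` are dropped before fitting.
#' @param truncation Truncation distance w (> 0), same units as `distance`.
#' @param formula One-sided formula naming scale covariates, e.g.
#'   `~ beaufort + ship`; default `~ 1` (no covariates).
#' @return An object of class `det_fn`: parameter estimates `theta`
#'   (intercept and coefficients on log sigma), covariance `V_theta`,
#'   log-likelihood, AIC, and everything needed to predict per-segment
#'   detection probabilities.
#' @seealso [average_p()], [predict_p_segments()], [varprop_refit()]
#' @export
fit_detection <- function(obs, truncation, formula = ~1) {
  if (!is.numeric(truncation) || truncation <= 0) {
    rlang::abort("truncation must be a single positive distance",
                 class = "dsmflow_domain_error")
  }
  obs <- validate_observations(obs)
  obs <- obs[obs$distance <= truncation, , drop = FALSE]
  if (nrow(obs) < 2) {
    rlang::abort("need at least 2 in-truncation observations",
                 class = "dsmflow_fit_error")
  }
  mf <- stats::model.frame(formula, data = obs)
  Z <- stats::model.matrix(formula, mf)
  xlev <- stats::.getXlevels(stats::terms(formula), mf)
  x <- obs$distance

  lw <- log(truncation)
  nll <- function(theta) {
    lsig <- drop(Z %*% theta)
    # clamp relative to the truncation scale: beyond sigma ~ e^7 w detection
    # is flat to machine precision and the likelihood has a ridge
    lsig <- pmin(pmax(lsig, lw - 10), lw + 7)
    -sum(hn_logdens(x, exp(lsig), truncation))
  }
  # scale of the data suggests a starting intercept (covariates start at 0),
  # but a coarse 1-d grid on the intercept guards against line-search
  # overshoot onto the flat sigma -> Inf ridge of the conditional likelihood
  iqr <- stats::IQR(x)
  start0 <- log(if (iqr > 0) iqr else max(mean(x), truncation / 10))
  grid0 <- lw + seq(-6, 6, by = 0.5)
  cand <- c(start0, grid0)
  vals <- vapply(cand, function(t0) nll(c(t0, rep(0, ncol(Z) - 1))),
                 numeric(1))
  theta0 <- c(cand[which.min(vals)], rep(0, ncol(Z) - 1))
  opt <- stats::optim(theta0, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (opt$convergence == 1) {  # rare slow path: polish with Nelder-Mead
    opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-10))
  }
  if (opt$convergence != 0) {
    rlang::abort(paste0("detection optimizer failed to converge (code ",
                        opt$convergence, "): ", opt$message %||% ""),
                 class = "dsmflow_fit_error")
  }
  theta_hat <- opt$par
  names(theta_hat) <- colnames(Z)
  # lower boundary: degenerate spike at zero; upper: near-uniform distances
  # (detection indistinguishable from certain), both leave theta ill-determined
  boundary <- theta_hat[1] < log(truncation) - 8 ||
    theta_hat[1] > log(truncation) + 5

  H <- fd_hessian(nll, theta_hat)
  V_theta <- tryCatch(solve(H), error = function(e) NULL)
  cov_ok <- !is.null(V_theta) && all(is.finite(V_theta)) &&
    all(eigen(sym(V_theta), symmetric = TRUE, only.values = TRUE)$values > 0)
  if (cov_ok) {
    V_theta <- sym(V_theta)
    dimnames(V_theta) <- list(colnames(Z), colnames(Z))
  }

  structure(list(
    theta = theta_hat,
    V_theta = if (cov_ok) V_theta else NULL,
    loglik = -opt$value,
    aic = 2 * opt$value + 2 * length(theta_hat),
    truncation = truncation,
    formula = formula,
    xlevels = xlev,
    n = nrow(obs),
    distances = x,
    boundary = boundary,
    cov_ok = cov_ok
  ), class = "det_fn")
}

# log conditional density of a half-normal detection at distance x,
# truncated at w: log g(x; sigma) - log int_0^w g
hn_logdens <- function(x, sigma, w) {
  -x^2 / (2 * sigma^2) - log(hn_integral(sigma, w))
}

# int_0^w exp(-u^2/(2 sigma^2)) du via the Gaussian error integral; series
# branch for w << sigma where pnorm(w/sigma) - 0.5 cancels catastrophically
hn_integral <- function(sigma, w) {
  r <- w / sigma
  out <- sigma * sqrt(2 * pi) * (stats::pnorm(r) - 0.5)
  small <- r < 1e-4
  if (any(small)) out[small] <- (w * (1 - r^2 / 6 + r^4 / 40))[small]
  out
}

#' Average detection probability within the truncation strip
#'
#' The probability of detecting an animal uniformly distributed in
#' perpendicular distance over `[0, w]`:
#' `p(z) = (1/w) int_0^w exp(-x^2 / (2 sigma(z)^2)) dx`, evaluated in closed
#' form through the Gaussian error integral. Always in (0, 1]; tends to 1 as
#' `sigma / w` grows (flat detection) and is monotone increasing in sigma.
#'
#' @param theta Detection parameter vector (intercept first) or a `det_fn`
#'   object, in which case its estimates are used.
#' @param z Covariate data frame (one row per evaluation) matching the
#'   detection formula, or `NULL` for a covariate-free model.
#' @param w Truncation distance (> 0); taken from the fit when `theta` is a
#'   `det_fn`.
#' @return Numeric vector of detection probabilities.
#' @export
#' @examples
#' average_p(log(1), w = 1)  # sigma = w = 1: about 0.8556
average_p <- function(theta, z = NULL, w = NULL) {
  if (inherits(theta, "det_fn")) {
    fit <- theta
    w <- w %||% fit$truncation
    return(average_p_fit(fit, z, w))
  }
  if (is.null(w) || w <= 0) {
    rlang::abort("w must be a positive distance", class = "dsmflow_domain_error")
  }
  if (is.null(z)) {
    sigma <- exp(theta[1])
  } else {
    Z <- stats::model.matrix(~., data = as.data.frame(z))
    if (ncol(Z) != length(theta)) {
      rlang::abort("covariate columns do not match length of theta",
                   class = "dsmflow_domain_error")
    }
    sigma <- exp(drop(Z %*% theta))
  }
  hn_integral(sigma, w) / w
}

average_p_fit <- function(fit, z, w) {
  if (is.null(z)) {
    if (length(fit$theta) > 1) {
      rlang::abort("fit has covariates; supply z", class = "dsmflow_domain_error")
    }
    return(hn_integral(exp(fit$theta[1]), w) / w)
  }
  Z <- detection_design(fit, as.data.frame(z))
  sigma <- exp(drop(Z %*% fit$theta))
  hn_integral(sigma, w) / w
}

# rebuild the detection model matrix for new data, respecting training
# factor levels; unseen levels are an error, not silent NA
detection_design <- function(fit, newdata) {
  for (v in names(fit$xlevels)) {
    if (!v %in% names(newdata)) {
      rlang::abort(sprintf("detection covariate '%s' missing", v),
                   class = "dsmflow_prediction_error")
    }
    seen <- fit$xlevels[[v]]
    new_lev <- setdiff(unique(as.character(newdata[[v]])), seen)
    if (length(new_lev) > 0) {
      rlang::abort(sprintf("unseen level(s) in '%s': %s", v,
                           paste(new_lev, collapse = ", ")),
                   class = "dsmflow_prediction_error")
    }
    newdata[[v]] <- factor(newdata[[v]], levels = seen)
  }
  stats::model.matrix(fit$formula, stats::model.frame(fit$formula, newdata,
                                                      xlev = fit$xlevels))
}

#' Per-segment detection probabilities
#'
#' Evaluates the fitted detection function at each segment's covariate values,
#' giving the `p_j` that enters the spatial model's offset. Detection
#' covariates must be available at segment level; observation-level covariates
#' should first be aggregated with [aggregate_detection_covariates()].
#'
#' @param fit A `det_fn` object.
#' @param segments Segment table carrying every detection covariate.
#' @return The segment tibble with a `p` column appended.
#' @export
predict_p_segments <- function(fit, segments) {
  stopifnot(inherits(fit, "det_fn"))
  segments <- validate_segments(segments)
  covs <- all.vars(fit$formula)
  if (length(covs) == 0) {
    segments$p <- rep(unname(average_p_fit(fit, NULL, fit$truncation)),
                      nrow(segments))
  } else {
    miss <- setdiff(covs, names(segments))
    if (length(miss) > 0) {
      rlang::abort(paste0("segment table lacks detection covariate(s): ",
                          paste(miss, collapse = ", ")),
                   class = "dsmflow_prediction_error")
    }
    segments$p <- average_p_fit(fit, segments[covs], fit$truncation)
  }
  segments
}

#' Aggregate observation-level detection covariates to segment level
#'
#' Variance propagation requires detectability to vary only between segments,
#' so observation-level covariates are summarised per segment: mean for
#' numeric covariates, most frequent level for factors/characters (ties break
#' to the first level). Segments without observations receive the overall
#' aggregate.
#'
#' @param segments Segment table.
#' @param obs Observation table holding the covariates.
#' @param vars Character vector of covariate names to aggregate.
#' @return The segment tibble with one new column per covariate.
#' @export
aggregate_detection_covariates <- function(segments, obs, vars) {
  segments <- validate_segments(segments)
  obs <- validate_observations(obs, segments = segments)
  agg_one <- function(x) {
    if (is.numeric(x)) mean(x)
    else names(sort(table(as.character(x)), decreasing = TRUE))[1]
  }
  for (v in vars) {
    if (!v %in% names(obs)) {
      rlang::abort(sprintf("observation table lacks covariate '%s'", v),
                   class = "dsmflow_schema_error")
    }
    per_seg <- obs |>
      dplyr::group_by(.data$segment_id) |>
      dplyr::summarise(.val = agg_one(.data[[v]]), .groups = "drop")
    overall <- agg_one(obs[[v]])
    segments[[v]] <- per_seg$.val[match(segments$segment_id, per_seg$segment_id)]
    segments[[v]][is.na(segments[[v]])] <- overall
  }
  segments
}

#' @export
print.det_fn <- function(x, ...) {
  cat("Half-normal detection function (conditional ML)\n")
  cat(sprintf("  observations: %d, truncation: %g\n", x$n, x$truncation))
  se <- if (!is.null(x$V_theta)) sqrt(diag(x$V_theta)) else rep(NA_real_, length(x$theta))
  est <- data.frame(estimate = x$theta, se = se)
  print(round(est, 4))
  cat(sprintf("  log-likelihood: %.3f  AIC: %.3f\n", x$loglik, x$aic))
  if (isTRUE(x$boundary)) cat("  WARNING: scale at lower boundary\n")
  if (!isTRUE(x$cov_ok)) cat("  WARNING: covariance unavailable (singular Hessian)\n")
  invisible(x)
}

#' Tidy a detection function fit
#'
#' @param x A `det_fn` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error` (log-sigma scale).
#' @export
tidy.det_fn <- function(x, ...) {
  se <- if (!is.null(x$V_theta)) sqrt(diag(x$V_theta)) else rep(NA_real_, length(x$theta))
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta),
                 std.error = unname(se))
}

#' @rdname tidy.det_fn
#' @return For `glance`: one-row tibble with `n`, `logLik`, `AIC`,
#'   `truncation` and the fitted `p` at the average covariate level.
#' @export
glance.det_fn <- function(x, ...) {
  tibble::tibble(n = x$n, logLik = x$loglik, AIC = x$aic,
                 truncation = x$truncation)
}

# write/read a machine-readable detection fit (plain YAML) so the spatial
# stage can run in a separate process
#' Serialize / restore a detection fit
#'
#' @param fit A `det_fn` object.
#' @param path File path (YAML text).
#' @return `write_detection_fit` returns `fit` invisibly;
#'   `read_detection_fit` returns the restored `det_fn`.
#' @export
write_detection_fit <- function(fit, path) {
  stopifnot(inherits(fit, "det_fn"))
  obj <- list(
    theta = as.list(fit$theta),
    V_theta = if (!is.null(fit$V_theta)) apply(fit$V_theta, 1, as.list) else NULL,
    loglik = fit$loglik, aic = fit$aic, truncation = fit$truncation,
    formula = deparse(fit$formula), xlevels = fit$xlevels,
    n = fit$n, boundary = fit$boundary, cov_ok = fit$cov_ok)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(fit)
}

#' @rdname write_detection_fit
#' @export
read_detection_fit <- function(path) {
  obj <- yaml::read_yaml(path)
  theta <- unlist(obj$theta)
  V <- if (!is.null(obj$V_theta)) {
    m <- do.call(rbind, lapply(obj$V_theta, unlist))
    dimnames(m) <- list(names(theta), names(theta))
    sym(m)
  }
  structure(list(
    theta = theta, V_theta = V, loglik = obj$loglik, aic = obj$aic,
    truncation = obj$truncation, formula = stats::as.formula(obj$formula),
    xlevels = obj$xlevels, n = obj$n, boundary = obj$boundary,
    cov_ok = obj$cov_ok), class = "det_fn")
}
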