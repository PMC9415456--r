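#' Propagate detection-function uncertainty into the spatial model
#'
#' Absorbs the detection function's parameter uncertainty into the GAM
#' coefficient covariance by refitting the count model with an extra random
#' effect whose prior covariance is the detection parameter covariance
#' `V_theta`. The random-effect design is the sensitivity matrix
#' `D[j, k] = d log p_j / d theta_k` (central finite differences on the
#' average detection probability), so a draw `delta` of the effect perturbs
#' the log-offset exactly as a first-order change `theta_hat + delta` would.
#' The refit's Bayesian coefficient covariance then carries the joint
#' (detection x spatial) uncertainty, including any covariance between the
#' two — which is why this dominates the delta method whenever detectability
#' varies over segments, and why resulting uncertainty can be smaller as well
#' as larger than the delta-method answer.
#'
#' The smooth terms' smoothing parameters are held at the base fit's
#' estimates and the random-effect penalty weight is fixed at 1 (its scale is
#' already carried by `V_theta`): the method is first-order around the base
#' fit. The detection offset itself stays evaluated at `theta_hat`.
#'
#' A large posterior shift of the detection parameters (any component moving
#' more than `shift_tol` prior SDs) signals disagreement between the
#' detection data and the spatial count data and raises a warning.
#'
#' @param fit A plain `dsm_fit` whose offset used `p_j` from `det_fit`.
#' @param det_fit The `det_fn` the offsets came from; must carry a valid
#'   `V_theta`.
#' @param shift_tol Shift threshold in prior SDs (default 2).
#' @return A `dsm_fit` whose covariance rungs are `V_beta_theta` (and, after
#'   [smoothing_uncertainty()], `V_beta_lambda_theta`), with elements
#'   `varprop$delta_theta` (posterior mean shift of the detection
#'   parameters) and `varprop$shift_flag`.
#' @export
varprop_refit <- function(fit, det_fit, shift_tol = 2) {
  stopifnot(inherits(fit, "dsm_fit"), inherits(det_fit, "det_fn"))
  if (!is.null(fit$varprop)) {
    rlang::abort("fit already variance-propagated", class = "dsmflow_spec_error")
  }
  if (is.null(det_fit$V_theta)) {
    rlang::abort(paste0("detection fit has no usable V_theta (singular ",
                        "Hessian); consider the delta-method route for a ",
                        "constant-p model"),
                 class = "dsmflow_spec_error")
  }
  prior_prec <- tryCatch(solve(det_fit$V_theta), error = function(e) {
    rlang::abort(paste0("V_theta is singular; consider the delta-method ",
                        "route for a constant-p model"),
                 class = "dsmflow_spec_error", parent = e)
  })

  D <- detection_sensitivity(det_fit, fit$data)
  dat <- fit$data
  dat$.detD <- D

  base_form <- stats::formula(fit$gam)
  form <- stats::update.formula(base_form, . ~ . + .detD)
  environment(form) <- environment(base_form)
  base_sp <- fit$gam$sp
  paraPen <- list(.detD = list(sym(prior_prec)))
  g <- fit_gam_checked(form, dat, fixed_family(fit),
                       sp = c(1, base_sp), paraPen = paraPen)

  cf <- stats::coef(g)
  det_idx <- grep("^\\.detD", names(cf))
  if (length(det_idx) != ncol(D)) {
    rlang::abort("internal error: detection random-effect block not located",
                 class = "dsmflow_fit_error")
  }
  delta_theta <- unname(cf[det_idx])
  prior_sd <- sqrt(diag(det_fit$V_theta))
  shift_flag <- any(abs(delta_theta) > shift_tol * prior_sd)
  if (shift_flag) {
    rlang::warn(paste0("detection parameters shifted more than ", shift_tol,
                       " prior SDs during variance propagation; detection ",
                       "and spatial data may conflict"))
  }

  out <- fit
  out$gam <- g
  out$data <- dat
  out$V_beta_lambda <- NULL
  out$varprop <- list(
    q = ncol(D), D = D, paraPen = paraPen, base_sp = base_sp,
    det_fit = det_fit, delta_theta = delta_theta, shift_flag = shift_flag,
    det_index = det_idx)
  out
}

# D[j, k] = d log p_j / d theta_k at theta_hat, by central finite differences
detection_sensitivity <- function(det_fit, segments, rel_step = 1e-4) {
  covs <- all.vars(det_fit$formula)
  z <- if (length(covs) > 0) {
    miss <- setdiff(covs, names(segments))
    if (length(miss) > 0) {
      rlang::abort(paste0("segment table lacks detection covariate(s): ",
                          paste(miss, collapse = ", ")),
                   class = "dsmflow_prediction_error")
    }
    segments[covs]
  } else NULL
  Z <- if (is.null(z)) matrix(1, nrow(segments), 1)
       else detection_design(det_fit, as.data.frame(z))
  w <- det_fit$truncation
  logp <- function(theta) log(hn_integral(exp(drop(Z %*% theta)), w) / w)
  D <- fd_jacobian(logp, det_fit$theta, rel_step = rel_step)
  colnames(D) <- names(det_fit$theta)
  D
}

#' Extract a rung of the propagated covariance ladder
#'
#' Convenience selector on a variance-propagated fit: with
#' `include_lambda = FALSE` returns `V_beta_theta`; with
#' `include_lambda = TRUE` returns `V_beta_lambda_theta` (requires
#' [smoothing_uncertainty()] to have been run on the refit).
#'
#' @param result A variance-propagated `dsm_fit` from [varprop_refit()].
#' @param include_lambda Also include smoothing-parameter uncertainty?
#' @return Symmetric PSD covariance matrix matched to `coef(result)`.
#' @export
combined_covariance <- function(result, include_lambda = FALSE) {
  stopifnot(inherits(result, "dsm_fit"))
  if (is.null(result$varprop)) {
    rlang::abort("not a variance-propagated fit; run varprop_refit() first",
                 class = "dsmflow_spec_error")
  }
  dsm_covariance(result,
                 rung = if (include_lambda) "V_beta_lambda_theta" else "V_beta_theta")
}

#' Variance-propagation report
#'
#' @param result A variance-propagated `dsm_fit`.
#' @return Tibble with the detection parameters' posterior shifts in prior-SD
#'   units and the overall shift flag as an attribute.
#' @export
varprop_report <- function(result) {
  stopifnot(inherits(result, "dsm_fit"), !is.null(result$varprop))
  vp <- result$varprop
  prior_sd <- sqrt(diag(vp$det_fit$V_theta))
  out <- tibble::tibble(
    term = names(vp$det_fit$theta),
    delta = vp$delta_theta,
    prior_sd = unname(prior_sd),
    shift_sds = vp$delta_theta / unname(prior_sd))
  attr(out, "shift_flag") <- vp$shift_flag
  out
}
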