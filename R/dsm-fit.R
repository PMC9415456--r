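#' Specify a smooth term
#'
#' Describes one smooth component of the density surface: a univariate
#' penalized regression spline, or a tensor-product surface over two
#' covariates (the usual choice for a bivariate spatial smooth of location).
#' With `shrinkage = TRUE` (default) a shrinkage basis is used, whose penalty
#' can shrink the whole term to (near-)zero effect; term selection then
#' happens inside the fit instead of by stepwise AIC/p-value deletion, and
#' the retained-but-shrunk terms contribute structural uncertainty to the
#' coefficient covariance.
#'
#' @param covariates Character vector of 1 (univariate) or 2 (tensor product)
#'   covariate names present in the segment table.
#' @param k Basis dimension per margin (>= 4).
#' @param shrinkage Use a shrinkage basis (`bs = "ts"`)?
#' @return A `smooth_spec` record.
#' @export
smooth_spec <- function(covariates, k = 10, shrinkage = TRUE) {
  if (!length(covariates) %in% 1:2) {
    rlang::abort("a smooth takes 1 or 2 covariates", class = "dsmflow_spec_error")
  }
  if (any(k < 4)) {
    rlang::abort("basis dimension k must be >= 4", class = "dsmflow_spec_error")
  }
  structure(list(covariates = as.character(covariates), k = k,
                 type = if (length(covariates) == 1) "univariate" else "tensor_2d",
                 shrinkage = isTRUE(shrinkage)),
            class = "smooth_spec")
}

#' Specify the count model
#'
#' Collects the smooth terms and response family of the spatial count model.
#' The model for segment counts is
#' `E(n_j) = offset_j * exp(beta_0 + sum_m f_m(...))` with a log link; the
#' offset carries segment area, detectability and any correction factors.
#'
#' @param ... `smooth_spec` terms (or a single list of them).
#' @param family `"poisson"` or `"negbin"` (negative binomial with size
#'   estimated alongside the smoothing parameters).
#' @return A `model_spec` record.
#' @export
#' @examples
#' model_spec(smooth_spec(c("x", "y"), k = 5), smooth_spec("sst", k = 8),
#'            family = "negbin")
model_spec <- function(..., family = c("poisson", "negbin")) {
  family <- match.arg(family)
  smooths <- list(...)
  if (length(smooths) == 1 && !inherits(smooths[[1]], "smooth_spec") &&
      is.list(smooths[[1]])) {
    smooths <- smooths[[1]]
  }
  ok <- vapply(smooths, inherits, logical(1), "smooth_spec")
  if (length(smooths) > 0 && !all(ok)) {
    rlang::abort("all terms must be smooth_spec objects",
                 class = "dsmflow_spec_error")
  }
  structure(list(smooths = smooths, family = family), class = "model_spec")
}

smooth_term_text <- function(sm) {
  bs <- if (sm$shrinkage) "ts" else "tp"
  if (sm$type == "univariate") {
    sprintf('s(%s, k = %d, bs = "%s")', sm$covariates[1], sm$k[1], bs)
  } else {
    kk <- if (length(sm$k) == 2) sm$k else rep(sm$k[1], 2)
    sprintf('te(%s, %s, k = c(%d, %d), bs = "%s")',
            sm$covariates[1], sm$covariates[2], kk[1], kk[2], bs)
  }
}

spec_formula <- function(spec, response = "count", with_offset = FALSE) {
  rhs <- if (length(spec$smooths) == 0) "1"
         else paste(vapply(spec$smooths, smooth_term_text, character(1)),
                    collapse = " + ")
  if (with_offset) rhs <- paste(rhs, "+ offset(.log_offset)")
  stats::as.formula(paste(response, "~", rhs))
}

spec_covariates <- function(spec) {
  unique(unlist(lapply(spec$smooths, `[[`, "covariates")))
}

#' Build the model design matrix and penalties
#'
#' Constructs, for a covariate table, the model matrix that maps coefficients
#' to the linear predictor, together with the quadratic penalty matrices of
#' each smooth. Each smooth is centred (sum-to-zero constraint absorbed into
#' the basis) so the intercept stays identifiable; a tensor-product term
#' carries one penalty per margin.
#'
#' @param spec A `model_spec`.
#' @param data Covariate table with at least one row.
#' @return List with `X` (model matrix, intercept first), `penalties` (list
#'   of penalty matrices expanded to full coefficient dimension), and
#'   `term_labels`.
#' @export
build_design <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  if (nrow(data) < 1) {
    rlang::abort("data must have at least one row", class = "dsmflow_spec_error")
  }
  for (v in spec_covariates(spec)) {
    if (!v %in% names(data)) {
      rlang::abort(sprintf("covariate '%s' not in data", v),
                   class = "dsmflow_spec_error")
    }
    if (length(unique(data[[v]])) < 2) {
      rlang::abort(sprintf("covariate '%s' is constant; cannot place knots", v),
                   class = "dsmflow_basis_error")
    }
  }
  X <- matrix(1, nrow(data), 1)
  colnames(X) <- "(Intercept)"
  penalties <- list()
  labels <- character(0)
  for (sm in spec$smooths) {
    sc <- mgcv::smoothCon(eval(str2lang(smooth_term_text(sm)),
                               envir = asNamespace("mgcv")),
                          data = data, absorb.cons = TRUE)[[1]]
    start <- ncol(X)
    X <- cbind(X, sc$X)
    for (S in sc$S) {
      penalties <- c(penalties, list(list(S = S, first = start + 1,
                                          last = start + ncol(sc$X))))
    }
    labels <- c(labels, sc$label)
  }
  p <- ncol(X)
  penalties <- lapply(penalties, function(pen) {
    full <- matrix(0, p, p)
    idx <- seq(pen$first, pen$last)
    # penalty block may be smaller than the term width (tensor margins are
    # full width after expansion in mgcv, so dimensions always agree here)
    full[idx, idx] <- pen$S
    full
  })
  list(X = X, penalties = penalties, term_labels = labels)
}

#' Fit a density surface model to segment counts
#'
#' Fits the penalized regression spline GAM
#' `E(n_j) = offset_j * exp(eta_j)` by REML, where `eta` contains an
#' intercept and the smooth terms of `spec`, and the offset is the product of
#' segment area, detection probability and any corrections already applied to
#' the observed counts. REML gives an empirical-Bayes posterior
#' `beta | lambda ~ N(beta_hat, V_beta)` that downstream posterior simulation
#' samples from.
#'
#' @param segments Segment table with a `count` column (see
#'   [attach_counts()]) and all model covariates.
#' @param spec A `model_spec`.
#' @param offset Per-segment positive offset on the response scale
#'   (`A_j * p_j * ...`). Defaults to the `offset` column of `segments`.
#' @param sp Optional fixed smoothing parameters (vector, one per penalty);
#'   when supplied REML estimation of lambda is skipped and there is no
#'   smoothing-parameter uncertainty.
#' @return A `dsm_fit` object: the underlying [mgcv::gam()] fit plus the
#'   coefficient covariance ladder and the training covariate ranges used to
#'   flag extrapolation at prediction time.
#' @export
fit_dsm <- function(segments, spec, offset = NULL, sp = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  segments <- validate_segments(segments)
  if (!"count" %in% names(segments)) {
    rlang::abort("segments need a 'count' column; see attach_counts()",
                 class = "dsmflow_spec_error")
  }
  if (all(segments$count == 0)) {
    rlang::abort(paste0("all counts are zero; check the response, or fit an ",
                        "intercept-only model deliberately"),
                 class = "dsmflow_fit_error")
  }
  offset <- offset %||% segments[["offset"]]
  if (is.null(offset)) {
    rlang::abort("supply `offset` or an offset column in segments",
                 class = "dsmflow_spec_error")
  }
  if (any(!is.finite(offset)) || any(offset <= 0)) {
    rlang::abort("offset must be finite and strictly positive",
                 class = "dsmflow_invariant_error")
  }
  dat <- as.data.frame(segments)
  dat$.log_offset <- log(offset)
  form <- spec_formula(spec, with_offset = TRUE)
  fam <- switch(spec$family, poisson = stats::poisson(link = "log"),
                negbin = mgcv::nb())
  g <- fit_gam_checked(form, dat, fam, sp = sp)

  covs <- spec_covariates(spec)
  ranges <- lapply(dat[covs], function(v) if (is.numeric(v)) range(v) else NULL)

  structure(list(
    gam = g,
    spec = spec,
    data = dat,
    sp_fixed = !is.null(sp),
    cov_ranges = ranges,
    V_beta_lambda = NULL,
    varprop = NULL
  ), class = "dsm_fit")
}

fit_gam_checked <- function(form, dat, fam, sp = NULL, paraPen = NULL) {
  g <- tryCatch(
    mgcv::gam(form, family = fam, data = dat, method = "REML",
              sp = sp, paraPen = paraPen),
    error = function(e) {
      rlang::abort(paste0("DSM fit failed: ", conditionMessage(e)),
                   class = "dsmflow_fit_error", parent = e)
    })
  if (!g$converged) {
    rlang::abort("penalized IRLS did not converge", class = "dsmflow_fit_error")
  }
  g
}

#' Coefficient estimates and the covariance ladder
#'
#' Accessors for the fitted coefficient vector and the requested rung of the
#' covariance ladder: `V_beta` (conditional on the smoothing parameters),
#' `V_beta_lambda` (plus smoothing-parameter uncertainty, see
#' [smoothing_uncertainty()]), and — after [varprop_refit()] —
#' `V_beta_theta` / `V_beta_lambda_theta`, which additionally absorb
#' detection-function parameter uncertainty.
#'
#' @param fit A `dsm_fit`.
#' @param rung One of `"V_beta"`, `"V_beta_lambda"`, `"V_beta_theta"`,
#'   `"V_beta_lambda_theta"`.
#' @return Symmetric positive semi-definite covariance matrix matched to
#'   `coef(fit)`.
#' @export
dsm_covariance <- function(fit, rung = c("V_beta", "V_beta_lambda",
                                         "V_beta_theta", "V_beta_lambda_theta")) {
  rung <- match.arg(rung)
  stopifnot(inherits(fit, "dsm_fit"))
  has_theta <- !is.null(fit$varprop)
  if (grepl("theta", rung) && !has_theta) {
    rlang::abort("detection uncertainty not propagated; run varprop_refit()",
                 class = "dsmflow_spec_error")
  }
  if (!grepl("theta", rung) && has_theta) {
    rlang::abort(paste0("this is a variance-propagated fit; its covariance ",
                        "rungs are V_beta_theta / V_beta_lambda_theta"),
                 class = "dsmflow_spec_error")
  }
  if (grepl("lambda", rung)) {
    if (is.null(fit$V_beta_lambda)) {
      rlang::abort("smoothing-parameter correction unavailable; run smoothing_uncertainty()",
                   class = "dsmflow_spec_error")
    }
    return(fit$V_beta_lambda)
  }
  sym(stats::vcov(fit$gam))
}

#' @rdname dsm_covariance
#' @param object A `dsm_fit`.
#' @param ... Unused.
#' @export
coef.dsm_fit <- function(object, ...) stats::coef(object$gam)

#' Add smoothing-parameter uncertainty to the coefficient covariance
#'
#' REML point-estimates the smoothing parameters lambda; treating them as
#' known understates coefficient uncertainty. This correction is
#' `V_beta_lambda = V_beta + J V_rho J'` where `rho = log(lambda)`,
#' `J = d beta_hat / d rho` (central finite differences, refitting at
#' perturbed fixed rho) and `V_rho` is the inverse Hessian of the negative
#' REML criterion at its optimum. The correction is a PSD add-on: it can only
#' increase uncertainty. When the fit used user-fixed smoothing parameters
#' there is nothing to correct and `V_beta_lambda = V_beta`.
#'
#' @param fit A `dsm_fit` (plain or variance-propagated).
#' @param rel_step Relative finite-difference step on the log smoothing
#'   parameters.
#' @return The fit with `V_beta_lambda` filled in.
#' @export
smoothing_uncertainty <- function(fit, rel_step = 1e-2) {
  stopifnot(inherits(fit, "dsm_fit"))
  rho_hat <- log(gam_sp(fit))
  if (fit$sp_fixed || length(rho_hat) == 0) {
    fit$V_beta_lambda <- sym(stats::vcov(fit$gam))
    return(fit)
  }
  refit <- refit_at_rho_fn(fit)
  cache <- new.env(parent = emptyenv())
  memo <- function(rho) {
    key <- paste(signif(rho, 12), collapse = ",")
    if (is.null(cache[[key]])) cache[[key]] <- refit(rho)
    cache[[key]]
  }
  J <- fd_jacobian(function(r) memo(r)$beta, rho_hat, rel_step = rel_step)
  H <- fd_hessian(function(r) memo(r)$reml, rho_hat, rel_step = rel_step)
  V_beta <- sym(stats::vcov(fit$gam))
  V_rho <- tryCatch(solve(sym(H)), error = function(e) NULL)
  if (is.null(V_rho) || !is_psd(V_rho)) {
    rlang::warn("REML Hessian not positive definite; smoothing-parameter correction skipped")
    fit$V_beta_lambda <- V_beta
    return(fit)
  }
  fit$V_beta_lambda <- sym(V_beta + J %*% V_rho %*% t(J))
  fit
}

# smoothing parameters of the underlying gam, excluding any fixed
# variance-propagation penalty (which always comes first in full.sp)
gam_sp <- function(fit) {
  if (!is.null(fit$varprop)) fit$varprop$base_sp else fit$gam$sp
}

# closure refitting the model at fixed log smoothing parameters, returning
# the coefficient vector and the REML criterion value there
refit_at_rho_fn <- function(fit) {
  dat <- fit$data
  form <- stats::formula(fit$gam)
  fam <- fixed_family(fit)
  paraPen <- fit$varprop$paraPen
  function(rho) {
    sp <- if (is.null(paraPen)) exp(rho) else c(1, exp(rho))
    g <- fit_gam_checked(form, dat, fam, sp = sp, paraPen = paraPen)
    list(beta = stats::coef(g), reml = g$gcv.ubre)
  }
}

# family object with any dispersion/size parameter frozen at its estimate,
# for refits at perturbed smoothing parameters
fixed_family <- function(fit) {
  if (fit$spec$family == "negbin") {
    mgcv::negbin(exp(fit$gam$family$getTheta()))
  } else {
    stats::poisson(link = "log")
  }
}

#' Linear predictor over a prediction grid
#'
#' Evaluates the stored spline bases (training knots and constraints) at one
#' period's grid cells, returning the linear predictor `eta = X beta_hat`,
#' the prediction matrix itself, and a per-cell flag marking extrapolation —
#' cells where any model covariate lies outside the range seen during
#' training, where spline behaviour is unconstrained by data.
#'
#' @param fit A `dsm_fit` (plain or variance-propagated).
#' @param grid One period's cells: a data frame with the model covariates
#'   (and usually `cell_id`, `cell_area`).
#' @return List with `eta`, `X` (cells x coefficients), and logical
#'   `extrapolated`.
#' @export
predict_eta <- function(fit, grid) {
  stopifnot(inherits(fit, "dsm_fit"))
  grid <- as.data.frame(grid)
  covs <- spec_covariates(fit$spec)
  miss <- setdiff(covs, names(grid))
  if (length(miss) > 0) {
    rlang::abort(paste0("prediction grid lacks covariate(s): ",
                        paste(miss, collapse = ", ")),
                 class = "dsmflow_prediction_error")
  }
  X <- prediction_matrix(fit, grid)
  eta <- unname(drop(X %*% stats::coef(fit$gam)))
  extrap <- rep(FALSE, nrow(grid))
  for (v in covs) {
    r <- fit$cov_ranges[[v]]
    if (!is.null(r)) extrap <- extrap | grid[[v]] < r[1] | grid[[v]] > r[2]
  }
  list(eta = eta, X = X, extrapolated = extrap)
}

# lpmatrix for new data; a variance-propagated fit carries extra detection
# random-effect columns which are zero for prediction (density predictions
# do not involve the detection offset, but the coefficient covariance block
# structure must be preserved)
prediction_matrix <- function(fit, grid) {
  nd <- grid
  nd$.log_offset <- 0
  if (!is.null(fit$varprop)) {
    nd$.detD <- matrix(0, nrow(grid), fit$varprop$q)
  }
  mgcv::predict.gam(fit$gam, newdata = nd, type = "lpmatrix",
                    newdata.guaranteed = TRUE)
}

#' @export
print.dsm_fit <- function(x, ...) {
  cat("Density surface model fit (REML", x$spec$family, "GAM)\n")
  cat(sprintf("  segments: %d, coefficients: %d\n",
              nrow(x$data), length(stats::coef(x$gam))))
  if (!is.null(x$varprop)) {
    cat("  detection-function uncertainty propagated (varprop refit)\n")
    if (x$varprop$shift_flag)
      cat("  WARNING: detection parameters shifted > 2 prior SDs\n")
  }
  if (!is.null(x$V_beta_lambda))
    cat("  smoothing-parameter uncertainty correction available\n")
  cat(sprintf("  REML: %.4f\n", x$gam$gcv.ubre))
  invisible(x)
}

#' Tidy a density surface model fit
#'
#' @param x A `dsm_fit`.
#' @param ... Unused.
#' @return Per-smooth tibble with `term`, `edf`, and the penalty count.
#' @export
tidy.dsm_fit <- function(x, ...) {
  g <- x$gam
  if (length(g$smooth) == 0) {
    return(tibble::tibble(term = character(), edf = numeric()))
  }
  tibble::tibble(
    term = vapply(g$smooth, `[[`, character(1), "label"),
    edf = vapply(g$smooth, function(s) {
      idx <- seq(s$first.para, s$last.para)
      sum(g$edf[idx])
    }, numeric(1)))
}

#' @rdname tidy.dsm_fit
#' @return For `glance`: one-row tibble with family, total edf, deviance
#'   explained, REML score and segment count.
#' @export
glance.dsm_fit <- function(x, ...) {
  g <- x$gam
  tibble::tibble(
    family = x$spec$family,
    edf = sum(g$edf),
    deviance = g$deviance,
    null.deviance = g$null.deviance,
    reml = g$gcv.ubre,
    nobs = nrow(x$data))
}
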