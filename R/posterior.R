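#' Sample coefficient vectors from the approximate posterior
#'
#' Draws `B` coefficient vectors `beta_b ~ N(beta_hat, V*)` where `V*` is the
#' requested rung of the covariance ladder. Each draw, pushed through
#' prediction, yields one plausible density surface; the spread of any
#' summary over draws is its uncertainty. The default sampler is exact
#' multivariate-normal simulation via a Cholesky factor (with escalating
#' diagonal jitter `1e-10 .. 1e-6` of the mean diagonal if the matrix is
#' semi-definite at machine precision). When the Gaussian approximation to
#' the posterior is in doubt, a random-walk Metropolis–Hastings sampler
#' targeting the penalized likelihood is available.
#'
#' @param fit A `dsm_fit` (plain or variance-propagated), or a bare
#'   `list(beta = , V = )` for low-level use.
#' @param B Number of draws (>= 2).
#' @param seed RNG seed; the same seed always yields the same draws.
#' @param rung Covariance rung, see [dsm_covariance()]; ignored for a bare
#'   list.
#' @param sampler `"mvn"` (default) or `"rw_metropolis"`.
#' @param rw_scale Random-walk proposal scale (multiplies `chol(V*)`).
#' @param burnin,thin Metropolis–Hastings burn-in and thinning.
#' @return A `B x p` matrix of draws with attribute `beta_hat`.
#' @export
sample_coefficients <- function(fit, B, seed = NULL,
                                rung = "V_beta",
                                sampler = c("mvn", "rw_metropolis"),
                                rw_scale = 0.25, burnin = 200, thin = 2) {
  sampler <- match.arg(sampler)
  if (B < 2) rlang::abort("B must be >= 2", class = "dsmflow_spec_error")
  if (inherits(fit, "dsm_fit")) {
    beta <- stats::coef(fit$gam)
    V <- dsm_covariance(fit, rung = rung)
  } else {
    beta <- fit$beta
    V <- fit$V
  }
  p <- length(beta)
  if (!is.null(seed)) set.seed(seed)

  if (sampler == "mvn") {
    if (max(abs(V)) == 0) {
      draws <- matrix(rep(beta, each = B), B, p)
    } else {
      U <- chol_with_jitter(V)
      z <- matrix(stats::rnorm(B * p), B, p)
      draws <- matrix(rep(beta, each = B), B, p) + z %*% U
    }
  } else {
    if (!inherits(fit, "dsm_fit")) {
      rlang::abort("rw_metropolis requires a dsm_fit (it targets the penalized likelihood)",
                   class = "dsmflow_spec_error")
    }
    draws <- rw_metropolis_draws(fit, V, B, rw_scale, burnin, thin)
  }
  colnames(draws) <- names(beta)
  attr(draws, "beta_hat") <- beta
  draws
}

# random-walk MH on the penalized log-likelihood of the fitted model;
# proposal N(0, rw_scale^2 V*)
rw_metropolis_draws <- function(fit, V, B, rw_scale, burnin, thin) {
  g <- fit$gam
  X <- stats::model.matrix(g)
  y <- g$y
  off <- fit$data$.log_offset
  S <- total_penalty(fit)
  fam <- fit$spec$family
  size <- if (fam == "negbin") exp(g$family$getTheta()) else NULL
  logpost <- function(beta) {
    mu <- exp(pmin(drop(X %*% beta) + off, 30))
    ll <- if (fam == "negbin") {
      sum(stats::dnbinom(y, mu = mu, size = size, log = TRUE))
    } else {
      sum(stats::dpois(y, lambda = mu, log = TRUE))
    }
    ll - 0.5 * drop(beta %*% S %*% beta)
  }
  U <- chol_with_jitter(V) * rw_scale
  p <- ncol(X)
  beta <- stats::coef(g)
  lp <- logpost(beta)
  keep <- matrix(NA_real_, B, p)
  stored <- 0L
  iter <- 0L
  total <- burnin + B * thin
  while (stored < B) {
    iter <- iter + 1L
    prop <- beta + drop(stats::rnorm(p) %*% U)
    lp_prop <- logpost(prop)
    if (log(stats::runif(1)) < lp_prop - lp) {
      beta <- prop
      lp <- lp_prop
    }
    if (iter > burnin && (iter - burnin) %% thin == 0) {
      stored <- stored + 1L
      keep[stored, ] <- beta
    }
    if (iter > 100 * total) break  # safety; cannot realistically trigger
  }
  keep
}

# sum of lambda-weighted smooth penalties (plus the fixed detection
# random-effect precision for a variance-propagated fit), full dimension
total_penalty <- function(fit) {
  g <- fit$gam
  p <- length(stats::coef(g))
  S <- matrix(0, p, p)
  k <- 0L
  for (sm in g$smooth) {
    idx <- seq(sm$first.para, sm$last.para)
    for (l in seq_along(sm$S)) {
      k <- k + 1L
      S[idx, idx] <- S[idx, idx] + gam_sp(fit)[k] * sm$S[[l]]
    }
  }
  if (!is.null(fit$varprop)) {
    idx <- fit$varprop$det_index
    S[idx, idx] <- S[idx, idx] + fit$varprop$paraPen$.detD[[1]]
  }
  S
}

#' Stream posterior abundance predictions over time-indexed grids
#'
#' The core prediction loop: for each time period `t` the prediction matrix
#' `X_t` is built once, every coefficient draw is pushed through
#' `N*_{b,t} = cell_area * linkinv(X_t beta_b)` and the resulting
#' `cells x B` block is folded into online per-cell accumulators (overall and
#' per grouping level) and per-period totals. The full draws array is never
#' stored. Detectability and corrections are survey offsets — they correct
#' observed counts — so they are not applied to predictions, which target
#' true abundance.
#'
#' Cells whose covariates fall outside the training range are flagged as
#' extrapolating; by default they are retained (and counted), or they can be
#' excluded or winsorized (covariates clamped to the training range).
#'
#' @param fit A `dsm_fit`.
#' @param grids Long prediction-grid tibble (see [read_prediction_grids()]).
#' @param draws Draw matrix from [sample_coefficients()].
#' @param period_groups Optional tibble mapping `period` to grouping labels
#'   (e.g. columns `month`, `year`) for grouped summaries.
#' @param extrapolation `"keep"` (default), `"exclude"` or `"winsorize"`.
#' @param linkinv Inverse link applied to the linear predictor; defaults to
#'   the fit's family (exp for the log link). An identity override supports
#'   linear-model validation of the simulation machinery.
#' @return An `abundance_stream` object; see [summarize_cells()] and
#'   [abundance_series()].
#' @export
predict_abundance_draws <- function(fit, grids, draws, period_groups = NULL,
                                    extrapolation = c("keep", "exclude", "winsorize"),
                                    linkinv = NULL) {
  extrapolation <- match.arg(extrapolation)
  stopifnot(inherits(fit, "dsm_fit"))
  grids <- validate_grids(grids)
  linkinv <- linkinv %||% fit$gam$family$linkinv
  periods <- unique(grids$period)
  cell_ids <- unique(grids$cell_id)
  d <- length(cell_ids)
  B <- nrow(draws)

  overall <- welford_init(d)
  group_acc <- list()
  group_cols <- if (!is.null(period_groups)) setdiff(names(period_groups), "period")
                else character(0)
  totals <- matrix(NA_real_, length(periods), B,
                   dimnames = list(as.character(periods), NULL))
  info <- vector("list", length(periods))
  tdraws <- t(draws)  # p x B, formed once

  for (ti in seq_along(periods)) {
    gt <- grids[grids$period == periods[ti], , drop = FALSE]
    if (nrow(gt) == 0) {
      rlang::warn(sprintf("period '%s' has no usable cells; skipped", periods[ti]))
      info[[ti]] <- tibble::tibble(period = periods[ti], n_cells = 0L,
                                   n_extrapolated = 0L, skipped = TRUE)
      next
    }
    pe <- predict_eta(fit, gt)
    extrap <- pe$extrapolated
    if (extrapolation == "exclude" && any(extrap)) {
      gt <- gt[!extrap, , drop = FALSE]
      pe <- predict_eta(fit, gt)
      extrap_n <- sum(extrap)
      extrap <- pe$extrapolated
    } else if (extrapolation == "winsorize" && any(extrap)) {
      extrap_n <- sum(extrap)
      for (v in names(fit$cov_ranges)) {
        r <- fit$cov_ranges[[v]]
        if (!is.null(r)) gt[[v]] <- pmin(pmax(gt[[v]], r[1]), r[2])
      }
      pe <- predict_eta(fit, gt)
    } else {
      extrap_n <- sum(extrap)
    }
    if (nrow(gt) == 0) {
      rlang::warn(sprintf("period '%s' has no usable cells; skipped", periods[ti]))
      info[[ti]] <- tibble::tibble(period = periods[ti], n_cells = 0L,
                                   n_extrapolated = extrap_n, skipped = TRUE)
      next
    }
    N <- gt$cell_area * linkinv(pe$X %*% tdraws)  # cells x B
    idx <- match(gt$cell_id, cell_ids)
    overall <- welford_add_batch(overall, N, idx)
    for (gc in group_cols) {
      lab <- period_groups[[gc]][match(periods[ti], period_groups$period)]
      key <- paste(gc, lab, sep = ":")
      if (is.null(group_acc[[key]])) {
        group_acc[[key]] <- list(col = gc, label = lab, acc = welford_init(d),
                                 n_periods = 0L)
      }
      group_acc[[key]]$acc <- welford_add_batch(group_acc[[key]]$acc, N, idx)
      group_acc[[key]]$n_periods <- group_acc[[key]]$n_periods + 1L
    }
    totals[ti, ] <- colSums(N)
    info[[ti]] <- tibble::tibble(period = periods[ti], n_cells = nrow(gt),
                                 n_extrapolated = extrap_n, skipped = FALSE)
  }

  structure(list(
    cell_ids = cell_ids,
    overall = overall,
    groups = group_acc,
    period_groups = period_groups,
    period_totals = totals,
    period_info = purrr::list_rbind(info),
    B = B
  ), class = "abundance_stream")
}

#' @export
print.abundance_stream <- function(x, ...) {
  used <- !x$period_info$skipped
  cat("Streamed posterior abundance summaries\n")
  cat(sprintf("  draws: %d, periods: %d (%d skipped), cells: %d\n",
              x$B, nrow(x$period_info), sum(!used), length(x$cell_ids)))
  cat(sprintf("  extrapolating cell-periods: %d\n",
              sum(x$period_info$n_extrapolated)))
  invisible(x)
}

#' Per-cell abundance mean and SE maps
#'
#' Summarizes the streamed posterior draws per prediction cell: the empirical
#' mean and standard error over all draw-period combinations, either overall
#' or within each level of a grouping (e.g. per year or per month). Cells
#' missing from some periods are summarized over the periods where they
#' appear and flagged as `partial`.
#'
#' @param stream An `abundance_stream`.
#' @param grouping `"overall"` or the name of a grouping column supplied as
#'   `period_groups` (e.g. `"year"`, `"month"`).
#' @return Tibble with `cell_id`, (`group`,) `mean`, `se`, `n` and `partial`.
#' @export
summarize_cells <- function(stream, grouping = "overall") {
  stopifnot(inherits(stream, "abundance_stream"))
  if (grouping == "overall") {
    fin <- welford_finalize(stream$overall)
    if (all(fin$n < 2)) {
      rlang::abort("need at least 2 accumulated draw-periods per cell",
                   class = "dsmflow_spec_error")
    }
    return(tibble::tibble(cell_id = stream$cell_ids, mean = fin$mean,
                          se = fin$sd, n = fin$n,
                          partial = fin$n < max(fin$n)))
  }
  sel <- purrr::keep(stream$groups, \(gr) gr$col == grouping)
  if (length(sel) == 0) {
    rlang::abort(sprintf("no accumulators for grouping '%s'", grouping),
                 class = "dsmflow_spec_error")
  }
  purrr::map(sel, function(gr) {
    fin <- welford_finalize(gr$acc)
    tibble::tibble(cell_id = stream$cell_ids, group = gr$label,
                   mean = fin$mean, se = fin$sd, n = fin$n,
                   partial = fin$n < max(fin$n))
  }) |> purrr::list_rbind()
}

#' Abundance time series with log-normal intervals
#'
#' Aggregates the per-period total-abundance draws into a time series: within
#' each group (e.g. month) the per-draw totals are averaged over the group's
#' periods, then summarized over draws into a point estimate, SE, CV and a
#' log-normal interval.
#'
#' @param stream An `abundance_stream`.
#' @param grouping `"period"` for one entry per period, or a grouping column
#'   from `period_groups`.
#' @param point `"mean"` (default) or `"median"` of the draws.
#' @param level Interval coverage (default 0.95).
#' @return An `abundance_series` tibble: `group`, `estimate`, `se`, `cv`,
#'   `lower`, `upper`.
#' @export
abundance_series <- function(stream, grouping = "period", point = c("mean", "median"),
                             level = 0.95) {
  stopifnot(inherits(stream, "abundance_stream"))
  point <- match.arg(point)
  used <- !stream$period_info$skipped
  tot <- stream$period_totals[used, , drop = FALSE]
  if (nrow(tot) == 0) {
    rlang::abort("no usable periods in stream", class = "dsmflow_spec_error")
  }
  if (grouping == "period") {
    labels <- rownames(tot)
    groups <- split(seq_len(nrow(tot)), factor(labels, levels = unique(labels)))
  } else {
    pg <- stream$period_groups
    if (is.null(pg) || !grouping %in% names(pg)) {
      rlang::abort(sprintf("grouping '%s' was not supplied as period_groups", grouping),
                   class = "dsmflow_spec_error")
    }
    lab <- pg[[grouping]][match(rownames(tot), as.character(pg$period))]
    groups <- split(seq_len(nrow(tot)), factor(lab, levels = unique(lab)))
  }
  rows <- purrr::imap(groups, function(idx, label) {
    per_draw <- colMeans(tot[idx, , drop = FALSE])
    est <- if (point == "mean") mean(per_draw) else stats::median(per_draw)
    se <- stats::sd(per_draw)
    if (est <= 0) {
      rlang::warn(sprintf("group '%s' has non-positive mean abundance; interval undefined", label))
      return(tibble::tibble(group = label, estimate = est, se = se,
                            cv = NA_real_, lower = NA_real_, upper = NA_real_))
    }
    cv <- se / est
    ci <- lognormal_interval(est, cv, level)
    tibble::tibble(group = label, estimate = est, se = se, cv = cv,
                   lower = ci$lower, upper = ci$upper)
  })
  out <- purrr::list_rbind(rows)
  attr(out, "level") <- level
  attr(out, "B") <- stream$B
  class(out) <- c("abundance_series", class(out))
  out
}

#' Fold in external correction factors by the delta method
#'
#' Adjusts an abundance summary for non-coincident correction factors
#' (trackline detection g(0), availability) estimated from independent data.
#' Their squared CVs add to the model CV:
#' `CV_total = sqrt(CV_model^2 + sum_i CV_i^2)`, and intervals are recomputed
#' from the total CV. Point estimates are divided by a correction's estimate
#' only when it was **not** already applied in the fitting offset — offsets
#' correct the observed counts during fitting, so predictions already target
#' true abundance and only the correction's uncertainty remains to be added.
#'
#' @param summary An `abundance_series`, or a per-cell map from
#'   [summarize_cells()] (columns `mean`, `se`).
#' @param corrections Tibble of [correction_factor()] rows, all with
#'   `coincident = FALSE`; an optional logical column `in_offset`
#'   (default `TRUE`) records whether each was part of the fitting offset.
#' @param level Interval coverage for recomputed intervals.
#' @return The summary with adjusted point estimates, `cv` (total), `se`,
#'   and intervals where applicable.
#' @export
#' @examples
#' s <- tibble::tibble(group = "all", estimate = 1000, se = 100, cv = 0.1,
#'                     lower = NA, upper = NA)
#' class(s) <- c("abundance_series", class(s))
#' combine_cv(s, correction_factor("g0", 0.921, 0.023))
combine_cv <- function(summary, corrections, level = 0.95) {
  if (is.null(corrections) || nrow(corrections) == 0) return(summary)
  if (any(corrections$coincident)) {
    rlang::abort(paste0("coincident corrections cannot be combined by the ",
                        "delta method; absorb them into the model (varprop)"),
                 class = "dsmflow_spec_error")
  }
  if (any(corrections$estimate <= 0)) {
    rlang::abort("correction estimates must be > 0", class = "dsmflow_domain_error")
  }
  in_offset <- corrections[["in_offset"]] %||% rep(TRUE, nrow(corrections))
  point_scale <- prod(1 / corrections$estimate[!in_offset])
  extra_cv2 <- sum(corrections$cv^2)

  if (all(c("estimate", "cv") %in% names(summary))) {
    summary$estimate <- summary$estimate * point_scale
    summary$cv <- sqrt(summary$cv^2 + extra_cv2)
    summary$se <- summary$cv * summary$estimate
    ci <- lognormal_interval(summary$estimate, summary$cv, level)
    summary$lower <- ci$lower
    summary$upper <- ci$upper
  } else if (all(c("mean", "se") %in% names(summary))) {
    cv <- ifelse(summary$mean > 0, summary$se / summary$mean, 0)
    summary$mean <- summary$mean * point_scale
    cv_tot <- sqrt(cv^2 + extra_cv2)
    summary$se <- cv_tot * summary$mean
  } else {
    rlang::abort("summary must have estimate/cv or mean/se columns",
                 class = "dsmflow_spec_error")
  }
  summary
}

#' Analytic (delta-method) variance of a linear abundance summary
#'
#' First-order analytic twin of posterior simulation for summaries that are
#' (possibly time-weighted) linear combinations of cell abundances:
#' `Var(sum_t w_t sum_c N_ct) ~ a' V* a` with
#' `a = sum_t w_t X_t' (area_t * exp(X_t beta_hat))` for the log link
#' (the gradient of the summary in the coefficients). Useful as a fast
#' cross-check of simulation output and for quick SEs when a full draw set
#' is unnecessary.
#'
#' @param fit A `dsm_fit`.
#' @param grids Long prediction-grid tibble.
#' @param weights Named vector of per-period weights (names = period labels);
#'   default weights every period `1 / T`, i.e. the time-averaged total.
#' @param rung Covariance rung, see [dsm_covariance()].
#' @param link `"log"` (default, matches the count model) or `"identity"`
#'   for linear-model validation.
#' @return One-row tibble: `estimate` (the summary at `beta_hat`),
#'   `variance`, `se`, `cv`.
#' @export
analytic_variance <- function(fit, grids, weights = NULL, rung = "V_beta",
                              link = c("log", "identity")) {
  link <- match.arg(link)
  stopifnot(inherits(fit, "dsm_fit"))
  grids <- validate_grids(grids)
  V <- dsm_covariance(fit, rung = rung)
  periods <- unique(grids$period)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1 / length(periods), length(periods)),
                               as.character(periods))
  }
  p <- length(stats::coef(fit$gam))
  a <- rep(0, p)
  est <- 0
  for (tlab in periods) {
    w <- weights[[as.character(tlab)]]
    if (is.null(w) || w == 0) next
    gt <- grids[grids$period == tlab, , drop = FALSE]
    pe <- predict_eta(fit, gt)
    if (link == "log") {
      Nc <- gt$cell_area * exp(pe$eta)
      a <- a + w * drop(t(pe$X) %*% Nc)
      est <- est + w * sum(Nc)
    } else {
      Nc <- gt$cell_area * pe$eta
      a <- a + w * drop(t(pe$X) %*% gt$cell_area)
      est <- est + w * sum(Nc)
    }
  }
  v <- drop(a %*% V %*% a)
  tibble::tibble(estimate = est, variance = v, se = sqrt(v),
                 cv = if (est > 0) sqrt(v) / est else NA_real_)
}
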