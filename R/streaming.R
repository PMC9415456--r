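#' Online (Welford) moment accumulators
#'
#' Running first and second moments over a stream of vector observations,
#' using Welford's numerically stable update with pairwise (Chan) combination
#' of batches. Posterior simulation over many time periods produces a
#' `B x cells x T` array that is never materialized: each period's
#' `cells x B` block is folded into these accumulators and discarded, so
#' memory is independent of the number of periods and draws.
#'
#' `welford_init` creates a state of dimension `d`; `welford_update` folds in
#' a single observation vector; `welford_add_batch` folds in a matrix of
#' observations (rows = components, columns = observations), optionally only
#' for a subset of components; `welford_combine` merges two states;
#' `welford_finalize` returns means, (sample) variances and SDs.
#'
#' @param d State dimension (number of tracked components).
#' @param state,a,b Accumulator states.
#' @param x Observation vector of length `d`.
#' @param m Matrix with `length(idx)` rows and one column per observation.
#' @param idx Integer indices of the components the batch refers to
#'   (default all).
#' @return States are lists with `n`, `mean`, `M2` (per component);
#'   `welford_finalize` returns a list with `n`, `mean`, `variance`, `sd`.
#' @export
welford_init <- function(d) {
  list(n = rep(0, d), mean = rep(0, d), M2 = rep(0, d))
}

#' @rdname welford_init
#' @export
welford_update <- function(state, x) {
  n1 <- state$n + 1
  delta <- x - state$mean
  mean <- state$mean + delta / n1
  list(n = n1, mean = mean, M2 = state$M2 + delta * (x - mean))
}

#' @rdname welford_init
#' @export
welford_add_batch <- function(state, m, idx = seq_along(state$n)) {
  m <- as.matrix(m)
  nb <- ncol(m)
  if (nb == 0) return(state)
  bm <- rowMeans(m)
  bM2 <- rowSums((m - bm)^2)
  n0 <- state$n[idx]
  nt <- n0 + nb
  delta <- bm - state$mean[idx]
  state$mean[idx] <- state$mean[idx] + delta * nb / nt
  state$M2[idx] <- state$M2[idx] + bM2 + delta^2 * n0 * nb / nt
  state$n[idx] <- nt
  state
}

#' @rdname welford_init
#' @export
welford_combine <- function(a, b) {
  nt <- a$n + b$n
  delta <- b$mean - a$mean
  mean <- ifelse(nt > 0, a$mean + delta * b$n / pmax(nt, 1), 0)
  M2 <- a$M2 + b$M2 + delta^2 * a$n * b$n / pmax(nt, 1)
  list(n = nt, mean = mean, M2 = M2)
}

#' @rdname welford_init
#' @export
welford_finalize <- function(state) {
  v <- ifelse(state$n > 1, state$M2 / (state$n - 1), NA_real_)
  list(n = state$n, mean = ifelse(state$n > 0, state$mean, NA_real_),
       variance = v, sd = sqrt(v))
}

#' Log-normal confidence interval for a positive estimate
#'
#' The standard interval for strictly positive abundance estimates:
#' `exp(log(N) +/- z * sqrt(log(1 + CV^2)))`. Collapses to the point
#' estimate when `cv = 0`; asymmetric (longer upper arm) otherwise.
#'
#' @param point Point estimate(s), > 0.
#' @param cv Coefficient(s) of variation, >= 0.
#' @param level Coverage level (default 0.95).
#' @return Tibble with `lower` and `upper`.
#' @export
#' @examples
#' lognormal_interval(1000, 0.2)
lognormal_interval <- function(point, cv, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  slog <- sqrt(log(1 + cv^2))
  tibble::tibble(lower = exp(log(point) - z * slog),
                 upper = exp(log(point) + z * slog))
}
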