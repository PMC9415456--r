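# numeric utilities shared across modules

# central finite-difference Hessian; relative step follows the detection
# module's convention (1e-4 * max(1, |x|) per coordinate)
fd_hessian <- function(f, x, rel_step = 1e-4) {
  p <- length(x)
  h <- rel_step * pmax(1, abs(x))
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# central finite-difference Jacobian of a vector-valued function
fd_jacobian <- function(f, x, rel_step = 1e-4) {
  h <- rel_step * pmax(1, abs(x))
  cols <- lapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    (f(xp) - f(xm)) / (2 * h[i])
  })
  do.call(cbind, cols)
}

sym <- function(A) (A + t(A)) / 2

# Cholesky factor with escalating diagonal jitter; covariance matrices from
# finite-difference corrections can be indefinite at machine precision
chol_with_jitter <- function(V, jitters = 10^seq(-10, -6, by = 1)) {
  V <- sym(V)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(L)) return(L)
  scale <- mean(diag(V))
  for (j in jitters) {
    L <- tryCatch(chol(V + diag(j * scale, nrow(V))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  rlang::abort("covariance matrix not positive definite after maximum jitter",
               class = "dsmflow_sampling_error")
}

# deterministic per-stage child seeds from one root seed (kept < 2^31)
child_seed <- function(seed, stage) {
  offsets <- c(detection = 11L, fields = 23L, survey = 37L, draws = 53L,
               recovery = 71L, mh = 89L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 97 + off) %% .Machine$integer.max)
}

is_psd <- function(A, tol = 1e-8) {
  ev <- eigen(sym(A), symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(abs(ev), 1))
}
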