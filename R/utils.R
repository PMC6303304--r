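# Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible child seed from a base seed and a stream name
#'
#' A single user-facing seed is fanned out into one named substream per
#' pipeline stage so stages can be rerun independently yet reproducibly.
#' The mapping is a fixed integer hash; it carries no statistical weight
#' beyond decorrelating the streams.
#'
#' @param seed integer base seed.
#' @param name character stream name, e.g. `"render"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  ch <- utf8ToInt(name)
  h <- sum(ch * seq_along(ch))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483646 + 1)
}

# Parameters (meanlog, sdlog) of the log-normal with given arithmetic
# mean and standard deviation.
lnorm_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Draw n sister pairs of log-normal values with Gaussian-copula
# correlation rho on the log scale.
rlnorm_pair <- function(n, meanlog, sdlog, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(exp(meanlog + sdlog * z1), exp(meanlog + sdlog * z2))
}

# Correlated pair of uniform quantiles through a Gaussian copula.
runif_pair_copula <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(stats::pnorm(z1), stats::pnorm(z2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pearson correlation of q(U1), q(U2) when (U1, U2) come from a Gaussian
# copula with parameter rho_n, by 2D Gauss-Hermite quadrature.
copula_margin_pearson <- function(rho_n, qfun, n_nodes = 48L) {
  gh <- function(n) {
    # Golub-Welsch: Hermite nodes/weights from the Jacobi matrix
    i <- seq_len(n - 1L)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- sqrt(i / 2)
    J[cbind(i + 1L, i)] <- sqrt(i / 2)
    e <- eigen(J, symmetric = TRUE)
    list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
  }
  g <- gh(n_nodes)
  z <- sqrt(2) * g$x
  w <- g$w / sqrt(pi)
  pn <- function(x) clip(stats::pnorm(x), 1e-12, 1 - 1e-12)
  q <- qfun(pn(z))
  mu <- sum(w * q)
  v <- sum(w * (q - mu)^2)
  # E[q(Z1) q(Z2)] with corr(Z1, Z2) = rho_n: condition on Z1
  s <- sqrt(max(1 - rho_n^2, 0))
  exy <- 0
  for (i in seq_along(z)) {
    z2 <- rho_n * z[i] + s * z
    exy <- exy + w[i] * q[i] * sum(w * qfun(pn(z2)))
  }
  (exy - mu^2) / v
}

# Gaussian-copula parameter giving a target Pearson correlation for the
# margin defined by quantile function qfun (monotone in rho, bisection).
copula_rho_for_pearson <- function(target, qfun) {
  if (target == 0) return(0)
  sgn <- sign(target); target <- abs(target)
  lo <- 0; hi <- 0.9999
  if (copula_margin_pearson(hi, qfun) < target) return(sgn * hi)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (copula_margin_pearson(mid, qfun) < target) lo <- mid else hi <- mid
  }
  sgn * (lo + hi) / 2
}
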