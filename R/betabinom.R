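# Beta-binomial emission model: log-pmf and weighted maximum-likelihood
# fitting (the M-step of Baum-Welch).

# Precision bounds. An unbounded alpha + beta collapses the beta-binomial to
# a plain binomial and destabilises training; shape parameters are kept away
# from zero for the same reason.
BB_MAX_PRECISION <- 1e4
BB_MIN_SHAPE <- 1e-2
BB_FALLBACK_PRECISION <- 10

#' Beta-binomial log probability mass
#'
#' `log P(m | n, alpha, beta) = log C(n, m) + log B(m + alpha, n - m + beta)
#' - log B(alpha, beta)`. A bin with no observations (`n = 0`) has
#' log-probability 0 in every state: it carries no evidence but stays in the
#' transition chain.
#'
#' @param m Methylated read count(s), `0 <= m <= n`.
#' @param n Total read count(s).
#' @param alpha,beta Positive shape parameters; the implied state mean is
#'   `alpha / (alpha + beta)`.
#' @return Log-probabilities, vectorised over `m` and `n`.
#' @export
betabinom_logpmf <- function(m, n, alpha, beta) {
  if (any(n < 0) || any(m < 0) || any(m > n)) {
    abort("Counts must satisfy 0 <= m <= n.")
  }
  if (alpha <= 0 || beta <= 0) abort("Shape parameters must be positive.")
  out <- lchoose(n, m) + lbeta(m + alpha, n - m + beta) - lbeta(alpha, beta)
  out[n == 0] <- 0
  out
}

#' Weighted maximum-likelihood fit of beta-binomial shape parameters
#'
#' Fits `(alpha, beta)` to counts `(m, n)` under non-negative observation
#' weights (state responsibilities during training). A method-of-moments
#' estimate seeds a quasi-Newton refinement of the weighted log-likelihood on
#' the log-shape scale. The precision `alpha + beta` is capped at `1e4` and
#' each shape floored at `1e-2`.
#'
#' Degenerate inputs -- fewer than two informative observations, or all
#' observed proportions identical -- fall back to a smoothed moment estimate:
#' mean `(sum(w m) + 0.5) / (sum(w n) + 1)` at a fixed fallback precision.
#'
#' @param ms,ns Methylated and total counts, equal length.
#' @param weights Per-observation weights, same length, non-negative with a
#'   positive sum. Default: unit weights.
#' @return A list with elements `alpha`, `beta` and `mean`.
#' @export
fit_betabinom <- function(ms, ns, weights = rep(1, length(ms))) {
  stopifnot(length(ms) == length(ns), length(weights) == length(ms))
  if (any(weights < 0)) abort("Weights must be non-negative.")
  keep <- ns >= 1 & weights > 0
  if (sum(weights) <= 0 || !any(ns >= 1)) {
    abort("At least one observation with n >= 1 and positive weight is required.")
  }
  m <- ms[keep]; n <- ns[keep]; w <- weights[keep]
  if (length(m) == 0L) abort("No informative observations after weighting.")

  p <- m / n
  sw <- sum(w)
  pbar <- sum(w * m) / sum(w * n)

  smoothed_mean <- (sum(w * m) + 0.5) / (sum(w * n) + 1)
  fallback <- bb_from_mean_precision(smoothed_mean, BB_FALLBACK_PRECISION)
  if (length(m) < 2L) return(fallback)
  var_p <- sum(w * (p - pbar)^2) / sw
  if (var_p < .Machine$double.eps || pbar <= 0 || pbar >= 1) return(fallback)

  # moment match: Var(p_i) ~ pbar(1-pbar) (1/n_i + (1 - 1/n_i) rho),
  # rho = 1 / (alpha + beta + 1)
  mean_inv_n <- sum(w / n) / sw
  rho <- (var_p / (pbar * (1 - pbar)) - mean_inv_n) / (1 - mean_inv_n)
  rho <- min(max(rho, 1e-4), 0.99)
  s0 <- 1 / rho - 1

  negll <- function(theta) {
    a <- exp(theta[1L]); b <- exp(theta[2L])
    if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(1e12)
    -sum(w * (lbeta(m + a, n - m + b) - lbeta(a, b)))
  }
  grad <- function(theta) {
    a <- exp(theta[1L]); b <- exp(theta[2L])
    da <- sum(w * (digamma(m + a) - digamma(n + a + b) - digamma(a) + digamma(a + b)))
    db <- sum(w * (digamma(n - m + b) - digamma(n + a + b) - digamma(b) + digamma(a + b)))
    -c(da * a, db * b)
  }

  theta0 <- log(c(pbar * s0, (1 - pbar) * s0))
  fit <- tryCatch(
    optim(theta0, negll, grad, method = "BFGS",
          control = list(maxit = 200, reltol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(bb_from_mean_precision(pbar, s0))
  a <- exp(fit$par[1L]); b <- exp(fit$par[2L])

  # clamp precision / shapes, preserving the fitted mean
  s <- a + b
  mu <- a / s
  if (s > BB_MAX_PRECISION) s <- BB_MAX_PRECISION
  a <- max(mu * s, BB_MIN_SHAPE)
  b <- max((1 - mu) * s, BB_MIN_SHAPE)
  list(alpha = a, beta = b, mean = a / (a + b))
}

bb_from_mean_precision <- function(mu, s) {
  mu <- min(max(mu, 1e-6), 1 - 1e-6)
  a <- max(mu * s, BB_MIN_SHAPE)
  b <- max((1 - mu) * s, BB_MIN_SHAPE)
  list(alpha = a, beta = b, mean = a / (a + b))
}
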