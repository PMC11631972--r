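#' The neutrosophic Burr-III distribution
#'
#' Density, distribution function, survival function, hazard rate, quantile
#' function and random generation for the neutrosophic Burr-III (NeS-BrIII)
#' distribution with shape parameters `lambda` (\eqn{\lambda > 0}) and
#' `theta` (\eqn{\theta > 0}) at a fixed indeterminacy value `indet`
#' (\eqn{I \ge 0}).
#'
#' The CDF is
#' \deqn{F(x) = \{1 + [(1+I)x]^{-\theta}\}^{-\lambda},}
#' so \eqn{X = Y/(1+I)} with \eqn{Y} classical Burr-III; `indet = 0` gives
#' the classical distribution.  The quantile function is the exact inverse,
#' \deqn{x_q = (1+I)^{-1} (q^{-1/\lambda} - 1)^{-1/\theta}.}
#'
#' Neutrosophic (interval-valued) results are obtained by evaluating at the
#' two endpoints of an indeterminacy interval; see [indet_interval()].
#'
#' `hnesbr3()` returns `Inf` with a warning where the survival function
#' underflows to zero at machine precision (the hazard is finite wherever
#' `S(x) > 0`).
#'
#' @param x,q vector of positive quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of observations (a single positive integer).
#' @param lambda,theta shape parameters, strictly positive.
#' @param indet indeterminacy value \eqn{I \ge 0} at this endpoint.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#' @return `dnesbr3` the density, `pnesbr3` the distribution function,
#'   `snesbr3` the survival function, `hnesbr3` the hazard rate,
#'   `qnesbr3` the quantile function, `rnesbr3` a vector of random deviates.
#' @examples
#' pnesbr3(1, lambda = 1, theta = 1)            # 0.5
#' dnesbr3(1, lambda = 1, theta = 1)            # 0.25
#' qnesbr3(0.5, lambda = 1, theta = 1)          # median = 1
#' x <- rnesbr3(5, lambda = 2, theta = 3, indet = 0.05)
#' @name nesbr3-distribution
NULL

## log(1 + exp(t)) without overflow for large t.
log1pexp <- function(t) {
  out <- t
  small <- t < 37
  out[small] <- log1p(exp(t[small]))
  out
}

#' @rdname nesbr3-distribution
#' @export
pnesbr3 <- function(q, lambda, theta, indet = 0, lower.tail = TRUE,
                    log.p = FALSE) {
  check_params(lambda, theta, indet)
  check_x_positive(q, "q")
  ## log F = -lambda * log(1 + ((1+I)q)^{-theta}), computed via log1pexp of
  ## t = -theta*(log1p(I) + log q) so extreme theta cannot overflow.
  t <- -theta * (log1p(indet) + log(q))
  logF <- -lambda * log1pexp(t)
  if (lower.tail) {
    if (log.p) logF else exp(logF)
  } else {
    sf <- -expm1(logF)
    if (log.p) log(sf) else sf
  }
}

#' @rdname nesbr3-distribution
#' @export
dnesbr3 <- function(x, lambda, theta, indet = 0, log = FALSE) {
  check_params(lambda, theta, indet)
  check_x_positive(x)
  t <- -theta * (log1p(indet) + log(x))
  logf <- log(lambda) + log(theta) - theta * log1p(indet) -
    (theta + 1) * log(x) - (lambda + 1) * log1pexp(t)
  if (log) logf else exp(logf)
}

#' @rdname nesbr3-distribution
#' @export
snesbr3 <- function(q, lambda, theta, indet = 0) {
  pnesbr3(q, lambda, theta, indet, lower.tail = FALSE)
}

#' @rdname nesbr3-distribution
#' @export
hnesbr3 <- function(x, lambda, theta, indet = 0) {
  s <- snesbr3(x, lambda, theta, indet)
  f <- dnesbr3(x, lambda, theta, indet)
  h <- ifelse(s > 0, f / s, Inf)
  if (any(s == 0))
    warning("hazard overflow: survival function underflows to 0 at some x",
            call. = FALSE)
  h
}

#' @rdname nesbr3-distribution
#' @export
qnesbr3 <- function(p, lambda, theta, indet = 0) {
  check_params(lambda, theta, indet)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  ## exact inverse of the CDF: x_q = (1+I)^{-1} (p^{-1/lambda} - 1)^{-1/theta}
  exp(-log1p(indet) - log(expm1(-log(p) / lambda)) / theta)
}

#' @rdname nesbr3-distribution
#' @export
rnesbr3 <- function(n, lambda, theta, indet = 0) {
  check_params(lambda, theta, indet)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a single integer >= 1", call. = FALSE)
  qnesbr3(runif(as.integer(n)), lambda, theta, indet)
}
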