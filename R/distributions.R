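#' Zero-inflated Beta density
#'
#' Mixture of a point mass `pi` at zero and a Beta distribution on (0, 1)
#' for positive proportions, parameterised by its mean `mu` and precision
#' `phi` (shapes `mu * phi` and `(1 - mu) * phi`). Values of exactly 1 are
#' not supported here; apply [squeeze_proportions()] first.
#'
#' @param y proportions in `[0, 1)` (vector).
#' @param mu conditional Beta mean in (0, 1).
#' @param phi Beta precision (> 0).
#' @param pi zero-inflation probability in `[0, 1)`.
#' @param log return log density/mass?
#' @return Density (for `y > 0`) or mass (at `y = 0`) values.
#' @export
dzibeta <- function(y, mu, phi, pi, log = FALSE) {
  if (any(y < 0 | y > 1)) stop("`y` must lie in [0, 1]")
  if (any(y == 1)) stop("y = 1 must be squeezed before evaluation; see squeeze_proportions()")
  if (!(mu > 0 && mu < 1)) stop("`mu` must lie in (0, 1)")
  if (!(phi > 0)) stop("`phi` must be positive")
  if (!(pi >= 0 && pi < 1)) stop("`pi` must lie in [0, 1)")
  ld <- ifelse(y == 0, log(pi),
               log1p(-pi) + dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  if (log) ld else exp(ld)
}

#' Draw from the zero-inflated Beta distribution
#'
#' @param n number of draws.
#' @inheritParams dzibeta
#' @return Numeric vector with exact zeros occurring with probability `pi`.
#' @export
rzibeta <- function(n, mu, phi, pi) {
  z <- rbinom(n, 1L, pi) == 1L
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  y[z] <- 0
  y
}

#' Tweedie compound Poisson-gamma density (1 < p < 2)
#'
#' Evaluates the Tweedie density with mean `mu`, dispersion `phi` and
#' power `p`, `Var(Y) = phi * mu^p`. The distribution is a Poisson sum of
#' gamma variables: rate `lambda = mu^(2-p) / (phi (2-p))`, gamma shape
#' `alpha = (2-p)/(p-1)`, scale `theta = phi (p-1) mu^(p-1)`; it has mass
#' `exp(-lambda)` at zero and a continuous density on (0, Inf) evaluated
#' by the series expansion with adaptive term selection.
#'
#' @param y nonnegative values (vector).
#' @param mu mean (> 0), scalar or vector of `length(y)`.
#' @param phi dispersion (> 0).
#' @param p power parameter in (1, 2).
#' @param log return log density?
#' @return Density (mass at `y = 0`) values.
#' @export
dtweedie_cpg <- function(y, mu, phi, p, log = FALSE) {
  if (any(y < 0)) stop("`y` must be nonnegative")
  ld <- cpp_tweedie_logdens(as.numeric(y), as.numeric(mu), phi, p)
  if (log) ld else exp(ld)
}

#' Draw from the Tweedie distribution via its compound representation
#'
#' @param n number of draws.
#' @inheritParams dtweedie_cpg
#' @return Nonnegative numeric vector with exact zeros.
#' @export
rtweedie_cpg <- function(n, mu, phi, p) {
  if (!(p > 1 && p < 2)) stop("`p` must lie in (1, 2)")
  lambda <- mu^(2 - p) / (phi * (2 - p))
  alpha <- (2 - p) / (p - 1)
  theta <- phi * (p - 1) * mu^(p - 1)
  N <- rpois(n, lambda)
  y <- numeric(n)
  pos <- N > 0
  y[pos] <- rgamma(sum(pos), shape = N[pos] * alpha, scale = theta)
  y
}

#' Squeeze proportions away from 1
#'
#' Standard Beta-regression transform applied to the nonzero responses:
#' `y' = (y * (n - 1) + 0.5) / n` with `n` the number of nonzero
#' responses. Exact zeros are preserved (they belong to the zero-inflation
#' component).
#'
#' @param y proportions in `[0, 1]`.
#' @return Transformed vector with nonzero entries strictly inside (0, 1).
#' @export
squeeze_proportions <- function(y) {
  pos <- y > 0
  n <- sum(pos)
  if (n == 0) return(y)
  y[pos] <- (y[pos] * (n - 1) + 0.5) / n
  y
}
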