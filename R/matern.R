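#' Matern covariance function
#'
#' Stationary Matern covariance
#' \deqn{C(d) = \sigma^2 \frac{2^{1-\nu}}{\Gamma(\nu)} (\kappa d)^\nu
#'       K_\nu(\kappa d), \qquad \kappa = \sqrt{8\nu}/\rho,}
#' parameterised by the marginal standard deviation \eqn{\sigma}, the
#' spatial range \eqn{\rho} (the distance at which correlation falls to
#' about 0.13, the usual SPDE convention) and the smoothness \eqn{\nu}.
#' At \eqn{\nu = 1/2} this reduces to the exponential covariance
#' \eqn{\sigma^2 e^{-\kappa d}} with \eqn{\kappa = 2/\rho}.
#'
#' @param d non-negative distances.
#' @param sd marginal standard deviation \eqn{\sigma > 0}.
#' @param range spatial range \eqn{\rho > 0}.
#' @param nu smoothness \eqn{\nu > 0}; default 1.
#' @return covariance values, `sd^2` at `d = 0`.
#' @export
matern_cov <- function(d, sd, range, nu = 1) {
  if (sd < 0 || range <= 0 || nu <= 0) stop("sd >= 0, range > 0, nu > 0 required")
  kappa <- sqrt(8 * nu) / range
  out <- numeric(length(d))
  z <- kappa * d
  pos <- z > 0
  out[!pos] <- sd^2
  if (any(pos)) {
    out[pos] <- sd^2 * 2^(1 - nu) / gamma(nu) * z[pos]^nu * besselK(z[pos], nu)
  }
  out
}

# Dense Matern covariance matrix over a set of 2-D locations.
matern_cov_matrix <- function(locations, sd, range, nu = 1) {
  locations <- as.matrix(locations)
  D <- as.matrix(stats::dist(locations))
  matrix(matern_cov(D, sd, range, nu), nrow(locations), nrow(locations))
}

#' Simulate a Gaussian random field with Matern covariance
#'
#' Draws a zero-mean multivariate Gaussian vector over the given
#' locations with Matern covariance, by Cholesky factorisation of the
#' dense covariance matrix.  Coincident locations are allowed (their
#' values are perfectly correlated); if the factorisation fails
#' numerically, an increasing diagonal jitter is added and the draw is
#' retried, aborting after `max_tries` attempts.
#'
#' @param locations n x 2 matrix (or data frame) of coordinates.
#' @inheritParams matern_cov
#' @param seed optional integer seed; the caller's RNG state is left
#'   untouched.
#' @param n_rep number of independent replicate fields; default 1.
#' @param max_tries jitter-and-retry attempts; default 4.
#' @return numeric vector of field values (length n), or an n x n_rep
#'   matrix when `n_rep > 1`.
#' @export
simulate_matern_field <- function(locations, sd, range, nu = 1, seed = NULL,
                                  n_rep = 1, max_tries = 4) {
  locations <- as.matrix(locations)
  n <- nrow(locations)
  if (n < 1) stop("at least one location required")
  if (sd == 0) {
    out <- matrix(0, n, n_rep)
    return(if (n_rep == 1) drop(out) else out)
  }
  # coincident locations share a single draw (correlation exactly 1)
  key <- paste(locations[, 1], locations[, 2], sep = "\r")
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  uloc <- locations[uk, , drop = FALSE]
  m <- nrow(uloc)
  S <- matern_cov_matrix(uloc, sd, range, nu)
  L <- NULL
  jitter <- 0
  for (k in seq_len(max_tries)) {
    L <- tryCatch(chol(S + diag(jitter, m)), error = function(e) NULL)
    if (!is.null(L)) break
    jitter <- if (jitter == 0) sd^2 * 1e-10 else jitter * 100
  }
  if (is.null(L)) stop("Matern covariance not positive definite after jitter")
  out <- with_seed(seed, {
    z <- matrix(rnorm(m * n_rep), m, n_rep)
    crossprod(L, z)
  })
  out <- out[map, , drop = FALSE]
  if (n_rep == 1) drop(out) else out
}
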