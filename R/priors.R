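#' Penalising-complexity prior settings
#'
#' PC priors shrink each flexible model component towards its simpler
#' base model.  For a random-effect standard deviation \eqn{\sigma}
#' (frailty, spatial, random-walk smoothing) the PC prior is an
#' exponential on \eqn{\sigma} with rate \eqn{-\ln(\alpha)/\sigma_0},
#' so that \eqn{P(\sigma > \sigma_0) = \alpha}.  For the Matern range
#' \eqn{\rho} (in two dimensions) the PC prior has
#' \eqn{P(\rho < \rho_0) = \alpha_\rho}, density
#' \eqn{\pi(\rho) = \lambda \rho^{-2} e^{-\lambda/\rho}} with
#' \eqn{\lambda = -\ln(\alpha_\rho)\,\rho_0}.
#'
#' @param sigma0,alpha tail parameters shared by all SD priors;
#'   defaults \eqn{\sigma_0 = 1}, \eqn{\alpha = 0.01}.
#' @param range0 reference range \eqn{\rho_0}; `NULL` (default) sets it
#'   at fit time to one tenth of the maximal inter-location distance.
#' @param alpha_range tail probability \eqn{P(\rho < \rho_0)}; default
#'   0.05.
#' @return list of class `"bpeh_priors"`.
#' @export
bpeh_priors <- function(sigma0 = 1, alpha = 0.01,
                        range0 = NULL, alpha_range = 0.05) {
  stopifnot(sigma0 > 0, alpha > 0, alpha < 1,
            alpha_range > 0, alpha_range < 1)
  structure(list(sigma0 = sigma0, alpha = alpha,
                 range0 = range0, alpha_range = alpha_range),
            class = "bpeh_priors")
}

# log density of the PC (exponential) prior for an SD.  The outer
# optimisation maximises the posterior in this natural parameterisation
# (no log-scale Jacobian), so a flat likelihood lets the prior shrink
# the SD to its base value 0.
pc_sd_logprior <- function(sigma, sigma0, alpha) {
  rate <- -log(alpha) / sigma0
  log(rate) - rate * sigma
}

# log density of the PC prior for a 2-D Matern range
pc_range_logprior <- function(range, range0, alpha) {
  lam <- -log(alpha) * range0
  log(lam) - 2 * log(range) - lam / range
}

#' Numerical controls for the Laplace engine
#'
#' @param newton_tol convergence tolerance for the inner Newton
#'   mode-finding: the infinity norm of the gradient must fall below
#'   `newton_tol * max(1, number of events)`.
#' @param newton_maxit maximal inner Newton iterations.
#' @param outer_reltol,outer_maxit relative tolerance and iteration cap
#'   for the outer (Nelder-Mead / Brent) hyperparameter optimisation.
#' @param theta_min,theta_max box for log-scale hyperparameters.
#' @return list of class `"bpeh_control"`.
#' @export
bpeh_control <- function(newton_tol = 1e-8, newton_maxit = 100,
                         outer_reltol = 1e-5, outer_maxit = 200,
                         theta_min = -8, theta_max = 5) {
  structure(list(newton_tol = newton_tol, newton_maxit = newton_maxit,
                 outer_reltol = outer_reltol, outer_maxit = outer_maxit,
                 theta_min = theta_min, theta_max = theta_max),
            class = "bpeh_control")
}
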