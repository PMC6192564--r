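# ---------------------------------------------------------------------
# Laplace engine for the Bayesian piecewise-exponential hazard model.
#
# Latent field x = (lambda[1..B], beta[1..p], u[1..n_u], s[1..n_s]):
# log baseline-hazard steps, fixed effects, individual frailty, spatial
# Matern effect at unique locations.  Likelihood is the Poisson
# equivalence of the piecewise-exponential model over expanded pieces:
#   sum_r d_r * eta_r - E_r * exp(eta_r),   eta = A x.
# Priors: improper RW1 on lambda (precision tau_rw), flat on beta,
# iid N(0, sigma_u^2) on u, Matern GP on s; PC priors on the
# hyperparameters.  Inference is empirical-Bayes Laplace: Newton
# mode-finding in x, quasi-Newton/Brent over log-scale hyperparameters
# maximising the Laplace-approximate log marginal posterior.
# ---------------------------------------------------------------------

# Assemble the model stack from expanded pieces.
# X: design matrix of fixed effects per piece (no intercept: the
# baseline steps carry the level).  uidx/sidx: 1-based group index per
# piece or NULL.  uloc: unique locations (n_s x 2) for the Matern block.
build_stack <- function(ex, X, breaks, uidx = NULL, sidx = NULL,
                        uloc = NULL, nu = 1, smooth = TRUE) {
  R <- nrow(ex)
  B <- length(breaks) - 1L
  p <- if (is.null(X)) 0L else ncol(X)
  n_u <- if (is.null(uidx)) 0L else max(uidx)
  n_s <- if (is.null(sidx)) 0L else nrow(uloc)
  K <- B + p + n_u + n_s
  blocks <- list(sparseMatrix(i = seq_len(R), j = ex$bin, x = 1,
                              dims = c(R, B)))
  if (p) blocks <- c(blocks, list(as(Matrix(X, sparse = TRUE), "CsparseMatrix")))
  if (n_u) blocks <- c(blocks, list(sparseMatrix(i = seq_len(R), j = uidx,
                                                 x = 1, dims = c(R, n_u))))
  if (n_s) blocks <- c(blocks, list(sparseMatrix(i = seq_len(R), j = sidx,
                                                 x = 1, dims = c(R, n_s))))
  A <- do.call(cbind, blocks)
  idx <- list(lambda = seq_len(B),
              beta = if (p) B + seq_len(p) else integer(),
              u = if (n_u) B + p + seq_len(n_u) else integer(),
              s = if (n_s) B + p + n_u + seq_len(n_s) else integer())
  # RW1 structure matrix and its log generalised determinant
  R1 <- NULL; c_R1 <- 0
  if (smooth && B > 1) {
    D <- sparseMatrix(i = rep(seq_len(B - 1L), 2L),
                      j = c(seq_len(B - 1L), seq_len(B - 1L) + 1L),
                      x = rep(c(-1, 1), each = B - 1L), dims = c(B - 1L, B))
    R1 <- crossprod(D)
    ev <- eigen(as.matrix(R1), symmetric = TRUE, only.values = TRUE)$values
    c_R1 <- sum(log(ev[ev > 1e-9]))
  }
  smooth <- smooth && B > 1
  list(A = A, d = ex$d, E = ex$exposure, breaks = breaks, B = B, p = p,
       n_u = n_u, n_s = n_s, K = K, idx = idx, R1 = R1, c_R1 = c_R1,
       smooth = smooth, uloc = uloc, nu = nu,
       xnames = if (p) colnames(X) else character())
}

# Prior precision matrix Q(theta) for the latent field, plus its log
# generalised determinant (flat beta block contributes a constant and
# is dropped).  theta: named list with sigma_rw, sigma_u, sigma_s,
# range_s as applicable.
build_Q <- function(stack, theta) {
  blocks <- list()
  gdet <- 0
  if (stack$smooth) {
    tau <- theta$sigma_rw^-2
    blocks$lambda <- tau * stack$R1
    gdet <- gdet + (stack$B - 1) * log(tau) + stack$c_R1
  } else {
    blocks$lambda <- Matrix(0, stack$B, stack$B, sparse = TRUE)
  }
  if (stack$p) blocks$beta <- Matrix(0, stack$p, stack$p, sparse = TRUE)
  if (stack$n_u) {
    tau_u <- theta$sigma_u^-2
    blocks$u <- Diagonal(stack$n_u, tau_u)
    gdet <- gdet + stack$n_u * log(tau_u)
  }
  if (stack$n_s) {
    S <- matern_cov_matrix(stack$uloc, theta$sigma_s, theta$range_s,
                           stack$nu)
    cS <- chol(S + diag(theta$sigma_s^2 * 1e-8, nrow(S)))
    Qs <- chol2inv(cS)
    blocks$s <- as(Matrix(Qs, sparse = TRUE), "CsparseMatrix")
    gdet <- gdet - 2 * sum(log(diag(cS)))
  }
  Q <- forceSymmetric(do.call(bdiag, blocks))
  list(Q = Q, gdet = gdet)
}

# Joint log density of data and latent field (up to constants in the
# data): Poisson piece likelihood plus Gaussian prior quadratic forms.
log_joint <- function(x, stack, Q) {
  eta <- as.vector(stack$A %*% x)
  ll <- sum(stack$d * eta) - sum(stack$E * exp(pmin(eta, 500)))
  as.numeric(ll - 0.5 * sum(x * as.vector(Q %*% x)))
}

# Newton mode-finding for the latent field at fixed hyperparameters.
# Returns mode, Cholesky factor of the negative Hessian, the value of
# log_joint at the mode, and diagnostics.
fit_latent <- function(stack, Q, x0 = NULL, control = bpeh_control()) {
  K <- stack$K
  x <- if (is.null(x0)) rep(0, K) else x0
  # start the baseline steps near the crude overall log rate
  if (is.null(x0)) {
    rate <- max(sum(stack$d), 0.5) / sum(stack$E)
    x[stack$idx$lambda] <- log(rate)
  }
  tol <- control$newton_tol * max(1, sum(stack$d))
  f <- log_joint(x, stack, Q)
  ch <- NULL
  trace <- numeric()
  for (it in seq_len(control$newton_maxit)) {
    eta <- as.vector(stack$A %*% x)
    w <- stack$E * exp(pmin(eta, 500))
    g <- as.vector(crossprod(stack$A, stack$d - w)) - as.vector(Q %*% x)
    gnorm <- max(abs(g))
    trace <- c(trace, gnorm)
    H <- forceSymmetric(crossprod(stack$A, stack$A * w) + Q)
    ch <- if (is.null(ch)) Cholesky(H, LDL = FALSE, perm = TRUE) else
      update(ch, H)
    if (gnorm < tol) {
      return(list(x = x, ch = ch, logjoint = f, iterations = it - 1L,
                  grad_norm = gnorm, converged = TRUE))
    }
    step <- as.vector(solve(ch, g))
    # backtracking line search on the log joint
    alpha <- 1
    repeat {
      xn <- x + alpha * step
      fn <- log_joint(xn, stack, Q)
      if (is.finite(fn) && fn >= f - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    if (alpha < 1e-8 && fn < f) {
      stop("Newton mode-finding failed to improve; gradient trace: ",
           paste(signif(trace, 3), collapse = ", "))
    }
    moved <- max(abs(xn - x))
    x <- xn
    f <- fn
    # numerical plateau: step is at machine precision of the iterate
    if (moved < 1e-10 * max(1, max(abs(x)))) {
      return(list(x = x, ch = ch, logjoint = f, iterations = it,
                  grad_norm = gnorm, converged = TRUE))
    }
  }
  stop("Newton mode-finding did not converge in ", control$newton_maxit,
       " iterations; gradient trace: ",
       paste(signif(tail(trace, 8), 3), collapse = ", "))
}

# log determinant of the negative Hessian from its Cholesky factor
chol_logdet <- function(ch) {
  2 * as.numeric(determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
}

# Laplace-approximate log marginal posterior of the hyperparameters
# (up to constants): logjoint(xhat) + 0.5 gdet(Q) - 0.5 logdet(H)
# + PC-prior log densities (with log-scale Jacobians).
laplace_logpost <- function(theta_log, stack, hyper_names, fixed, priors,
                            control, warm) {
  theta_log <- pmin(pmax(theta_log, control$theta_min), control$theta_max)
  theta <- fixed
  for (i in seq_along(hyper_names)) {
    nm <- hyper_names[i]
    theta[[nm]] <- exp(theta_log[i])
  }
  qq <- build_Q(stack, theta)
  fit <- fit_latent(stack, qq$Q, x0 = warm$x, control = control)
  warm$x <- fit$x
  lp <- fit$logjoint + 0.5 * qq$gdet - 0.5 * chol_logdet(fit$ch)
  for (i in seq_along(hyper_names)) {
    nm <- hyper_names[i]
    lp <- lp + if (nm == "range_s") {
      pc_range_logprior(exp(theta_log[i]), priors$range0, priors$alpha_range)
    } else {
      pc_sd_logprior(exp(theta_log[i]), priors$sigma0, priors$alpha)
    }
  }
  as.numeric(lp)
}

#' Fit the Bayesian piecewise-exponential proportional-hazards model
#'
#' Fits, by an empirical-Bayes Laplace approximation, a proportional
#' hazards model whose log baseline hazard is piecewise constant on
#' time bins with a first-order random-walk (RW1) smoothness penalty,
#' with optional individual frailty (iid Gaussian log-hazard offsets
#' per participant) and an optional spatially structured Gaussian
#' effect with Matern covariance over participant locations.
#' Hyperparameters (RW1 smoothing SD, frailty SD, spatial SD and
#' range) carry penalising-complexity priors and are optimised on the
#' log scale against the Laplace-approximate marginal posterior; the
#' latent field is found by Newton iteration with a sparse Cholesky
#' factorisation.
#'
#' The data are a counting-process (start-stop) table, so delayed
#' entry and time-varying covariates are handled by construction; the
#' likelihood is the standard Poisson equivalence of the
#' piecewise-exponential model after splitting each risk interval at
#' the bin boundaries (see [poisson_expand()]).
#'
#' @param formula model formula with a [survival::Surv()]
#'   counting-process response, e.g.
#'   `Surv(start, stop, status) ~ ppi + age70`.  No intercept is used:
#'   the baseline-hazard steps carry the level.
#' @param data data frame holding the start-stop table.
#' @param id name of the participant-id column; required for frailty.
#' @param frailty logical: include iid Gaussian individual frailty.
#' @param coords `NULL`, or the names of two coordinate columns (or a
#'   two-column matrix) switching on the spatial Matern effect;
#'   coincident locations share one effect.
#' @param bins either a single integer (number of equal-width bins over
#'   the observed time range; default 24) or a vector of bin
#'   boundaries.
#' @param nu Matern smoothness; default 1.
#' @param smooth logical: RW1 smoothness penalty on the log baseline
#'   hazard (default TRUE; automatically off with a single bin).  When
#'   FALSE the baseline steps are unpenalised and, with random effects
#'   off, the fit reproduces Poisson-GLM maximum likelihood.
#' @param priors a [bpeh_priors()] object.
#' @param control a [bpeh_control()] object.
#' @param fixed named list fixing hyperparameters instead of optimising
#'   them, e.g. `list(sigma_u = 0.3)` or `list(range_s = 0.2)`.
#' @return object of class `"bpeh"`; see [summary.bpeh()],
#'   [hazard_ratio()], [predict.bpeh()], [plot.bpeh()].
#' @examples
#' d <- data.frame(start = 0, stop = c(2, 4, 6, 8), status = c(1, 1, 0, 1),
#'                 x = c(1, 0, 1, 0))
#' f <- bpeh(survival::Surv(start, stop, status) ~ x, d, bins = 1)
#' hazard_ratio(f, "x")
#' @export
bpeh <- function(formula, data, id = NULL, frailty = FALSE, coords = NULL,
                 bins = 24, nu = 1, smooth = TRUE,
                 priors = bpeh_priors(), control = bpeh_control(),
                 fixed = list()) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv") || attr(y, "type") != "counting") {
    stop("the response must be Surv(start, stop, status)")
  }
  cp <- data.frame(start = y[, 1], stop = y[, 2], status = y[, 3])
  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) == 0L) X <- NULL

  if (length(bins) == 1L) {
    breaks <- seq(min(cp$start), max(cp$stop), length.out = bins + 1)
  } else breaks <- sort(bins)
  if (breaks[1] > min(cp$start) || breaks[length(breaks)] < max(cp$stop)) {
    stop("bins do not cover the observed time range")
  }

  uid <- NULL
  if (!is.null(id)) {
    uid <- factor(data[[id]])
    dup_ev <- tapply(cp$status, uid, sum)
    if (any(dup_ev > 1)) stop("a participant has more than one event row")
  }
  if (frailty && is.null(uid)) stop("frailty requires an id column")

  sidx_row <- NULL; uloc <- NULL
  if (!is.null(coords)) {
    locs <- if (is.character(coords)) as.matrix(data[, coords]) else
      as.matrix(coords)
    key <- paste(locs[, 1], locs[, 2], sep = "\r")
    ukey <- unique(key)
    sidx_row <- match(key, ukey)
    uloc <- locs[match(ukey, key), , drop = FALSE]
  }

  ex <- poisson_expand(cp, breaks)
  row <- attr(ex, "row")
  Xe <- if (is.null(X)) NULL else X[row, , drop = FALSE]
  uidx <- if (frailty) as.integer(uid)[row] else NULL
  sidx <- if (!is.null(sidx_row)) sidx_row[row] else NULL
  stack <- build_stack(ex, Xe, breaks, uidx = uidx, sidx = sidx,
                       uloc = uloc, nu = nu, smooth = smooth)

  # active hyperparameters and their starting values (log scale)
  hyper_names <- character(); theta0 <- numeric()
  if (stack$smooth && is.null(fixed$sigma_rw)) {
    hyper_names <- c(hyper_names, "sigma_rw"); theta0 <- c(theta0, log(0.5))
  }
  if (frailty && is.null(fixed$sigma_u)) {
    hyper_names <- c(hyper_names, "sigma_u"); theta0 <- c(theta0, log(0.3))
  }
  if (!is.null(uloc)) {
    if (is.null(priors$range0)) {
      priors$range0 <- 0.1 * max(stats::dist(uloc))
    }
    if (is.null(fixed$sigma_s)) {
      hyper_names <- c(hyper_names, "sigma_s"); theta0 <- c(theta0, log(0.5))
    }
    if (is.null(fixed$range_s)) {
      hyper_names <- c(hyper_names, "range_s")
      theta0 <- c(theta0, log(5 * priors$range0))
    }
  }

  warm <- new.env()
  warm$x <- NULL
  obj <- function(th) -laplace_logpost(th, stack, hyper_names, fixed,
                                       priors, control, warm)
  opt <- NULL
  if (length(hyper_names) == 0L) {
    theta_hat <- numeric()
  } else if (length(hyper_names) == 1L) {
    opt <- stats::optimize(obj, c(control$theta_min, control$theta_max),
                           tol = control$outer_reltol)
    theta_hat <- opt$minimum
  } else {
    opt <- stats::optim(theta0, obj, method = "Nelder-Mead",
                        control = list(reltol = control$outer_reltol,
                                       maxit = control$outer_maxit))
    theta_hat <- opt$par
  }
  theta_hat <- pmin(pmax(theta_hat, control$theta_min), control$theta_max)
  theta <- fixed
  for (i in seq_along(hyper_names)) theta[[hyper_names[i]]] <- exp(theta_hat[i])

  qq <- build_Q(stack, theta)
  fit <- fit_latent(stack, qq$Q, x0 = warm$x, control = control)
  logml <- fit$logjoint + 0.5 * qq$gdet - 0.5 * chol_logdet(fit$ch)

  # marginal posterior SDs of baseline steps and fixed effects
  nfix <- stack$B + stack$p
  V <- matrix(0, nfix, nfix)
  for (j in seq_len(nfix)) {
    ej <- rep(0, stack$K); ej[j] <- 1
    V[, j] <- as.vector(solve(fit$ch, ej))[seq_len(nfix)]
  }
  sds <- sqrt(pmax(diag(V), 0))

  beta <- if (stack$p) setNames(fit$x[stack$idx$beta], stack$xnames) else
    numeric()
  degenerate <- character()
  if (frailty && !is.null(theta$sigma_u) && theta$sigma_u < 1e-3) {
    degenerate <- c(degenerate, "sigma_u")
  }
  if (!is.null(theta$sigma_s) && theta$sigma_s < 1e-3) {
    degenerate <- c(degenerate, "sigma_s")
  }

  structure(list(
    call = cl, formula = formula, terms = mt, breaks = breaks,
    coefficients = beta,
    beta_sd = if (stack$p) setNames(sds[stack$idx$beta], stack$xnames) else
      numeric(),
    vcov_fixed = if (stack$p)
      V[stack$idx$beta, stack$idx$beta, drop = FALSE] else matrix(0, 0, 0),
    lambda = fit$x[stack$idx$lambda],
    lambda_sd = sds[stack$idx$lambda],
    frailty = if (frailty) setNames(fit$x[stack$idx$u], levels(uid)) else NULL,
    spatial = if (!is.null(uloc))
      data.frame(x = uloc[, 1], y = uloc[, 2],
                 effect = fit$x[stack$idx$s]) else NULL,
    hyper = unlist(theta),
    priors = priors, logml = logml,
    iterations = fit$iterations, grad_norm = fit$grad_norm,
    converged = fit$converged, degenerate = degenerate, opt = opt,
    n = if (is.null(uid)) nrow(cp) else nlevels(uid),
    n_events = sum(cp$status), total_exposure = sum(cp$stop - cp$start),
    smooth = stack$smooth), class = "bpeh")
}
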