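#' @export
print.bpeh <- function(x, ...) {
  cat("Bayesian piecewise-exponential hazard model\n")
  cat(sprintf("  %d participants, %d events, %.0f days at risk, %d bins%s\n",
              x$n, x$n_events, x$total_exposure, length(x$lambda),
              if (x$smooth) " (RW1-smoothed)" else ""))
  if (length(x$coefficients)) {
    cat("Fixed effects (posterior mode, log hazard scale):\n")
    print(round(x$coefficients, 4))
  }
  if (length(x$hyper)) {
    cat("Hyperparameters:",
        paste(names(x$hyper), signif(x$hyper, 3), sep = " = ",
              collapse = ", "), "\n")
  }
  if (length(x$degenerate)) {
    cat("Degenerate (collapsed to 0):", paste(x$degenerate, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Summarise a fitted hazard model
#'
#' @param object a [bpeh()] fit.
#' @param level credible level for the Gaussian-approximation
#'   intervals; default 0.95.
#' @param ... unused.
#' @return object of class `"summary.bpeh"` whose `coefficients` table
#'   holds posterior mode, SD, hazard ratio and credible bounds per
#'   fixed effect.
#' @export
summary.bpeh <- function(object, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  co <- data.frame(
    mode = object$coefficients,
    sd = object$beta_sd,
    hr = exp(object$coefficients),
    lower = exp(object$coefficients - z * object$beta_sd),
    upper = exp(object$coefficients + z * object$beta_sd),
    row.names = names(object$coefficients))
  structure(list(coefficients = co, hyper = object$hyper,
                 logml = object$logml, level = level, n = object$n,
                 n_events = object$n_events,
                 degenerate = object$degenerate, call = object$call),
            class = "summary.bpeh")
}

#' @export
print.summary.bpeh <- function(x, ...) {
  cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("%d participants, %d events\n", x$n, x$n_events))
  cat(sprintf("Fixed effects (HR with %g%% credible interval):\n",
              100 * x$level))
  print(round(x$coefficients, 4))
  if (length(x$hyper)) {
    cat("Hyperparameters:",
        paste(names(x$hyper), signif(x$hyper, 3), sep = " = ",
              collapse = ", "), "\n")
  }
  cat("Laplace log marginal likelihood:", round(x$logml, 2), "\n")
  invisible(x)
}

#' @export
coef.bpeh <- function(object, ...) object$coefficients

#' @export
vcov.bpeh <- function(object, ...) {
  v <- object$vcov_fixed
  dimnames(v) <- list(names(object$coefficients), names(object$coefficients))
  v
}

#' @export
confint.bpeh <- function(object, parm, level = 0.95, ...) {
  co <- summary(object, level = level)$coefficients
  out <- log(as.matrix(co[, c("lower", "upper")]))
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Hazard ratio with credible interval
#'
#' Posterior-mode hazard ratio \eqn{\exp(\hat\beta)} and its Gaussian
#' Laplace credible interval
#' \eqn{\exp(\hat\beta \pm z \cdot \mathrm{sd})} for one or all model
#' covariates.
#'
#' @param fit a [bpeh()] fit.
#' @param covariate covariate name; `NULL` returns all.
#' @param level credible level; default 0.95.
#' @return data frame with columns `hr`, `lower`, `upper`.
#' @export
hazard_ratio <- function(fit, covariate = NULL, level = 0.95) {
  co <- summary(fit, level = level)$coefficients
  if (!is.null(covariate)) {
    if (!all(covariate %in% rownames(co))) {
      stop("unknown covariate: ",
           paste(setdiff(covariate, rownames(co)), collapse = ", "))
    }
    co <- co[covariate, , drop = FALSE]
  }
  co[, c("hr", "lower", "upper")]
}

#' Baseline hazard and survival predictions
#'
#' `type = "hazard"` returns the baseline-hazard step value per bin;
#' `"cumhaz"` and `"survival"` integrate the steps, optionally for a
#' covariate profile in `newdata` (one row; the linear predictor
#' multiplies the baseline hazard).
#'
#' @param object a [bpeh()] fit.
#' @param times evaluation times (days); defaults to bin boundaries.
#' @param newdata optional one-row data frame of covariate values;
#'   omitted means the reference profile (all covariates 0).
#' @param type `"hazard"`, `"cumhaz"`, `"survival"` or `"lp"`.
#' @param ... unused.
#' @return data frame `time`, `value`.
#' @export
predict.bpeh <- function(object, times = NULL, newdata = NULL,
                         type = c("survival", "cumhaz", "hazard", "lp"),
                         ...) {
  type <- match.arg(type)
  lp <- 0
  if (!is.null(newdata)) {
    X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
    lp <- as.vector(X %*% object$coefficients)[1]
  }
  if (type == "lp") return(lp)
  br <- object$breaks
  if (is.null(times)) times <- br[-1]
  h <- exp(object$lambda + lp)
  if (type == "hazard") {
    bin <- pmin(pmax(findInterval(times, br, left.open = TRUE), 1),
                length(h))
    return(data.frame(time = times, value = h[bin]))
  }
  cum_at_break <- c(0, cumsum(h * diff(br)))
  cum <- vapply(times, function(t) {
    t <- min(max(t, br[1]), br[length(br)])
    k <- pmin(findInterval(t, br, left.open = TRUE), length(h))
    if (k < 1) return(0)
    cum_at_break[k] + h[k] * (t - br[k])
  }, numeric(1))
  if (type == "cumhaz") return(data.frame(time = times, value = cum))
  data.frame(time = times, value = exp(-cum))
}

#' Martingale residuals
#'
#' Residuals of the expanded Poisson representation,
#' \eqn{d_r - E_r e^{\hat\eta_r}}, aggregated per participant when the
#' fit carries frailty (otherwise per input row).  Random effects are
#' included in \eqn{\hat\eta}.
#'
#' @param object a [bpeh()] fit.
#' @param data the counting-process data the model was fitted to.
#' @param ... unused.
#' @return named numeric vector.
#' @export
residuals.bpeh <- function(object, data = NULL, ...) {
  if (is.null(data)) stop("supply the counting-process data used in the fit")
  mf <- stats::model.frame(object$formula, data)
  y <- stats::model.response(mf)
  cp <- data.frame(start = y[, 1], stop = y[, 2], status = y[, 3])
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  ex <- poisson_expand(cp, object$breaks)
  row <- attr(ex, "row")
  lp <- object$lambda[ex$bin]
  if (length(object$coefficients)) {
    lp <- lp + as.vector(X[row, , drop = FALSE] %*% object$coefficients)
  }
  r <- ex$d - ex$exposure * exp(lp)
  tapply(r, row, sum)[as.character(seq_len(nrow(cp)))]
}

#' Plot the fitted baseline hazard
#'
#' Draws the posterior-mode baseline-hazard step function with a
#' pointwise Gaussian credible band.
#'
#' @param x a [bpeh()] fit.
#' @param level credible level; default 0.95.
#' @param log_scale plot on the log-hazard scale; default TRUE.
#' @param ... passed to [plot()].
#' @export
plot.bpeh <- function(x, level = 0.95, log_scale = TRUE, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  br <- x$breaks
  mid <- head(br, -1) + diff(br) / 2
  val <- if (log_scale) x$lambda else exp(x$lambda)
  lo <- if (log_scale) x$lambda - z * x$lambda_sd else
    exp(x$lambda - z * x$lambda_sd)
  hi <- if (log_scale) x$lambda + z * x$lambda_sd else
    exp(x$lambda + z * x$lambda_sd)
  plot(mid, val, type = "s", ylim = range(lo, hi),
       xlab = "days since study start",
       ylab = if (log_scale) "log baseline hazard (per day)" else
         "baseline hazard (per day)", ...)
  graphics::lines(mid, lo, type = "s", lty = 2)
  graphics::lines(mid, hi, type = "s", lty = 2)
  invisible(x)
}

#' @importFrom survival Surv
#' @export
survival::Surv
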