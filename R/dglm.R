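#' Double generalized linear model for joint mean and dispersion estimation
#'
#' Fits a mean submodel and a log-linear dispersion submodel jointly by
#' iterating between (weighted) least squares for the mean and a gamma GLM
#' with log link on leverage-corrected squared residuals (Gaussian traits) or
#' leverage-corrected unit deviances (Poisson traits). This is the estimation
#' engine behind the parametric vQTL dispersion test: a covariate (typically
#' an allele dosage) entering the dispersion submodel with a nonzero
#' coefficient means the trait variance depends on genotype beyond what the
#' mean model already implies.
#'
#' For a Gaussian trait the model is
#' \deqn{y_i \sim N(x_i^T \beta,\; \sigma_i^2), \qquad
#'       \log \sigma_i^2 = z_i^T \lambda,}
#' fitted by cycling: (1) weighted least squares of `y` on the mean design
#' with weights \eqn{1/\sigma_i^2}; (2) a gamma GLM with log link of the
#' leverage-corrected squared residuals \eqn{d_i = \hat e_i^2/(1-h_{ii})} on
#' the dispersion design, with prior weights \eqn{(1-h_{ii})/2}; (3) update
#' \eqn{\sigma_i^2 = \exp(z_i^T\hat\lambda)}. Division by \eqn{1-h_{ii}}
#' corrects the downward bias of estimated squared residuals (they are
#' residuals of a fitted, not the true, mean). For a Poisson trait the mean
#' submodel is a log-link Poisson GLM with prior weights \eqn{1/\phi_i} and
#' the dispersion response is the unit deviance
#' \eqn{d_i = 2[y_i \log(y_i/\hat\mu_i) - (y_i - \hat\mu_i)]}
#' (with \eqn{0\log 0 = 0}), leverage-corrected identically.
#'
#' The reported log-likelihood is the exact normal log-likelihood for the
#' Gaussian family and the extended quasi-likelihood (EQL) for Poisson.
#'
#' @param formula mean-submodel formula, e.g. `y ~ g` or `y ~ sex + g`.
#' @param dformula dispersion-submodel formula (right-hand side only),
#'   e.g. `~ g`. Defaults to `~ 1` (constant dispersion).
#' @param data data frame in which the formulas are evaluated.
#' @param family `"gaussian"` or `"poisson"` (log link mean submodel;
#'   requires non-negative integer responses).
#' @param maxit maximum number of outer iterations.
#' @param tol convergence tolerance on the maximum relative change in the
#'   stacked coefficient vector \eqn{(\beta, \lambda)}.
#' @return an object of class `"dglm"` with components `coefficients`
#'   (mean submodel \eqn{\beta}), `dispersion$coefficients`
#'   (\eqn{\lambda}), `sigma2` (per-observation variance, or per-observation
#'   dispersion \eqn{\phi_i} for Poisson), `leverages`, `loglik`,
#'   `iter`, `converged`, standard errors for both submodels, and the call.
#' @seealso [dglm_vqtl_test()] for the single-marker dispersion test built
#'   on two nested `dglm` fits; [leverages()] for the hat values.
#' @examples
#' set.seed(1)
#' d <- data.frame(g = rbinom(200, 2, 0.4))
#' d$y <- rnorm(200, 0.1 * d$g, exp(0.5 * 0.2 * d$g))
#' fit <- dglm(y ~ g, ~ g, data = d)
#' summary(fit)
#' coef(fit, "dispersion")
#' @export
dglm <- function(formula, dformula = ~1, data, family = c("gaussian", "poisson"),
                 maxit = 100, tol = 1e-8) {
  family <- match.arg(family)
  cl <- match.call()
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X_m <- model.matrix(formula, mf)
  X_d <- model.matrix(dformula, model.frame(dformula, data))
  fit <- dglm_fit(y, X_m, X_d, family = family, maxit = maxit, tol = tol)
  fit$call <- cl
  fit$formula <- formula
  fit$dformula <- dformula
  fit
}

#' Low-level DGLM fitting on design matrices
#'
#' The workhorse behind [dglm()]: takes a response and explicit design
#' matrices for the mean and dispersion submodels. Exposed because the
#' benchmark and scan code build designs directly.
#'
#' @param y numeric response vector; for `family = "poisson"` non-negative
#'   integers.
#' @param X_m mean-submodel design matrix (n x p_m, full column rank).
#' @param X_d dispersion-submodel design matrix (n x p_d, full column rank).
#' @inheritParams dglm
#' @return an object of class `"dglm"`; see [dglm()].
#' @export
dglm_fit <- function(y, X_m, X_d, family = c("gaussian", "poisson"),
                     maxit = 100, tol = 1e-8) {
  family <- match.arg(family)
  n <- length(y)
  if (!is.matrix(X_m)) X_m <- as.matrix(X_m)
  if (!is.matrix(X_d)) X_d <- as.matrix(X_d)
  p_m <- ncol(X_m); p_d <- ncol(X_d)
  if (!all(is.finite(y))) stop("response contains non-finite values")
  if (nrow(X_m) != n || nrow(X_d) != n) stop("design row count does not match response length")
  if (n <= p_m || n <= p_d) stop("more coefficients than observations")
  if (qr(X_m)$rank < p_m) stop("mean design matrix is rank deficient")
  if (qr(X_d)$rank < p_d) stop("dispersion design matrix is rank deficient")
  if (family == "poisson" && (any(y < 0) || any(y != round(y))))
    stop("poisson family requires non-negative integer responses")

  gam <- Gamma(link = "log")
  phi <- rep.int(1, n)
  theta_old <- NULL
  converged <- FALSE
  loglik_trace <- numeric(0)
  warn <- character(0)
  it <- 0L
  fm <- fd <- NULL
  e <- h <- mu <- NULL

  for (it in seq_len(maxit)) {
    if (family == "gaussian") {
      fm <- lm.wfit(X_m, y, w = 1 / phi)
      e <- fm$residuals
      h <- .hat_qr(fm$qr, p_m, n)
      d <- e^2 / (1 - h)
    } else {
      fm <- suppressWarnings(glm.fit(X_m, y, weights = 1 / phi, family = poisson()))
      mu <- fm$fitted.values
      h <- .hat_qr(fm$qr, p_m, n)
      d <- .poisson_unit_dev(y, mu) / (1 - h)
    }
    d <- pmax(d, 1e-10)
    fd <- suppressWarnings(glm.fit(X_d, d, weights = (1 - h) / 2, family = gam,
                                   control = glm.control(epsilon = 1e-12,
                                                         maxit = 50)))
    lambda <- fd$coefficients
    eta_d <- drop(X_d %*% lambda)
    if (max(abs(eta_d)) > 700)
      stop("dispersion linear predictor diverged (|eta| > 700)")
    phi <- exp(eta_d)
    loglik_trace <- c(loglik_trace, .dglm_loglik(y, fm, phi, family))
    theta <- c(fm$coefficients, lambda)
    if (!is.null(theta_old)) {
      delta <- max(abs(theta - theta_old) / pmax(abs(theta_old), 1e-4))
      if (delta < tol) { converged <- TRUE; break }
    }
    theta_old <- theta
  }
  if (!converged) {
    warn <- c(warn, "max_iter_reached")
    warning("dglm did not converge in ", maxit, " iterations")
  }
  nt <- length(loglik_trace)
  if (nt > 1 && any(diff(loglik_trace) < -1e-6)) {
    warn <- c(warn, "loglik_decreased")
    warning("log-likelihood decreased during dglm iterations")
  }

  ## mean-submodel covariance at convergence
  R_m <- qr.R(fm$qr)[, order(fm$qr$pivot), drop = FALSE]
  cov_m <- chol2inv(chol(crossprod(R_m)))
  if (family == "gaussian") {
    se_m <- sqrt(diag(cov_m))
  } else {
    se_m <- sqrt(diag(cov_m))   # IRLS information already includes weights
  }
  ## dispersion-submodel covariance: gamma GLM information with the
  ## chi^2_1 dispersion factor 2 absorbed by the (1-h)/2 prior weights
  R_d <- qr.R(fd$qr)[, order(fd$qr$pivot), drop = FALSE]
  cov_d <- chol2inv(chol(crossprod(R_d)))
  se_d <- sqrt(diag(cov_d))

  beta <- fm$coefficients
  names(se_m) <- names(beta)
  lambda <- fd$coefficients
  names(se_d) <- names(lambda)

  structure(list(
    coefficients = beta,
    se = se_m,
    dispersion = list(coefficients = lambda, se = se_d, cov = cov_d),
    fitted.values = if (family == "gaussian") drop(y - e) else mu,
    residuals = if (family == "gaussian") e else y - mu,
    sigma2 = phi,
    leverages = h,
    loglik = loglik_trace[length(loglik_trace)],
    loglik_trace = loglik_trace,
    iter = it,
    converged = converged,
    warnings = warn,
    family = family,
    n = n, p_m = p_m, p_d = p_d,
    y = y, X_m = X_m, X_d = X_d
  ), class = "dglm")
}

## unit deviance of the Poisson family, with the 0*log(0) = 0 convention
.poisson_unit_dev <- function(y, mu) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  2 * (t1 - (y - mu))
}

.dglm_loglik <- function(y, fm, phi, family) {
  if (family == "gaussian") {
    -0.5 * sum(log(2 * pi * phi) + fm$residuals^2 / phi)
  } else {
    ## extended quasi-likelihood; V(y) floored at 1/6 for zero counts
    ## (the term is constant across nested fits, so LRTs are unaffected)
    d0 <- .poisson_unit_dev(y, fm$fitted.values)
    -0.5 * sum(d0 / phi + log(2 * pi * phi * pmax(y, 1 / 6)))
  }
}

## leverages of the (weighted) projection from a QR decomposition:
## rowSums of squares of the thin-Q factor
.hat_qr <- function(qrobj, p, n) {
  rowSums(qr.qy(qrobj, diag(1, n, p))^2)
}

#' Hat values (leverages) of a weighted least-squares projection
#'
#' Returns the diagonal of \eqn{H = W^{1/2} X (X^T W X)^{-1} X^T W^{1/2}},
#' the matrix mapping observed to fitted responses. Leverages quantify how
#' much each observation's squared residual underestimates its true squared
#' error; the DGLM divides squared residuals by \eqn{1 - h_{ii}} to correct
#' this, and [hat_screen()] uses them to vet two-stage tests.
#'
#' @param X design matrix, full column rank.
#' @param w optional positive observation weights (default all 1).
#' @return numeric vector of leverages, each in \[0, 1\], summing to `ncol(X)`.
#' @examples
#' leverages(cbind(1, 0:2))   # c(5/6, 1/3, 5/6)
#' @export
leverages <- function(X, w = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep.int(1, n)
  if (any(w <= 0)) stop("weights must be positive")
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < p) stop("design matrix is singular")
  .hat_qr(qrX, p, n)
}

#' @export
print.dglm <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Double generalized linear model (", x$family, " family)\n", sep = "")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat("\nMean coefficients:\n")
  print(round(x$coefficients, digits))
  cat("\nDispersion (log scale) coefficients:\n")
  print(round(x$dispersion$coefficients, digits))
  cat("\nLog-likelihood:", format(x$loglik, digits = digits),
      " iterations:", x$iter,
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

#' @export
summary.dglm <- function(object, ...) {
  mk <- function(b, s, df) {
    t <- b / s
    p <- if (is.finite(df)) 2 * pt(abs(t), df, lower.tail = FALSE)
         else 2 * pnorm(abs(t), lower.tail = FALSE)
    cbind(Estimate = b, `Std. Error` = s, `t value` = t, `Pr(>|t|)` = p)
  }
  df_m <- if (object$family == "gaussian") object$n - object$p_m else Inf
  out <- list(
    call = object$call, family = object$family,
    mean_table = mk(object$coefficients, object$se, df_m),
    dispersion_table = mk(object$dispersion$coefficients, object$dispersion$se, Inf),
    loglik = object$loglik, iter = object$iter, converged = object$converged,
    n = object$n
  )
  class(out) <- "summary.dglm"
  out
}

#' @export
print.summary.dglm <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Double generalized linear model (", x$family, " family), n = ", x$n, "\n", sep = "")
  cat("\nMean submodel:\n")
  printCoefmat(x$mean_table, digits = digits)
  cat("\nDispersion submodel (log scale):\n")
  printCoefmat(x$dispersion_table, digits = digits)
  cat("\nLog-likelihood:", format(x$loglik, digits = digits),
      " iterations:", x$iter,
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

#' @param part `"mean"` for \eqn{\beta}, `"dispersion"` for \eqn{\lambda}.
#' @rdname dglm
#' @param object,x a fitted `dglm` object.
#' @param ... passed on / ignored.
#' @export
coef.dglm <- function(object, part = c("mean", "dispersion"), ...) {
  part <- match.arg(part)
  if (part == "mean") object$coefficients else object$dispersion$coefficients
}

#' @export
fitted.dglm <- function(object, ...) object$fitted.values

#' @export
residuals.dglm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "pearson") {
    v <- if (object$family == "gaussian") object$sigma2
         else object$sigma2 * object$fitted.values
    r <- r / sqrt(v)
  }
  r
}

#' @export
logLik.dglm <- function(object, ...) {
  structure(object$loglik, df = object$p_m + object$p_d,
            nobs = object$n, class = "logLik")
}

#' Predict means and variances from a fitted DGLM
#'
#' @param object a fitted `dglm` object.
#' @param newdata optional data frame; fitted values are returned when absent.
#' @param what `"mean"` for the fitted mean, `"dispersion"` for the fitted
#'   variance (Gaussian) or dispersion factor (Poisson).
#' @param ... ignored.
#' @export
predict.dglm <- function(object, newdata = NULL,
                         what = c("mean", "dispersion"), ...) {
  what <- match.arg(what)
  if (is.null(newdata)) {
    return(if (what == "mean") object$fitted.values else object$sigma2)
  }
  if (is.null(object$formula))
    stop("predict with newdata requires a fit from the formula interface")
  if (what == "mean") {
    X <- model.matrix(delete.response(terms(object$formula)), newdata)
    eta <- drop(X %*% object$coefficients)
    if (object$family == "poisson") exp(eta) else eta
  } else {
    Z <- model.matrix(object$dformula, newdata)
    exp(drop(Z %*% object$dispersion$coefficients))
  }
}

#' Simulate responses from a fitted DGLM
#'
#' Draws new traits from the fitted generative model: Gaussian with
#' per-observation variance `sigma2`, or Poisson at the fitted mean
#' (the dispersion submodel does not alter Poisson draws).
#'
#' @param object a fitted `dglm` object.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... ignored.
#' @return a data frame with `nsim` columns, one simulated response each.
#' @export
simulate.dglm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  sims <- replicate(nsim, {
    if (object$family == "gaussian")
      rnorm(n, object$fitted.values, sqrt(object$sigma2))
    else
      rpois(n, object$fitted.values)
  })
  as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
}

#' Diagnostic plots for a fitted DGLM
#'
#' Left: absolute Pearson residuals against fitted means (residual
#' heteroscedasticity after dispersion modelling should be absent).
#' Right: log-likelihood trace across the outer iterations.
#'
#' @param x a fitted `dglm` object.
#' @param ... passed to [plot()].
#' @export
plot.dglm <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(x$fitted.values, abs(residuals(x, "pearson")),
       xlab = "Fitted mean", ylab = "|Pearson residual|", ...)
  plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
       xlab = "Iteration", ylab = "Log-likelihood", ...)
  invisible(x)
}
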