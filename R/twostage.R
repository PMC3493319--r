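#' Two-stage squared-residual tests for variance effects (SVLM and variants)
#'
#' Stage 1 fits an ordinary least-squares "GWAS" model of the trait on an
#' intercept, optional covariates, and (by default) the marker dosage.
#' Stage 2 regresses a function of the stage-1 residuals on the dosage:
#' \describe{
#'   \item{`normal_sq`}{(SVLM) least squares of the squared residuals
#'     \eqn{\hat e^2} on `[1, g]`, with a t-test on the dosage slope;}
#'   \item{`gamma_sq`}{a gamma GLM with log link of \eqn{\hat e^2} on
#'     `[1, g]`, Wald test (the Visscher-Posthuma approximation);}
#'   \item{`normal_abs`}{least squares of \eqn{|\hat e|} on `[1, g]`.}
#' }
#' These approximate the parametric joint fit at a fraction of its cost but
#' condition on estimated residuals without accounting for their estimation
#' error; run [hat_screen()] on the stage-1 design before trusting them on
#' small or unbalanced data.
#'
#' @param y numeric trait vector.
#' @param g allele dosage vector (fractional values allowed).
#' @param covariates optional matrix / data frame of stage-1 covariates.
#' @param stage2 stage-2 model; see Details.
#' @param stage1_includes_snp keep the marker in the stage-1 mean model
#'   (default `TRUE`, an ordinary GWAS model; set `FALSE` for
#'   covariate-only pre-correction).
#' @param stage2_includes_covariates also carry the covariates into stage 2
#'   (default `FALSE`; they were already removed in stage 1).
#' @param marker_id optional marker label.
#' @return a `vqtl_test` result; `mean_beta`/`mean_p` report the stage-1
#'   dosage effect when the marker is in stage 1.
#' @export
svlm_test <- function(y, g, covariates = NULL,
                      stage2 = c("normal_sq", "gamma_sq", "normal_abs"),
                      stage1_includes_snp = TRUE,
                      stage2_includes_covariates = FALSE,
                      marker_id = NA_character_) {
  stage2 <- match.arg(stage2)
  n <- length(y)
  if (length(g) != n) stop("y and g lengths differ")
  if (length(unique(g)) < 2) stop("marker is monomorphic")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X1 <- cbind(matrix(1, n, 1), C, if (stage1_includes_snp) g)
  p1 <- ncol(X1)
  if (n <= p1 + 2) stop("too few observations for the two-stage fit")
  f1 <- lm.fit(X1, y)
  e <- f1$residuals
  if (all(abs(e) < 1e-12 * max(1, abs(y))))
    stop("stage-1 fit is saturated: residuals are all zero")
  warn <- character(0)

  mean_beta <- mean_se <- mean_p <- NA_real_
  if (stage1_includes_snp) {
    R1 <- qr.R(f1$qr)[, order(f1$qr$pivot), drop = FALSE]
    s2 <- sum(e^2) / (n - p1)
    mean_beta <- unname(f1$coefficients[p1])
    mean_se <- sqrt(s2 * chol2inv(chol(crossprod(R1)))[p1, p1])
    mean_p <- 2 * pt(abs(mean_beta / mean_se), n - p1, lower.tail = FALSE)
  }

  X2 <- cbind(1, if (stage2_includes_covariates) C, g)
  p2 <- ncol(X2)
  ig <- p2
  r2_probe <- if (stage2 == "normal_abs") abs(e) else e^2
  if (diff(range(r2_probe)) < 1e-12 * max(1, max(r2_probe))) {
    ## perfectly homoscedastic residual transform: nothing to regress
    return(new_vqtl_test(marker_id = marker_id,
                         method = if (stage2 == "gamma_sq") "svlm_gamma"
                                  else if (stage2 == "normal_abs") "absres"
                                  else "svlm",
                         n_used = n,
                         mean_beta = mean_beta, mean_se = mean_se,
                         mean_p = mean_p,
                         disp_beta = 0, disp_se = NA_real_,
                         disp_stat = 0, disp_df = 1, disp_p = 1,
                         warnings = "constant_stage2_response",
                         note = paste0("stage2=", stage2)))
  }
  if (stage2 == "gamma_sq") {
    r2 <- e^2
    if (any(r2 == 0)) {
      warning("zero squared residuals floored at 1e-12 for the gamma fit")
      warn <- c(warn, "zero_sq_residual_floored")
      r2 <- pmax(r2, 1e-12)
    }
    f2 <- suppressWarnings(glm.fit(X2, r2, family = Gamma(link = "log")))
    R2 <- qr.R(f2$qr)[, order(f2$qr$pivot), drop = FALSE]
    ## gamma dispersion by the Pearson estimator, as summary.glm does
    mu2 <- f2$fitted.values
    phi <- sum((r2 - mu2)^2 / mu2^2) / (n - p2)
    se <- sqrt(phi * chol2inv(chol(crossprod(R2)))[ig, ig])
    beta2 <- unname(f2$coefficients[ig])
    tstat <- beta2 / se
    p <- 2 * pt(abs(tstat), n - p2, lower.tail = FALSE)
  } else {
    r2 <- if (stage2 == "normal_sq") e^2 else abs(e)
    f2 <- lm.fit(X2, r2)
    R2 <- qr.R(f2$qr)[, order(f2$qr$pivot), drop = FALSE]
    s2_2 <- sum(f2$residuals^2) / (n - p2)
    se <- sqrt(s2_2 * chol2inv(chol(crossprod(R2)))[ig, ig])
    beta2 <- unname(f2$coefficients[ig])
    tstat <- beta2 / se
    p <- 2 * pt(abs(tstat), n - p2, lower.tail = FALSE)
  }
  new_vqtl_test(marker_id = marker_id,
                method = if (stage2 == "gamma_sq") "svlm_gamma"
                         else if (stage2 == "normal_abs") "absres" else "svlm",
                n_used = n,
                mean_beta = mean_beta, mean_se = mean_se, mean_p = mean_p,
                disp_beta = beta2, disp_se = se,
                disp_stat = tstat^2, disp_df = 1, disp_p = p,
                warnings = warn, note = paste0("stage2=", stage2))
}

#' Hat-value screen for two-stage variance tests
#'
#' Two-stage tests condition on squared residuals that are biased downwards
#' by a factor \eqn{1 - h_{ii}}. When all leverages of the stage-1 design
#' are small (below 0.05 by convention) the bias is negligible and the
#' shortcut is safe; large leverages flag observations whose residuals are
#' poorly estimated.
#'
#' @param X stage-1 design matrix (including the intercept column).
#' @param threshold leverage threshold above which samples are flagged.
#' @return list with `max_hat`, `flagged` (indices with
#'   \eqn{h_{ii} \ge} `threshold`), `threshold` and logical `pass`.
#' @export
hat_screen <- function(X, threshold = 0.05) {
  h <- leverages(X)
  flagged <- which(h >= threshold)
  structure(list(max_hat = max(h), flagged = flagged,
                 threshold = threshold, pass = length(flagged) == 0),
            class = "hat_screen")
}

#' @export
print.hat_screen <- function(x, ...) {
  cat("Hat-value screen: max h_ii =", format(x$max_hat, digits = 4),
      "(threshold", x$threshold, ")\n")
  if (x$pass) cat("  PASS: residual estimation error is negligible\n")
  else cat("  FLAG:", length(x$flagged), "sample(s) at or above threshold\n")
  invisible(x)
}

#' Concordance of p-values between two methods
#'
#' Pearson correlation of paired raw p-values, used to quantify how closely
#' a two-stage approximation tracks the full parametric test.
#'
#' @param p_a,p_b numeric p-value vectors of equal length (>= 3), in \[0, 1\].
#' @return the Pearson correlation.
#' @export
pvalue_concordance <- function(p_a, p_b) {
  if (length(p_a) != length(p_b) || length(p_a) < 3)
    stop("p-value vectors must have equal length >= 3")
  if (any(p_a < 0 | p_a > 1 | p_b < 0 | p_b > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (sd(p_a) == 0 || sd(p_b) == 0)
    stop("correlation undefined: a p-value vector is constant")
  cor(p_a, p_b)
}
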