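#' @keywords internal
new_vqtl_test <- function(marker_id = NA_character_, method, n_used,
                          mean_beta = NA_real_, mean_se = NA_real_,
                          mean_p = NA_real_,
                          disp_beta = NA_real_, disp_se = NA_real_,
                          disp_stat = NA_real_, disp_df = NA_real_,
                          disp_p = NA_real_, converged = TRUE,
                          warnings = character(0), note = NULL) {
  stopifnot(is.na(disp_p) || (disp_p >= 0 && disp_p <= 1))
  structure(list(
    marker_id = marker_id, method = method, n_used = as.integer(n_used),
    mean_beta = mean_beta, mean_se = mean_se, mean_p = mean_p,
    disp_beta = disp_beta, disp_se = disp_se,
    disp_stat = disp_stat, disp_df = disp_df, disp_p = disp_p,
    converged = converged, warnings = warnings, note = note
  ), class = "vqtl_test")
}

#' @export
print.vqtl_test <- function(x, digits = 4, ...) {
  cat("vQTL test (", x$method, ")",
      if (!is.na(x$marker_id)) paste0(" marker ", x$marker_id),
      ", n = ", x$n_used, "\n", sep = "")
  if (!is.na(x$mean_p))
    cat(sprintf("  mean effect:      beta = %.*g (se %.*g), p = %.*g\n",
                digits, x$mean_beta, digits, x$mean_se, digits, x$mean_p))
  if (!is.na(x$disp_beta))
    cat(sprintf("  dispersion slope: %.*g (se %.*g)\n",
                digits, x$disp_beta, digits, x$disp_se))
  cat(sprintf("  dispersion test:  stat = %.*g, df = %g, p = %.*g\n",
              digits, x$disp_stat, x$disp_df, digits, x$disp_p))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.vqtl_test <- function(x, ...) {
  data.frame(marker_id = x$marker_id, method = x$method, n_used = x$n_used,
             mean_beta = x$mean_beta, mean_se = x$mean_se, mean_p = x$mean_p,
             disp_beta = x$disp_beta, disp_se = x$disp_se,
             disp_stat = x$disp_stat, disp_df = x$disp_df, disp_p = x$disp_p,
             converged = x$converged,
             warnings = paste(x$warnings, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Parametric DGLM test for a variance-controlling locus
#'
#' Fits the full double GLM with the marker dosage in both the mean design
#' `[1, covariates, g]` and the dispersion design `[1, g]`, and a null model
#' with the same mean design but constant dispersion. The default
#' likelihood-ratio statistic `2 (l_full - l_null)` is referred to
#' \eqn{\chi^2(1)}; the Wald alternative uses the dispersion-submodel
#' coefficient and its standard error with a normal reference. The mean
#' effect of the marker is tested from the full model's mean submodel.
#'
#' @param y numeric trait vector.
#' @param g allele dosage vector in \[0, 2\] (fractional dosages allowed).
#' @param covariates optional numeric matrix / data frame of covariates
#'   entering the mean design.
#' @param family `"gaussian"` or `"poisson"`.
#' @param test `"lrt"` (default) or `"wald"`.
#' @param coding `"additive"` (default): dosage enters both submodels as a
#'   single 1-df term; `"genotype"`: hard-called genotype classes enter as
#'   indicator columns, giving a 2-df dispersion test (LRT only).
#' @param marker_id optional marker label.
#' @param maxit,tol passed to [dglm_fit()].
#' @return a `vqtl_test` result; `disp_beta` is the dosage coefficient of
#'   the log-variance submodel, i.e. the log fold-change in residual
#'   variance per allele.
#' @export
dglm_vqtl_test <- function(y, g, covariates = NULL,
                           family = c("gaussian", "poisson"),
                           test = c("lrt", "wald"),
                           coding = c("additive", "genotype"),
                           marker_id = NA_character_,
                           maxit = 100, tol = 1e-8) {
  family <- match.arg(family)
  test <- match.arg(test)
  coding <- match.arg(coding)
  if (length(unique(g)) < 2) stop("marker is monomorphic")
  n <- length(y)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (coding == "genotype") {
    if (test == "wald") stop("genotype coding supports the lrt test only")
    gf <- dosage_to_groups(g)
    G <- model.matrix(~gf)[, -1, drop = FALSE]  # indicator columns
    colnames(G) <- paste0("g", levels(gf)[-1])
  } else {
    G <- cbind(g = g)
  }
  X_m <- cbind(`(Intercept)` = 1, C, G)
  X_d <- cbind(`(Intercept)` = 1, G)
  df_disp <- ncol(G)
  warn <- character(0)
  full <- withCallingHandlers(
    dglm_fit(y, X_m, X_d, family = family, maxit = maxit, tol = tol),
    warning = function(w) { warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning") })
  if (coding == "additive") {
    ig <- ncol(X_m)  # index of g in the mean design
    mean_beta <- unname(full$coefficients[ig])
    mean_se <- unname(full$se[ig])
    mean_p <- if (family == "gaussian")
      2 * pt(abs(mean_beta / mean_se), n - full$p_m, lower.tail = FALSE)
    else 2 * pnorm(abs(mean_beta / mean_se), lower.tail = FALSE)
    disp_beta <- unname(full$dispersion$coefficients[2])
    disp_se <- unname(full$dispersion$se[2])
  } else {
    mean_beta <- mean_se <- mean_p <- disp_beta <- disp_se <- NA_real_
  }
  converged <- full$converged

  if (test == "lrt") {
    null <- withCallingHandlers(
      dglm_fit(y, X_m, matrix(1, n, 1), family = family, maxit = maxit, tol = tol),
      warning = function(w) { warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning") })
    converged <- converged && null$converged
    stat <- 2 * (full$loglik - null$loglik)
    if (stat < -1e-8) warn <- c(warn, "negative_lrt_floored")
    stat <- max(0, stat)
    p <- pchisq(stat, df = df_disp, lower.tail = FALSE)
  } else {
    stat <- (disp_beta / disp_se)^2
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  new_vqtl_test(marker_id = marker_id,
                method = if (family == "gaussian") "dglm" else "dglm_poisson",
                n_used = n,
                mean_beta = mean_beta, mean_se = mean_se, mean_p = mean_p,
                disp_beta = disp_beta, disp_se = disp_se,
                disp_stat = stat, disp_df = df_disp, disp_p = p,
                converged = converged, warnings = unique(warn),
                note = paste0("test=", test, ",coding=", coding))
}
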