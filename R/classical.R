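#' Convert allele dosages to genotype classes
#'
#' Group-based variance tests need discrete genotype classes. Fractional
#' dosages (expected allele counts from imputation) are rounded to the
#' nearest integer in \{0, 1, 2\} using round-half-to-even; a warning reports
#' how many dosages were more than 0.1 from an integer, since hard-calling
#' such genotypes discards real uncertainty (regression-based tests accept
#' the fractional dosage directly and should be preferred there).
#'
#' @param dosages numeric vector of allele dosages in \[0, 2\].
#' @return factor of genotype classes with levels among `"0"`, `"1"`, `"2"`.
#' @export
dosage_to_groups <- function(dosages) {
  if (any(!is.finite(dosages)) || any(dosages < 0) || any(dosages > 2))
    stop("dosages must be finite and within [0, 2]")
  lab <- round(dosages)
  n_frac <- sum(abs(dosages - lab) > 0.1)
  if (n_frac > 0)
    warning(n_frac, " dosage(s) more than 0.1 from an integer were hard-called")
  f <- factor(lab, levels = sort(unique(lab)))
  if (nlevels(f) < 2)
    stop("marker is monomorphic after rounding: fewer than 2 genotype classes")
  f
}

## drop groups with fewer than 2 observations; error if < 2 groups remain
.prep_groups <- function(y, groups) {
  groups <- droplevels(as.factor(groups))
  keep_lv <- names(which(table(groups) >= 2))
  if (length(keep_lv) < nlevels(groups))
    warning("dropping ", nlevels(groups) - length(keep_lv),
            " genotype class(es) with fewer than 2 observations")
  keep <- groups %in% keep_lv
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2)
    stop("fewer than 2 usable genotype classes")
  list(y = y[keep], groups = groups)
}

#' Levene's test for variance heterogeneity across genotype classes
#'
#' Computes absolute deviations \eqn{z_{ij} = |y_{ij} - c_j|} of trait values
#' from their genotype-class centre \eqn{c_j} (class median by default --
#' the Brown-Forsythe variant -- or class mean), then the one-way ANOVA F
#' statistic on the \eqn{z}:
#' \deqn{W = \frac{N-k}{k-1} \cdot
#'   \frac{\sum_j n_j (\bar z_j - \bar z)^2}
#'        {\sum_j \sum_i (z_{ij} - \bar z_j)^2},}
#' referred to \eqn{F(k-1, N-k)}. Being rank-free but centre-robust, it is a
#' standard non-parametric screen for vQTL; it cannot adjust for continuous
#' covariates.
#'
#' @param y numeric trait vector.
#' @param groups genotype class labels (factor or coercible); classes with
#'   fewer than 2 observations are dropped with a warning.
#' @param center `"median"` (Brown-Forsythe, default) or `"mean"`.
#' @param marker_id optional marker label carried into the result.
#' @return a `vqtl_test` result with `disp_stat` = W, `disp_df` = k-1 and
#'   `disp_p` from the F reference.
#' @export
levene_test <- function(y, groups, center = c("median", "mean"),
                        marker_id = NA_character_) {
  center <- match.arg(center)
  pg <- .prep_groups(y, groups)
  y <- pg$y; groups <- pg$groups
  N <- length(y); k <- nlevels(groups)
  if (N - k < 1) stop("no residual degrees of freedom")
  gi <- as.integer(groups)
  cfun <- if (center == "median") median else mean
  cj <- vapply(split(y, groups), cfun, numeric(1))
  z <- abs(y - cj[gi])
  nj <- tabulate(gi, k)
  zbj <- vapply(split(z, groups), mean, numeric(1))
  zb <- mean(z)
  num <- sum(nj * (zbj - zb)^2) / (k - 1)
  den <- sum((z - zbj[gi])^2) / (N - k)
  warn <- character(0)
  if (den <= .Machine$double.eps * max(1, mean(z))^2) {
    if (num <= .Machine$double.eps) {
      warning("all absolute deviations equal; statistic set to 0")
      warn <- "degenerate_deviations"
      W <- 0; p <- 1
    } else stop("zero within-group variance of deviations")
  } else {
    W <- num / den
    p <- pf(W, k - 1, N - k, lower.tail = FALSE)
  }
  new_vqtl_test(marker_id = marker_id, method = "levene", n_used = N,
                disp_stat = W, disp_df = k - 1, disp_p = p, warnings = warn,
                note = paste0("center=", center))
}

#' Fligner-Killeen test for variance heterogeneity
#'
#' Rank-based analogue of Levene's test: absolute deviations from genotype
#' class medians are ranked across all observations (midranks for ties),
#' mapped to normal scores \eqn{a(r) = \Phi^{-1}(1/2 + r/(2(N+1)))}, and the
#' between-class dispersion of mean scores is referred to
#' \eqn{\chi^2(k-1)}. The computation is delegated to
#' [stats::fligner.test()].
#'
#' @inheritParams levene_test
#' @return a `vqtl_test` result with the chi-squared statistic and p-value.
#' @export
fligner_killeen_test <- function(y, groups, marker_id = NA_character_) {
  pg <- .prep_groups(y, groups)
  y <- pg$y; groups <- pg$groups
  gi <- as.integer(groups)
  cj <- vapply(split(y, groups), median, numeric(1))
  warn <- character(0)
  if (all(abs(y - cj[gi]) < .Machine$double.eps * max(1, abs(y)))) {
    warning("all deviations zero; statistic set to 0")
    return(new_vqtl_test(marker_id = marker_id, method = "fligner",
                         n_used = length(y), disp_stat = 0,
                         disp_df = nlevels(groups) - 1, disp_p = 1,
                         warnings = "degenerate_deviations"))
  }
  ft <- fligner.test(y, groups)
  new_vqtl_test(marker_id = marker_id, method = "fligner", n_used = length(y),
                disp_stat = unname(ft$statistic), disp_df = unname(ft$parameter),
                disp_p = ft$p.value, warnings = warn)
}

#' Per-genotype-class descriptive summaries
#'
#' Reports, per genotype class, the count, mean, unbiased variance, standard
#' deviation and coefficient of variation (CV = sd/mean). The CV is the
#' classical scale-aware dispersion measure for positive traits whose
#' standard deviation is expected to grow with the mean; it is flagged
#' undefined (`NA` with `cv_defined = FALSE`) when the class mean is not
#' positive.
#'
#' @param y numeric trait vector.
#' @param groups genotype class labels.
#' @return data frame with one row per class: `group`, `n`, `mean`,
#'   `variance`, `sd`, `cv`, `cv_defined`.
#' @export
group_summary <- function(y, groups) {
  groups <- droplevels(as.factor(groups))
  sp <- split(y, groups)
  out <- data.frame(
    group = names(sp),
    n = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    variance = vapply(sp, function(v) if (length(v) > 1) var(v) else NA_real_,
                      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$sd <- sqrt(out$variance)
  out$cv_defined <- out$mean > 0
  out$cv <- ifelse(out$cv_defined, out$sd / out$mean, NA_real_)
  out
}
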