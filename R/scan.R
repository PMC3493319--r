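#' Genome scan for variance-controlling loci
#'
#' Applies one vQTL test to every marker of a genotype matrix against the
#' trait of a phenotype table, after aligning the two on shared samples.
#' Monomorphic markers are skipped with a warning rather than aborting the
#' scan. For two-stage methods a hat-value screen of each marker's stage-1
#' design is run and its verdict recorded, per the recommendation that
#' squared-residual shortcuts be trusted only when all leverages are small.
#'
#' @param genotypes genotype matrix (see [read_genotypes_tsv()] /
#'   [read_genotypes_vcf()]).
#' @param phenotypes phenotype data frame (see [read_phenotypes_tsv()]).
#' @param method one of `"levene"`, `"fligner"`, `"svlm"`, `"svlm_gamma"`,
#'   `"absres"`, `"dglm"`, `"dglm_poisson"`.
#' @param covariates character vector of phenotype-table column names used
#'   as covariates (regression-based methods only).
#' @param levene_center centring for `"levene"`.
#' @param na_policy passed to [align_samples()].
#' @param ... further arguments to the underlying test.
#' @return data frame of class `"vqtl_scan"`, one row per tested marker,
#'   with the per-marker test fields plus `hat_pass` (`NA` for non-two-stage
#'   methods); attribute `n_skipped` counts skipped markers.
#' @export
vqtl_scan <- function(genotypes, phenotypes, method = c("levene", "fligner",
                      "svlm", "svlm_gamma", "absres", "dglm", "dglm_poisson"),
                      covariates = character(0), levene_center = "median",
                      na_policy = "drop", ...) {
  method <- match.arg(method)
  al <- align_samples(genotypes, phenotypes, na_policy = na_policy)
  g_all <- al$genotypes
  ph <- al$phenotypes
  y <- ph[[2]]
  miss_cov <- setdiff(covariates, names(ph))
  if (length(miss_cov))
    stop("covariate column(s) not in phenotype table: ",
         paste(miss_cov, collapse = ", "))
  C <- if (length(covariates)) as.matrix(ph[, covariates, drop = FALSE]) else NULL
  two_stage <- method %in% c("svlm", "svlm_gamma", "absres")
  rows <- list(); skipped <- character(0)
  for (mk in colnames(g_all)) {
    g <- g_all[, mk]
    res <- tryCatch({
      r <- switch(method,
        levene = levene_test(y, dosage_to_groups(g), center = levene_center,
                             marker_id = mk),
        fligner = fligner_killeen_test(y, dosage_to_groups(g), marker_id = mk),
        svlm = svlm_test(y, g, covariates = C, marker_id = mk, ...),
        svlm_gamma = svlm_test(y, g, covariates = C, stage2 = "gamma_sq",
                               marker_id = mk, ...),
        absres = svlm_test(y, g, covariates = C, stage2 = "normal_abs",
                           marker_id = mk, ...),
        dglm = dglm_vqtl_test(y, g, covariates = C, family = "gaussian",
                              marker_id = mk, ...),
        dglm_poisson = dglm_vqtl_test(y, g, covariates = C,
                                      family = "poisson", marker_id = mk, ...))
      df <- as.data.frame(r)
      df$hat_pass <- if (two_stage)
        hat_screen(cbind(1, C, g))$pass else NA
      df
    }, error = function(e) {
      warning("marker '", mk, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) skipped <- c(skipped, mk) else rows[[mk]] <- res
  }
  if (length(rows) == 0) stop("no markers could be tested")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- length(skipped)
  attr(out, "skipped") <- skipped
  class(out) <- c("vqtl_scan", "data.frame")
  out
}

#' @export
print.vqtl_scan <- function(x, ...) {
  cat("vQTL scan:", nrow(x), "marker(s) tested,",
      length(attr(x, "skipped")), "skipped\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
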