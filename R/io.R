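#' Read a genotype dosage matrix from TSV
#'
#' Expects a tab-separated file with a header row of marker identifiers,
#' one row per sample, and the sample identifier in the first column. Body
#' cells are allele dosages: expected counts of the alternate allele in
#' \[0, 2\], fractional values representing imputed genotypes.
#'
#' @param path file path.
#' @return numeric matrix (samples x markers) with sample ids as row names
#'   and marker ids as column names, validated by [validate_genotypes()].
#' @export
read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", na.strings = ".")
  if (ncol(df) < 2) stop("malformed genotype file: need sample id column plus markers")
  sample_ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(sample_ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad))
      stop("non-numeric dosage at row ", bad[1], ", marker '",
           colnames(body)[j], "'")
    m[, j] <- v
  }
  validate_genotypes(m)
}

#' Validate a genotype dosage matrix
#'
#' Checks finiteness, the \[0, 2\] dosage range, and uniqueness of sample
#' and marker identifiers.
#'
#' @param m numeric matrix, samples in rows (named), markers in columns
#'   (named).
#' @return the validated matrix, invisibly classed `"genotype_matrix"`.
#' @export
validate_genotypes <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("genotype matrix must have sample row names and marker column names")
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(m))) stop("duplicate marker ids")
  if (any(!is.finite(m))) stop("genotype dosages must be finite")
  if (any(m < 0 | m > 2))
    stop("dosage out of range [0, 2]: first offending value ",
         m[which(m < 0 | m > 2)[1]])
  class(m) <- c("genotype_matrix", class(m))
  m
}

#' Write a genotype dosage matrix as TSV
#'
#' @param m genotype matrix (samples x markers, named dimensions).
#' @param path output path.
#' @export
write_genotypes_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' Column 1 is the sample identifier, column 2 the trait, and any remaining
#' columns are covariates. Missing numeric fields are encoded as `.` or
#' `NA`.
#'
#' @param path file path.
#' @return data frame with columns `sample_id`, `trait`, then covariates.
#' @export
read_phenotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = c("NA", "."))
  if (ncol(df) < 2) stop("phenotype file needs sample id and trait columns")
  names(df)[1:2] <- c("sample_id", names(df)[2])
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in phenotype file")
  for (j in 2:ncol(df)) {
    if (!is.numeric(df[[j]])) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      if (any(is.na(v) & !is.na(df[[j]])))
        stop("non-numeric value in phenotype column '", names(df)[j], "'")
      df[[j]] <- v
    }
  }
  df
}

#' Read genotypes from a VCF into allele dosages
#'
#' Converts biallelic records of a VCF v4.x file to per-sample dosages.
#' When a `DS` (dosage) FORMAT field is present it takes precedence;
#' otherwise the alternate-allele count of the `GT` field is used.
#' Multi-allelic records are skipped with a warning. Missing genotypes are
#' either an error or mean-imputed from the observed dosages at that
#' marker, per `missing_policy`.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param missing_policy `"error"` (default) or `"mean_impute"`.
#' @return validated genotype matrix (samples x markers).
#' @export
read_genotypes_vcf <- function(path, missing_policy = c("error", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))   # single record comes back as a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("no records in VCF")
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt)
  if (!all(biallelic))
    warning("skipping ", sum(!biallelic), " multi-allelic marker(s)")
  if (!any(biallelic)) stop("no biallelic markers in VCF")
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  samples <- colnames(gt)
  keep <- which(biallelic)
  m <- matrix(NA_real_, length(samples), length(keep),
              dimnames = list(samples, ids[keep]))
  for (jj in seq_along(keep)) {
    r <- keep[jj]
    if (!is.null(ds) && any(!is.na(ds[r, ]))) {
      dose <- as.numeric(ds[r, ])
    } else {
      gtr <- gt[r, ]
      miss <- is.na(gtr) | grepl("\\.", gtr)
      dose <- rep(NA_real_, length(gtr))
      al <- strsplit(gtr[!miss], "[/|]")
      dose[!miss] <- vapply(al, function(a) sum(a == "1"), numeric(1))
    }
    if (anyNA(dose)) {
      if (missing_policy == "error")
        stop("missing genotype at marker '", ids[r], "'")
      dose[is.na(dose)] <- mean(dose, na.rm = TRUE)
    }
    m[, jj] <- dose
  }
  validate_genotypes(m)
}

#' Align genotype and phenotype objects on shared samples
#'
#' Restricts both objects to the intersection of their sample ids, ordered
#' as in the phenotype table (making downstream fits deterministic), and
#' handles samples with missing trait or covariate values by listwise
#' deletion (`na_policy = "drop"`) or rejection (`"error"`).
#'
#' @param genotypes genotype matrix (samples x markers, row names = ids).
#' @param phenotypes phenotype data frame from [read_phenotypes_tsv()].
#' @param na_policy `"drop"` (default) or `"error"`.
#' @return list with `genotypes`, `phenotypes`, and `n_dropped`.
#' @export
align_samples <- function(genotypes, phenotypes, na_policy = c("drop", "error")) {
  na_policy <- match.arg(na_policy)
  shared <- phenotypes$sample_id[phenotypes$sample_id %in% rownames(genotypes)]
  if (length(shared) == 0) stop("no shared sample ids between genotypes and phenotypes")
  ph <- phenotypes[match(shared, phenotypes$sample_id), , drop = FALSE]
  complete <- stats::complete.cases(ph)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    if (na_policy == "error")
      stop(n_dropped, " sample(s) have missing trait/covariate values")
    message("dropped ", n_dropped, " sample(s) with missing values")
    ph <- ph[complete, , drop = FALSE]
    shared <- shared[complete]
  }
  gm <- genotypes[shared, , drop = FALSE]
  class(gm) <- c("genotype_matrix", "matrix", "array")
  rownames(ph) <- NULL
  list(genotypes = gm, phenotypes = ph, n_dropped = n_dropped)
}

#' Write per-marker vQTL test results as TSV
#'
#' One row per marker x method with a fixed column order, plus a
#' multiplicity-adjusted dispersion p-value column (`disp_p_adj`) computed
#' within each method across markers by the chosen procedure.
#'
#' @param results a list of `vqtl_test` objects, or the data frame returned
#'   by [vqtl_scan()].
#' @param path output path.
#' @param adjust `"none"`, `"bonferroni"`, or `"bh"`
#'   (Benjamini-Hochberg).
#' @return the results data frame (with `disp_p_adj`), invisibly.
#' @export
write_results_tsv <- function(results, path, adjust = c("none", "bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  if (inherits(results, "vqtl_test")) results <- list(results)
  df <- if (is.data.frame(results)) results
        else do.call(rbind, lapply(results, as.data.frame))
  if (nrow(df) == 0) stop("no results to write")
  meth <- if (adjust == "bh") "BH" else if (adjust == "bonferroni") "bonferroni" else "none"
  df$disp_p_adj <- ave(df$disp_p, df$method,
                       FUN = function(p) p.adjust(p, method = meth))
  cols <- c("marker_id", "method", "n_used", "mean_beta", "mean_se", "mean_p",
            "disp_beta", "disp_se", "disp_stat", "disp_df", "disp_p",
            "disp_p_adj", "converged", "warnings")
  df <- df[, cols]
  out <- df
  for (cc in cols) if (is.numeric(out[[cc]])) out[[cc]] <- ifelse(is.na(out[[cc]]), ".", format(out[[cc]], digits = 10, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(df)
}
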