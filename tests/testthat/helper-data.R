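# shared fixtures, built in code

# small random grouped dataset with all three genotype classes present
rand_grouped <- function(n = 30, seed = 1) {
  set.seed(seed)
  g <- sample(0:2, n, replace = TRUE, prob = c(.36, .48, .16))
  g[1:6] <- rep(0:2, 2)  # guarantee >= 2 per class
  y <- rnorm(n, 0.1 * g, exp(0.1 * g))
  list(y = y, g = g)
}

# genotype matrix + phenotype table pair with matching ids
toy_pair <- function(n = 20, m = 3, seed = 42) {
  set.seed(seed)
  ids <- paste0("s", seq_len(n))
  geno <- matrix(round(runif(n * m, 0, 2), 3), n, m,
                 dimnames = list(ids, paste0("mk", seq_len(m))))
  pheno <- data.frame(sample_id = ids, trait = rnorm(n), age = runif(n, 20, 60))
  list(geno = validate_genotypes(geno), pheno = pheno)
}

# minimal VCF body as text lines
toy_vcf_lines <- function(gt = c("0/0", "0/1", "1/1", "0/1", "1/1"),
                          ds = NULL, id = "rs1") {
  fmt <- if (is.null(ds)) "GT" else "GT:DS"
  cells <- if (is.null(ds)) gt else paste(gt, ds, sep = ":")
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(ds))
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("s", seq_along(gt))), collapse = "\t"),
    paste(c("1", "100", id, "A", "G", ".", "PASS", ".", fmt, cells),
          collapse = "\t"))
}

write_vcf <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}
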