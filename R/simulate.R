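#' Simulate benchmark scenarios for vQTL test evaluation
#'
#' Generates single-marker datasets under the three generative laws used to
#' calibrate and compare the tests:
#' \describe{
#'   \item{`interaction_vqtl`}{a latent-interaction vQTL:
#'     \eqn{g_i \sim Bin(2, 0.4)}, \eqn{F_i \sim N(0,1)} an unobserved
#'     interacting factor, and
#'     \eqn{y_i \sim N(\beta_F F_i + \beta_{gF}\, g_i F_i,\; 1)}.
#'     Marginally over \eqn{F} the trait variance is
#'     \eqn{1 + (\beta_F + \beta_{gF} g)^2}, i.e. genotype-dependent -- a
#'     true vQTL with no direct mean effect.}
#'   \item{`gaussian_null`}{\eqn{y_i \sim N(0, 1)} independent of
#'     \eqn{g_i \sim Bin(2, 0.4)}: no mean and no variance effect.}
#'   \item{`poisson_null`}{\eqn{y_i \sim Poisson(e^{\mu + \beta_g g_i})}
#'     with \eqn{\mu = -1}, \eqn{\beta_g = 0.05}: a genotype mean effect
#'     whose variance tracks the mean only through the Poisson law -- no
#'     vQTL, but a trap for tests that assume constant mean-variance
#'     relation.}
#' }
#' The latent factor `F` is returned for truth-checking only; the tests are
#' meant to see `(y, g)` alone.
#'
#' @param scenario one of `"interaction_vqtl"`, `"gaussian_null"`,
#'   `"poisson_null"`.
#' @param n number of samples.
#' @param maf allele frequency `q` of the dosage-increasing allele;
#'   `g ~ Bin(2, q)`.
#' @param beta_F main effect of the latent factor (interaction scenario).
#' @param beta_gF genotype-by-factor interaction effect; `0` turns the
#'   interaction scenario into a null.
#' @param mu,beta_g log-scale intercept and genotype mean effect of the
#'   Poisson scenario.
#' @param seed optional RNG seed for reproducibility.
#' @return object of class `"vqtl_sim"`: list with `y`, `g`, `F` (or `NULL`),
#'   `truth` (`has_vqtl`, `has_mean_effect`), `scenario`, `n` and the
#'   parameters used.
#' @examples
#' sim <- simulate_scenario("interaction_vqtl", n = 500, seed = 1)
#' group_summary(sim$y, dosage_to_groups(sim$g))
#' @export
simulate_scenario <- function(scenario = c("interaction_vqtl", "gaussian_null",
                                           "poisson_null"),
                              n = 10000, maf = 0.4,
                              beta_F = 0.85, beta_gF = 0.06,
                              mu = -1, beta_g = 0.05, seed = NULL) {
  scenario <- match.arg(scenario)
  if (n < 10) stop("n must be at least 10")
  if (maf <= 0 || maf >= 1) stop("maf must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  g <- rbinom(n, 2, maf)
  Fv <- NULL
  truth <- list(has_vqtl = FALSE, has_mean_effect = FALSE)
  if (scenario == "interaction_vqtl") {
    Fv <- rnorm(n)
    y <- rnorm(n, beta_F * Fv + beta_gF * g * Fv, 1)
    truth$has_vqtl <- beta_gF != 0
  } else if (scenario == "gaussian_null") {
    y <- rnorm(n)
  } else {
    y <- rpois(n, exp(mu + beta_g * g))
    truth$has_mean_effect <- beta_g != 0
  }
  structure(list(y = y, g = g, F = Fv, truth = truth, scenario = scenario,
                 n = n, params = list(maf = maf, beta_F = beta_F,
                                      beta_gF = beta_gF, mu = mu,
                                      beta_g = beta_g), seed = seed),
            class = "vqtl_sim")
}

#' @export
print.vqtl_sim <- function(x, ...) {
  cat("Simulated vQTL dataset:", x$scenario, " n =", x$n, "\n")
  cat("  genotype counts:", paste(table(factor(x$g, 0:2)), collapse = "/"), "\n")
  cat("  truth: has_vqtl =", x$truth$has_vqtl,
      ", has_mean_effect =", x$truth$has_mean_effect, "\n")
  invisible(x)
}

#' Write a simulated dataset as a genotype/phenotype TSV pair
#'
#' Emits the simulated marker as a one-column genotype matrix and the trait
#' as a phenotype table, in the formats read by [read_genotypes_tsv()] and
#' [read_phenotypes_tsv()], so scans can be exercised end to end on
#' synthetic data. The latent factor is deliberately not written.
#'
#' @param sim a `vqtl_sim` object.
#' @param geno_path,pheno_path output file paths.
#' @param marker_id name for the simulated marker column.
#' @return invisibly, the two paths.
#' @export
write_sim_tsv <- function(sim, geno_path, pheno_path, marker_id = "m1") {
  ids <- paste0("s", seq_len(sim$n))
  geno <- matrix(sim$g, ncol = 1, dimnames = list(ids, marker_id))
  write_genotypes_tsv(geno, geno_path)
  ph <- data.frame(sample_id = ids, trait = sim$y)
  write.table(ph, pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(geno_path, pheno_path))
}
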