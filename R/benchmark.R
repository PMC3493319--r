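## fast per-trial dispersion p-values for the Monte-Carlo studies;
## thin re-expressions of the user-facing tests without result packaging
.study_pvalue <- function(y, g, method, levene_center = "median") {
  switch(method,
    levene = levene_test(y, dosage_to_groups(g), center = levene_center)$disp_p,
    fligner = fligner_killeen_test(y, dosage_to_groups(g))$disp_p,
    svlm = svlm_test(y, g)$disp_p,
    svlm_gamma = svlm_test(y, g, stage2 = "gamma_sq")$disp_p,
    absres = svlm_test(y, g, stage2 = "normal_abs")$disp_p,
    dglm_gaussian = dglm_vqtl_test(y, g, family = "gaussian")$disp_p,
    dglm_poisson = dglm_vqtl_test(y, g, family = "poisson")$disp_p,
    stop("unknown method: ", method)
  )
}

.study_methods <- c("levene", "fligner", "svlm", "svlm_gamma", "absres",
                    "dglm_gaussian", "dglm_poisson")

#' Monte-Carlo study of rejection rates for vQTL tests
#'
#' Runs `trials` independent replicates of a simulation scenario and applies
#' every requested method to the same dataset within each trial (a paired
#' design, so method comparisons are not confounded by simulation noise).
#' Reports per-method rejection rates at level `alpha` with Monte-Carlo
#' standard errors \eqn{\sqrt{r(1-r)/trials}}, and stores the full p-value
#' matrix so rates at other levels, or p-value concordances, can be
#' computed exactly afterwards. Under a null scenario the rejection rate
#' estimates the false-positive rate; under the interaction scenario it
#' estimates power.
#'
#' Per-trial seeds are derived as `seed + trial - 1`, making studies
#' reproducible and resumable.
#'
#' @param scenario passed to [simulate_scenario()].
#' @param methods subset of `"levene"`, `"fligner"`, `"svlm"`,
#'   `"svlm_gamma"`, `"absres"`, `"dglm_gaussian"`, `"dglm_poisson"`.
#' @param trials number of Monte-Carlo replicates.
#' @param n samples per replicate.
#' @param alpha significance level.
#' @param seed master seed; trial `i` uses `seed + i - 1`.
#' @param levene_center centring for the Levene rows (`"median"` default).
#' @param ... further scenario parameters for [simulate_scenario()].
#' @return object of class `"vqtl_study"`: `summary` data frame (method,
#'   scenario, trials, alpha, rejection_rate, mc_se, n_warn), `pvalues`
#'   matrix (trials x methods), and the configuration.
#' @examples
#' st <- run_study("gaussian_null", c("levene", "svlm"), trials = 20,
#'                 n = 300, seed = 1)
#' st$summary
#' @export
run_study <- function(scenario, methods = c("levene", "svlm", "dglm_gaussian"),
                      trials = 1000, n = 10000, alpha = 0.05, seed = 1,
                      levene_center = "median", ...) {
  methods <- match.arg(methods, .study_methods, several.ok = TRUE)
  if (trials < 1) stop("trials must be >= 1")
  if ("dglm_poisson" %in% methods && scenario != "poisson_null")
    stop("dglm_poisson requires integer traits; use the poisson_null scenario")
  pv <- matrix(NA_real_, trials, length(methods),
               dimnames = list(NULL, methods))
  n_warn <- setNames(integer(length(methods)), methods)
  for (i in seq_len(trials)) {
    sim <- simulate_scenario(scenario, n = n, seed = seed + i - 1, ...)
    for (m in methods) {
      pv[i, m] <- withCallingHandlers(
        .study_pvalue(sim$y, sim$g, m, levene_center),
        warning = function(w) { n_warn[m] <<- n_warn[m] + 1L
                                invokeRestart("muffleWarning") })
    }
  }
  rates <- colMeans(pv < alpha)
  smry <- data.frame(
    method = methods, scenario = scenario, trials = trials, n = n,
    alpha = alpha, rejection_rate = unname(rates),
    mc_se = unname(sqrt(rates * (1 - rates) / trials)),
    n_warn = unname(n_warn[methods]),
    stringsAsFactors = FALSE
  )
  if (any(smry$n_warn > 0.02 * trials))
    warning("more than 2% of trials raised fit warnings for: ",
            paste(smry$method[smry$n_warn > 0.02 * trials], collapse = ", "))
  structure(list(summary = smry, pvalues = pv, scenario = scenario,
                 alpha = alpha, seed = seed),
            class = "vqtl_study")
}

#' @export
print.vqtl_study <- function(x, ...) {
  cat("vQTL Monte-Carlo study:", x$scenario, "\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rejection rates of a finished study at other significance levels
#'
#' Evaluated exactly on the stored p-value matrix, so rates are
#' non-decreasing in `alpha` by construction.
#'
#' @param study a `vqtl_study` object.
#' @param alpha significance level(s).
#' @return matrix of rejection rates, levels x methods.
#' @export
rejection_rates <- function(study, alpha = c(0.01, 0.05, 0.10)) {
  out <- sapply(colnames(study$pvalues), function(m)
    sapply(alpha, function(a) mean(study$pvalues[, m] < a)))
  matrix(out, nrow = length(alpha),
         dimnames = list(paste0("alpha=", alpha), colnames(study$pvalues)))
}

#' Power study under the latent-interaction vQTL scenario
#'
#' [run_study()] on the `interaction_vqtl` alternative, additionally
#' reporting the Pearson concordance of raw p-values between the two-stage
#' SVLM and the parametric Gaussian DGLM when both are present -- the
#' quantitative sense in which the cheap approximation matches the full fit
#' on large, well-balanced samples.
#'
#' @inheritParams run_study
#' @return a `vqtl_study` with an extra `concordance` element (or `NA`).
#' @export
run_power_study <- function(methods = c("levene", "svlm", "dglm_gaussian"),
                            trials = 1000, n = 10000, alpha = 0.05, seed = 1,
                            ...) {
  st <- run_study("interaction_vqtl", methods = methods, trials = trials,
                  n = n, alpha = alpha, seed = seed, ...)
  st$concordance <-
    if (all(c("svlm", "dglm_gaussian") %in% methods))
      pvalue_concordance(st$pvalues[, "svlm"], st$pvalues[, "dglm_gaussian"])
    else NA_real_
  st
}
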