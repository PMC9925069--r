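# Shared builders for small instrument sets and panels.

# A harmonised instrument set with configurable ratios; defaults give a
# strongly-instrumented homogeneous set.
make_harmonised <- function(n = 5, gamma = NULL, s_gamma = NULL,
                            Gamma = NULL, s_Gamma = NULL, seed = 1) {
  withr::with_seed(seed, {
    gamma <- gamma %||% (runif(n, 0.03, 0.12) * sample(c(-1, 1), n, TRUE))
    s_gamma <- s_gamma %||% rep(0.005, n)
    Gamma <- Gamma %||% (-0.2 * gamma + rnorm(n, 0, 0.001))
    s_Gamma <- s_Gamma %||% runif(n, 0.02, 0.05)
    tibble::tibble(
      variant_id = paste0("rs", seq_len(n)), chrom = "1",
      pos = 1000L * seq_len(n),
      effect_allele = "A", other_allele = "G", eaf = runif(n, 0.1, 0.4),
      gamma = gamma, s_gamma = s_gamma, pvalue_exposure = NA_real_,
      Gamma = Gamma, s_Gamma = s_Gamma,
      palindromic = FALSE, inferred_by_freq = FALSE
    )
  })
}

# One simulate -> harmonise pass under a scenario (per-exposure-increase
# orientation, as the estimators' recovery tests need).
sim_harmonised <- function(seed, ...) {
  sim <- simulate_two_sample(sim_scenario(seed = seed, ...))
  harmonise(sim$exposure, sim$outcome)
}

cis_fixture_path <- function() {
  system.file("extdata", "cisil6r_exposure_synthetic.tsv", package = "cismr")
}

il6r_region <- function() gene_region("IL6R", "1", 154377669, 154441926)

`%||%` <- rlang::`%||%`
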