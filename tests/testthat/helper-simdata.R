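# shared small fixtures, built once per test run
.fixture_env <- new.env()

small_cohort <- function() {
  if (is.null(.fixture_env$coh)) {
    panel <- simulate_ancestral_panel(n_pops = 2, n_variants = 300, n_genes = 5,
                                      block_size = 20, rho_per_pop = c(0.5, 0.5),
                                      F = 0.15, seed = 101)
    theta <- simulate_theta(200, mean = 0.8, seed = 101)
    .fixture_env$coh <- simulate_admixed_genotypes(panel, 200, theta, seed = 101)
  }
  .fixture_env$coh
}

small_expression <- function() {
  if (is.null(.fixture_env$expr)) {
    coh <- small_cohort()
    sc <- scenario_config(c("shared", "null", "tier1", "tier3", "shared"),
                          h2 = 0.2)
    .fixture_env$expr <- simulate_expression(coh, sc, seed = 102)
  }
  .fixture_env$expr
}
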