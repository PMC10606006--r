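# Shared small cohorts, built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

# modest cohort with causal genes, reused by several test files
get_small_cohort <- function() {
  if (is.null(.cohort_cache$small)) {
    cfg <- sim_config(n_individuals = 4000, n_genes = 15,
                      variants_per_gene = c(8, 16),
                      causal_gene_fraction = 0.2, seed = 42)
    .cohort_cache$small <- simulate_cohort(cfg)
  }
  .cohort_cache$small
}

covar_matrix_of <- function(cohort) {
  ph <- as.data.frame(cohort$phenotypes)
  as.matrix(ph[, c("sex", "age", "batch", paste0("PC", 1:10))])
}

# correlated rare genotype block via a Gaussian AR(1) copula (oracle-side
# generator, independent of the package's simulator)
ar1_genotypes <- function(n, maf, rho, seed = 1) {
  set.seed(seed)
  m <- length(maf)
  hap <- function() {
    Z <- matrix(stats::rnorm(n * m), n, m)
    for (j in 2:m) Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
    sweep(Z, 2, stats::qnorm(maf), `<`) + 0
  }
  G <- hap() + hap()
  colnames(G) <- paste0("v", seq_len(m))
  G
}
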