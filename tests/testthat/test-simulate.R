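# Synthetic cohort generator: panel structure, Hardy-Weinberg dosages,
# and the liability-threshold trait architecture.

test_that("variant panel respects counts, MAF bounds, and gene structure", {
  cfg <- sim_config(n_individuals = 1000, n_genes = 50,
                    variants_per_gene = 30, seed = 7,
                    intergenic_fraction = 0)
  panel <- simulate_variant_panel(cfg)
  expect_equal(nrow(panel), 1500L)
  expect_equal(length(unique(panel$gene)), 50L)
  expect_true(all(panel$maf <= 0.01))
  expect_true(all(panel$maf > 0))
  expect_false(is.unsorted(panel$pos, strictly = TRUE))
  regions <- attr(panel, "gene_regions")
  expect_true(all(regions$start <= regions$end))
  # genes are non-overlapping intervals
  expect_true(all(regions$start[-1] > regions$end[-nrow(regions)]))
})

test_that("degenerate consequence distribution labels every variant LoF", {
  probs <- c(stop_gained = 1)
  cfg <- sim_config(n_individuals = 500, n_genes = 5,
                    variants_per_gene = 10, consequence_probs = probs,
                    intergenic_fraction = 0, seed = 1)
  panel <- simulate_variant_panel(cfg)
  expect_true(all(panel$consequence %in% mask_vocabularies$LoF))
})

test_that("genotypes are HWE draws, deterministic under the seed", {
  cfg <- sim_config(n_individuals = 50000, n_genes = 1,
                    variants_per_gene = 5, seed = 3)
  panel <- simulate_variant_panel(cfg)
  panel$maf <- rep(0.005, nrow(panel))
  G1 <- simulate_genotypes(panel, cfg)
  G2 <- simulate_genotypes(panel, cfg)
  expect_identical(G1, G2)
  expect_true(all(G1 %in% 0:2))
  # realized allele frequency within 3 binomial SE of the truth
  se <- sqrt(0.005 * 0.995 / (2 * 50000))
  expect_true(all(abs(colMeans(G1) / 2 - 0.005) < 3 * se))
})

test_that("zero-MAF variant gives an all-zero dosage column", {
  cfg <- sim_config(n_individuals = 200, n_genes = 1,
                    variants_per_gene = 3, seed = 2)
  panel <- simulate_variant_panel(cfg)
  panel$maf[2] <- 0
  G <- simulate_genotypes(panel, cfg)
  expect_true(all(G[, 2] == 0))
})

test_that("realized prevalences hit their targets", {
  co <- get_small_cohort()
  prev <- colMeans(as.matrix(as.data.frame(co$phenotypes)[, co$truth$cfg$traits]))
  target <- co$truth$cfg$prevalences
  # empirical-quantile thresholding puts realized prevalence within 1/n,
  # far inside the 3-SE binomial envelope
  se <- sqrt(target * (1 - target) / nrow(co$geno))
  expect_true(all(abs(prev - target) < pmax(3 * se, 1 / nrow(co$geno) + 1e-9)))
})

test_that("single shared factor drives pairwise genetic correlations to lambda_i lambda_j", {
  cfg <- sim_config(n_individuals = 3000, n_genes = 40,
                    variants_per_gene = c(10, 20),
                    causal_gene_fraction = 0.5,
                    factor_loadings = c(1, 1, 1),
                    specific_effect_frac = 1, seed = 9)
  co <- simulate_cohort(cfg)
  gc <- co$truth$realized_genetic_corr
  # lambda = 1 means the specific components get zero weight
  expect_true(all(gc[upper.tri(gc)] > 0.999))
})

test_that("no heritability means null association z-scores at causal variants", {
  cfg <- sim_config(n_individuals = 4000, n_genes = 25,
                    variants_per_gene = 12, h2 = c(0, 0, 0),
                    causal_gene_fraction = 1, seed = 13,
                    intergenic_fraction = 0)
  co <- simulate_cohort(cfg)
  covars <- covar_matrix_of(co)
  ss <- ewas(co$geno, co$phenotypes$CBP, covars, qc = qc_config(maf_min = 5e-4))
  z <- ss$z[is.finite(ss$z)]
  expect_gt(length(z), 100)
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(sd(z) - 1), 0.1)
})

test_that("impossible phenotypic-correlation targets fail loudly", {
  # a target correlation of 0.999 cannot be reached when the genetic
  # side contributes only ~0.1 and environments are bounded by 1
  expect_error(
    env_corr_for_target(matrix(c(1, .999, .999, 1), 2),
                        h2 = c(0.5, 0.5), lambda = c(0.3, 0.3)),
    "not attainable")
})

test_that("pure null cohort carries no causal structure", {
  cfg <- sim_config(n_individuals = 500, n_genes = 5,
                    causal_gene_fraction = 0, seed = 21)
  co <- simulate_cohort(cfg)
  expect_length(co$truth$causal_genes, 0)
  expect_true(all(co$truth$realized_h2 == 0))
})
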