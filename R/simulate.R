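# Synthetic cohort generator.  Three (by default) binary traits arise
# from a liability-threshold model with a single shared genetic factor:
#   liability_k = sqrt(h2_k) * (lambda_k g_shared + sqrt(1-lambda_k^2) g_spec_k)
#                 + env_k,
# where the genetic components are standardized scores over causal rare
# variants and env_k carries the covariate effects plus correlated
# residual noise.  Cases are individuals above the empirical
# (1 - prevalence) liability quantile, so realized prevalences hit their
# targets to within 1/n by construction.

.default_consequence_probs <- function() {
  p <- c(
    frameshift_variant = 0.015, splice_acceptor_variant = 0.005,
    splice_donor_variant = 0.005, start_lost = 0.002, stop_gained = 0.012,
    stop_lost = 0.002, transcript_ablation = 0.001,
    transcript_amplification = 0.001, inframe_insertion = 0.008,
    inframe_deletion = 0.010, missense_variant = 0.300,
    protein_altering_variant = 0.004,
    synonymous_variant = 0.180, start_retained_variant = 0.001,
    stop_retained_variant = 0.001, coding_sequence_variant = 0.005,
    incomplete_terminal_codon_variant = 0.001,
    intron_variant = 0.330, `5_prime_UTR_variant` = 0.053,
    `3_prime_UTR_variant` = 0.065
  )
  p / sum(p)
}

#' Simulation configuration
#'
#' Defines the synthetic cohort: panel size, rare-variant MAF spectrum,
#' consequence label probabilities, and the shared-factor liability
#' architecture of the binary traits.  Defaults emulate the study
#' conditions: three traits with prevalences 17.97% / 3.48% / 1.76%,
#' liability-scale SNP heritabilities 0.12 / 0.114 / 0.08, and pairwise
#' genetic correlations of 0.9 (a single shared factor with loadings
#' `sqrt(0.9)`).
#'
#' @param n_individuals Cohort size.
#' @param n_genes Number of genes in the panel.
#' @param variants_per_gene Single count or `c(min, max)` range.
#' @param maf_range MAF spectrum bounds; true MAFs are drawn log-uniform
#'   on `(maf_range[1], maf_range[2]]`.  The lower bound defaults to
#'   `1/(2 n_individuals)` and the upper bound must be `<= 0.01` (rare
#'   variants only).
#' @param consequence_probs Named probability vector over the VEP-style
#'   consequence vocabulary (must sum to 1).
#' @param intergenic_fraction Fraction of additional variants placed
#'   between genes (consequence `"intergenic"`, no gene membership).
#' @param traits Trait names (length K).
#' @param prevalences Target prevalences in (0, 1).
#' @param h2 Liability-scale SNP heritabilities in `[0, 1)`.
#' @param factor_loadings True shared-factor loadings in `[0, 1]`;
#'   pairwise genetic correlations are `lambda_i * lambda_j`.
#' @param env_corr K x K correlation matrix of the residual
#'   environmental components, or `NULL` to solve it from
#'   `pheno_corr_liability` via [env_corr_for_target()].
#' @param pheno_corr_liability Target liability-scale phenotypic
#'   correlation matrix (used only when `env_corr` is `NULL`).
#' @param causal_gene_fraction Fraction of genes harbouring causal
#'   variants; 0 yields a pure null cohort.
#' @param effect_base Scale of per-variant liability effects; effect
#'   magnitudes are `effect_base * |log10 MAF|` (rarer variants hit
#'   harder, the usual rare-variant convention).
#' @param lof_sign_prob Probability that a LoF causal variant's effect is
#'   deleterious (positive liability sign); non-LoF signs are random.
#' @param specific_effect_frac Relative magnitude of trait-specific
#'   causal effects (same variants, independent draws) feeding the
#'   specific genetic components.
#' @param covar_effects Named vector of liability effects of the
#'   standardized `age` and `sex` covariates (identical across traits).
#' @param missing_rate Probability a dosage is missing.
#' @param ld_rho First-order autoregressive haplotype correlation along
#'   the variant sequence (0 = independent sites).
#' @param seed Integer seed used by the `simulate_*` functions.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20000L,
                       n_genes = 60L,
                       variants_per_gene = c(10L, 40L),
                       maf_range = c(NA, 0.01),
                       consequence_probs = .default_consequence_probs(),
                       intergenic_fraction = 0.05,
                       traits = c("CBP", "dorsalgia", "IDD"),
                       prevalences = c(0.1797, 0.0348, 0.0176),
                       h2 = c(0.12, 0.114, 0.08),
                       factor_loadings = rep(sqrt(0.9), 3),
                       env_corr = NULL,
                       pheno_corr_liability = NULL,
                       causal_gene_fraction = 0.1,
                       effect_base = 0.15,
                       lof_sign_prob = 0.95,
                       specific_effect_frac = 1,
                       covar_effects = c(age = 0.08, sex = 0.04),
                       missing_rate = 0,
                       ld_rho = 0,
                       seed = 1L) {
  K <- length(traits)
  stopifnot(n_individuals >= 2, n_genes >= 1,
            length(variants_per_gene) %in% c(1L, 2L),
            all(variants_per_gene >= 1),
            length(prevalences) == K, all(prevalences > 0 & prevalences < 1),
            length(h2) == K, all(h2 >= 0 & h2 < 1),
            length(factor_loadings) == K,
            all(factor_loadings >= 0 & factor_loadings <= 1),
            causal_gene_fraction >= 0, causal_gene_fraction <= 1,
            missing_rate >= 0, missing_rate < 1,
            ld_rho >= 0, ld_rho < 1)
  if (is.na(maf_range[1])) maf_range[1] <- 1 / (2 * n_individuals)
  if (maf_range[1] <= 0 || maf_range[2] > 0.01 || maf_range[1] >= maf_range[2]) {
    stop("sim_config: maf_range must satisfy 0 < min < max <= 0.01")
  }
  if (abs(sum(consequence_probs) - 1) > 1e-8) {
    stop("sim_config: consequence_probs must sum to 1")
  }
  if (is.null(pheno_corr_liability)) {
    pheno_corr_liability <- matrix(c(1, 0.55, 0.45,
                                     0.55, 1, 0.55,
                                     0.45, 0.55, 1), 3, 3)[seq_len(K), seq_len(K)]
    diag(pheno_corr_liability) <- 1
  }
  if (is.null(env_corr)) {
    env_corr <- env_corr_for_target(pheno_corr_liability, h2, factor_loadings)
  }
  stopifnot(is.matrix(env_corr), nrow(env_corr) == K, ncol(env_corr) == K)
  if (min(eigen(env_corr, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("sim_config: env_corr is not positive definite")
  }
  structure(list(
    n_individuals = as.integer(n_individuals), n_genes = as.integer(n_genes),
    variants_per_gene = as.integer(variants_per_gene),
    maf_range = maf_range, consequence_probs = consequence_probs,
    intergenic_fraction = intergenic_fraction,
    traits = traits, prevalences = prevalences, h2 = h2,
    factor_loadings = factor_loadings, env_corr = env_corr,
    causal_gene_fraction = causal_gene_fraction,
    effect_base = effect_base, lof_sign_prob = lof_sign_prob,
    specific_effect_frac = specific_effect_frac,
    covar_effects = covar_effects, missing_rate = missing_rate,
    ld_rho = ld_rho, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Residual environmental correlation matching a target liability correlation
#'
#' Under the shared-factor model the liability correlation decomposes as
#' `P_ij = lambda_i lambda_j sqrt(h2_i h2_j) + env_ij sqrt((1-h2_i)(1-h2_j))`;
#' this solves for the environmental correlation and fails loudly if the
#' result is not a valid positive-definite correlation matrix.
#'
#' @param P_target Target liability-scale phenotypic correlation matrix.
#' @param h2 Heritabilities.
#' @param lambda Shared-factor loadings.
#' @return The K x K environmental correlation matrix.
#' @export
env_corr_for_target <- function(P_target, h2, lambda) {
  K <- length(h2)
  stopifnot(is.matrix(P_target), nrow(P_target) == K, ncol(P_target) == K,
            length(lambda) == K)
  gcov <- outer(lambda * sqrt(h2), lambda * sqrt(h2))
  diag(gcov) <- h2
  esd <- sqrt(1 - h2)
  E <- (P_target - gcov) / outer(esd, esd)
  diag(E) <- 1
  if (any(abs(E[upper.tri(E)]) >= 1)) {
    stop("env_corr_for_target: target phenotypic correlation is not attainable ",
         "given h2 and the factor loadings")
  }
  if (min(eigen(E, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("env_corr_for_target: implied environmental correlation is not ",
         "positive definite")
  }
  E
}

#' Simulate the rare-variant panel
#'
#' Draws gene regions as non-overlapping intervals on chromosome 1,
#' per-gene variant counts, log-uniform MAFs within the configured rare
#' spectrum, and consequence labels from `consequence_probs`; a fraction
#' of intergenic variants is interleaved between genes.
#'
#' @param cfg A [sim_config()].
#' @return A `data.table` ("variant table") with columns `id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene` (`NA` for intergenic), `consequence`,
#'   `maf`, plus a `gene_regions` attribute (`data.table` of `gene`,
#'   `chrom`, `start`, `end`, 1-based inclusive).
#' @export
simulate_variant_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  vpg <- cfg$variants_per_gene
  nv <- if (length(vpg) == 1L) rep(vpg, cfg$n_genes) else
    sample(vpg[1]:vpg[2], cfg$n_genes, replace = TRUE)
  gene_ids <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  gene_span <- 200000L                       # gene start spacing, bp
  starts <- 1L + (seq_len(cfg$n_genes) - 1L) * gene_span
  ends <- starts + pmax(nv * 60L, 2000L)
  rows <- vector("list", cfg$n_genes)
  bases <- c("A", "C", "G", "T")
  for (g in seq_len(cfg$n_genes)) {
    pos <- sort(sample(starts[g]:ends[g], nv[g]))
    rows[[g]] <- data.table(
      chrom = "1", pos = pos, gene = gene_ids[g],
      consequence = sample(names(cfg$consequence_probs), nv[g],
                           replace = TRUE, prob = cfg$consequence_probs)
    )
  }
  panel <- rbindlist(rows)
  n_inter <- round(cfg$intergenic_fraction * nrow(panel))
  if (n_inter > 0) {
    gaps <- data.table(
      chrom = "1",
      pos = sample(setdiff(seq(1L, max(ends) + gene_span), panel$pos), n_inter),
      gene = NA_character_, consequence = "intergenic"
    )
    panel <- rbind(panel, gaps)
  }
  setorder(panel, chrom, pos)
  # positions unique by construction of the intergenic draw; enforce anyway
  panel <- panel[!duplicated(pos)]
  lo <- log(cfg$maf_range[1]); hi <- log(cfg$maf_range[2])
  panel[, maf := exp(runif(.N, lo, hi))]
  panel[, ref := sample(bases, .N, replace = TRUE)]
  panel[, alt := vapply(ref, function(r) sample(setdiff(bases, r), 1), "")]
  panel[, id := sprintf("1:%d:%s:%s", pos, ref, alt)]
  setcolorder(panel, c("id", "chrom", "pos", "ref", "alt", "gene",
                       "consequence", "maf"))
  regions <- data.table(gene = gene_ids, chrom = "1",
                        start = starts, end = ends)
  setattr(panel, "gene_regions", regions)
  panel[]
}

#' Simulate additive dosages for a variant panel
#'
#' Hardy-Weinberg dosages at each variant's true MAF.  With `ld_rho > 0`
#' the two haplotypes follow a first-order autoregressive Gaussian
#' copula along the position-ordered variant sequence, giving decaying
#' linkage disequilibrium between neighbouring variants (including
#' across gene boundaries, which the conditional-analysis tests rely
#' on).
#'
#' @param panel Variant table from [simulate_variant_panel()].
#' @param cfg A [sim_config()]; uses `n_individuals`, `missing_rate`,
#'   `ld_rho`, and `seed + 1`.
#' @return Integer matrix (individuals x variants) with dimnames; minor
#'   (alt) allele dosage in `{0, 1, 2}`, `NA` for missing.
#' @export
simulate_genotypes <- function(panel, cfg) {
  stopifnot(nrow(panel) >= 1L)
  set.seed(cfg$seed + 1L)
  n <- cfg$n_individuals
  m <- nrow(panel)
  G <- matrix(0L, n, m, dimnames = list(sprintf("IND%06d", seq_len(n)),
                                        panel$id))
  if (cfg$ld_rho > 0) {
    rho <- cfg$ld_rho
    z1 <- rnorm(n); z2 <- rnorm(n)
    for (j in seq_len(m)) {
      if (j > 1L) {
        z1 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
        z2 <- rho * z2 + sqrt(1 - rho^2) * rnorm(n)
      }
      thr <- qnorm(panel$maf[j])
      G[, j] <- (z1 < thr) + (z2 < thr)
    }
  } else {
    for (j in seq_len(m)) G[, j] <- rbinom(n, 2L, panel$maf[j])
  }
  if (cfg$missing_rate > 0) {
    nmiss <- rbinom(1L, n * m, cfg$missing_rate)
    if (nmiss > 0) G[sample(length(G), nmiss)] <- NA_integer_
  }
  G
}

#' Simulate correlated binary traits from the liability-threshold model
#'
#' Builds standardized shared and trait-specific genetic scores from the
#' causal variants, mixes them with covariate effects and correlated
#' environmental noise per the configured architecture, and thresholds
#' each liability at its empirical `(1 - prevalence)` quantile.
#'
#' @param geno Dosage matrix from [simulate_genotypes()].
#' @param panel Variant table from [simulate_variant_panel()].
#' @param cfg A [sim_config()]; uses `seed + 2` for this stage.
#' @return A list with
#'   `phenotypes`: `data.table` of `id`, one 0/1 column per trait, and
#'     covariates `sex`, `age`, `batch`, `PC1`..`PC10`;
#'   `truth`: list with `causal_genes`, `causal_variants`,
#'     `shared_effects`, `specific_effects`, `realized_h2`,
#'     `realized_genetic_corr`, `realized_pheno_corr_liability`,
#'     `liability` matrix, and the generating `cfg`.
#' @export
simulate_liability_traits <- function(geno, panel, cfg) {
  stopifnot(nrow(geno) == cfg$n_individuals, ncol(geno) == nrow(panel))
  set.seed(cfg$seed + 2L)
  n <- nrow(geno)
  K <- length(cfg$traits)
  lambda <- cfg$factor_loadings
  h2 <- cfg$h2

  genes <- unique(panel$gene[!is.na(panel$gene)])
  n_causal <- round(cfg$causal_gene_fraction * length(genes))
  causal_genes <- if (n_causal > 0) sort(sample(genes, n_causal)) else character(0)
  coding <- mask_vocabularies$LoF_protein_coding
  cidx <- which(panel$gene %in% causal_genes & panel$consequence %in% coding)

  shared_eff <- numeric(length(cidx))
  spec_eff <- matrix(0, length(cidx), K)
  g_shared <- rep(0, n)
  g_spec <- matrix(0, n, K)
  if (length(cidx) > 0) {
    mafs <- panel$maf[cidx]
    mag <- cfg$effect_base * abs(log10(mafs))
    is_lof <- panel$consequence[cidx] %in% mask_vocabularies$LoF
    sgn <- ifelse(runif(length(cidx)) < 0.5, -1, 1)
    sgn[is_lof] <- ifelse(runif(sum(is_lof)) < cfg$lof_sign_prob, 1,
                          sgn[is_lof])
    shared_eff <- mag * sgn
    X <- geno[, cidx, drop = FALSE]
    X[is.na(X)] <- 0L
    Xs <- scale(X, center = 2 * mafs, scale = sqrt(2 * mafs * (1 - mafs)))
    raw <- as.numeric(Xs %*% shared_eff)
    g_shared <- raw / max(sd(raw), 1e-12)
    for (k in seq_len(K)) {
      spec_eff[, k] <- cfg$specific_effect_frac * mag *
        ifelse(runif(length(cidx)) < 0.5, -1, 1)
      rawk <- as.numeric(Xs %*% spec_eff[, k])
      g_spec[, k] <- rawk / max(sd(rawk), 1e-12)
    }
  }

  # covariates: effects are shared across traits, folded into the
  # non-genetic component so the total liability variance stays at 1
  sex <- rbinom(n, 1L, 0.5)
  age <- rnorm(n, 57, 8)
  batch <- rbinom(n, 1L, 0.5)
  pcs <- matrix(rnorm(n * 10L), n, 10L,
                dimnames = list(NULL, paste0("PC", 1:10)))
  cv <- cfg$covar_effects
  cov_lin <- cv[["age"]] * as.numeric(scale(age)) +
    cv[["sex"]] * (sex - 0.5) / 0.5
  cov_var <- cv[["age"]]^2 + cv[["sex"]]^2
  E <- cfg$env_corr
  resid_sd <- sqrt(pmax(1 - h2 - cov_var, 1e-6))
  # residual correlation chosen so the full non-genetic component
  # (covariates + residual) matches env_corr on the liability scale
  target_cov <- E * outer(sqrt(1 - h2), sqrt(1 - h2))
  resid_cov <- target_cov - cov_var
  diag(resid_cov) <- resid_sd^2
  ev <- eigen((resid_cov + t(resid_cov)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    stop("simulate_liability_traits: residual covariance not positive ",
         "definite; reduce covar_effects or env_corr")
  }
  L <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
  resid <- matrix(rnorm(n * K), n, K) %*% L

  has_gen <- length(cidx) > 0 & h2 > 0
  gen <- matrix(0, n, K)
  lia <- matrix(0, n, K, dimnames = list(rownames(geno), cfg$traits))
  for (k in seq_len(K)) {
    if (has_gen[k]) {
      gen[, k] <- sqrt(h2[k]) * (lambda[k] * g_shared +
                                   sqrt(1 - lambda[k]^2) * g_spec[, k])
    }
    lia[, k] <- gen[, k] + cov_lin + resid[, k]
  }
  status <- matrix(0L, n, K, dimnames = list(rownames(geno), cfg$traits))
  for (k in seq_len(K)) {
    thr <- quantile(lia[, k], 1 - cfg$prevalences[k], names = FALSE)
    status[, k] <- as.integer(lia[, k] > thr)
  }
  phen <- data.table(id = rownames(geno))
  for (k in seq_len(K)) set(phen, j = cfg$traits[k], value = status[, k])
  set(phen, j = "sex", value = sex)
  set(phen, j = "age", value = age)
  set(phen, j = "batch", value = batch)
  phen <- cbind(phen, as.data.table(pcs))

  gcor <- if (any(has_gen)) suppressWarnings(cor(gen)) else diag(K)
  truth <- list(
    causal_genes = causal_genes,
    causal_variants = panel$id[cidx],
    shared_effects = shared_eff,
    specific_effects = spec_eff,
    realized_h2 = vapply(seq_len(K), function(k)
      var(gen[, k]) / var(lia[, k]), numeric(1)),
    realized_genetic_corr = gcor,
    realized_pheno_corr_liability = cor(lia),
    liability = lia,
    cfg = cfg
  )
  list(phenotypes = phen, truth = truth)
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper chaining [simulate_variant_panel()],
#' [simulate_genotypes()], and [simulate_liability_traits()].
#'
#' @param cfg A [sim_config()].
#' @return A list with `panel`, `geno`, `phenotypes`, `truth`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  panel <- simulate_variant_panel(cfg)
  geno <- simulate_genotypes(panel, cfg)
  tr <- simulate_liability_traits(geno, panel, cfg)
  list(panel = panel, geno = geno, phenotypes = tr$phenotypes,
       truth = tr$truth)
}
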