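# Gene-based association tests from summary statistics: a weighted z
# vector per gene plus the genotype correlation (LD) matrix is all every
# test consumes.  Under the null z ~ N(0, R), so each statistic's null
# law follows from the kernel eigenvalues.

#' Consequence vocabularies of the four nested annotation masks
#'
#' VEP-style consequence terms defining the nested masks: `LoF`,
#' `LoF_missense`, `LoF_protein_coding`, and `all_intragenic` (which
#' accepts every within-gene term, UTRs and introns included).
#'
#' @format A named list of character vectors.
#' @export
mask_vocabularies <- local({
  lof <- c("frameshift_variant", "splice_acceptor_variant",
           "splice_donor_variant", "start_lost", "stop_gained",
           "stop_lost", "transcript_ablation")
  missense_extra <- c("transcript_amplification", "inframe_insertion",
                      "inframe_deletion", "missense_variant",
                      "protein_altering_variant")
  coding_extra <- c("synonymous_variant", "start_retained_variant",
                    "stop_retained_variant", "coding_sequence_variant",
                    "incomplete_terminal_codon_variant")
  noncoding <- c("intron_variant", "5_prime_UTR_variant",
                 "3_prime_UTR_variant")
  list(
    LoF = lof,
    LoF_missense = c(lof, missense_extra),
    LoF_protein_coding = c(lof, missense_extra, coding_extra),
    all_intragenic = c(lof, missense_extra, coding_extra, noncoding)
  )
})

#' Names of the four annotation masks, in nesting order
#' @export
mask_names <- function() names(mask_vocabularies)

#' Gene-test configuration
#'
#' @param weight_beta Shape parameters of the Beta density used to weight
#'   variants by MAF (default `c(1, 25)`, the rare-variant convention that
#'   up-weights the rarest variants).
#' @param rho_grid SKAT-O mixing grid over `[0, 1]`.
#' @param pca_var_threshold Cumulative variance-explained cutoff selecting
#'   the number of principal components of the weighted LD kernel.
#' @param maf_max,mac_min Frequency filters applied when building masks:
#'   variants must have MAF `<= maf_max`; variants with MAC
#'   `<= collapse_mac` are routed to the ultra-rare collapsing path and
#'   only variants with MAC `> collapse_mac` are tested individually.
#' @param collapse_mac MAC cutoff below (and at) which variants are
#'   collapsed into a single pseudo-variant.
#' @param ld_mac_min,ld_miss_max Filters applied to the genotype subset
#'   used for LD estimation (minor allele count and missingness).
#' @param eig_floor Eigenvalue floor used to regularize LD matrices.
#' @return An object of class `gene_test_config`.
#' @export
gene_test_config <- function(weight_beta = c(1, 25),
                             rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                             pca_var_threshold = 0.85,
                             maf_max = 0.01,
                             mac_min = 11L,
                             collapse_mac = 10L,
                             ld_mac_min = 3L,
                             ld_miss_max = 0.02,
                             eig_floor = 1e-8) {
  stopifnot(length(weight_beta) == 2L, all(weight_beta > 0),
            all(rho_grid >= 0), all(rho_grid <= 1),
            !is.unsorted(rho_grid),
            pca_var_threshold > 0, pca_var_threshold <= 1,
            maf_max > 0, maf_max < 0.5, collapse_mac >= 1)
  structure(list(weight_beta = weight_beta, rho_grid = rho_grid,
                 pca_var_threshold = pca_var_threshold, maf_max = maf_max,
                 mac_min = as.integer(mac_min),
                 collapse_mac = as.integer(collapse_mac),
                 ld_mac_min = as.integer(ld_mac_min),
                 ld_miss_max = ld_miss_max, eig_floor = eig_floor),
            class = "gene_test_config")
}

#' MAF-based variant weights
#'
#' Beta-density weights `w_j = dbeta(maf_j, a, b)`, defaulting to the
#' Beta(1, 25) convention for rare-variant masks.
#'
#' @param maf Minor allele frequencies.
#' @param shape Two Beta shape parameters.
#' @return Positive weights, one per variant.
#' @export
maf_weights <- function(maf, shape = c(1, 25)) {
  stopifnot(all(maf >= 0 & maf <= 1))
  stats::dbeta(pmin(pmax(maf, 1e-12), 1 - 1e-12), shape[1], shape[2])
}

#' Build an annotation mask for one gene
#'
#' Selects a gene's variants under one of the four nested consequence
#' vocabularies, applies the MAF filter, and splits the selection into
#' individually testable variants (MAC above the collapsing cutoff) and
#' ultra-rare variants routed to the collapsing path.
#'
#' @param panel A variant table (see [simulate_variant_panel()]) with
#'   columns `id`, `gene`, `consequence`.
#' @param gene_id Gene identifier.
#' @param mask_name One of [mask_names()].
#' @param sumstats Summary-statistic table with columns `id`, `freq`,
#'   `mac` (one trait; the selection only uses frequency columns).
#' @param cfg A [gene_test_config()].
#' @return A list of class `annotation_mask` with elements `gene`,
#'   `mask`, `test_ids`, `collapse_ids`, `weights` (for `test_ids`),
#'   `collapse_weight` (maximum member weight, used for the
#'   pseudo-variant), or `NULL` if no variant matches the vocabulary.
#' @export
build_mask <- function(panel, gene_id, mask_name, sumstats,
                       cfg = gene_test_config()) {
  stopifnot(mask_name %in% names(mask_vocabularies))
  vocab <- mask_vocabularies[[mask_name]]
  panel <- as.data.table(panel)
  sumstats <- as.data.table(sumstats)
  members <- panel[gene %in% gene_id & consequence %in% vocab, id]
  ss <- sumstats[id %in% members & freq <= cfg$maf_max]
  if (nrow(ss) == 0L) return(NULL)
  test <- ss[mac > cfg$collapse_mac]
  coll <- ss[mac <= cfg$collapse_mac]
  w_test <- if (nrow(test)) maf_weights(test$freq, cfg$weight_beta) else numeric(0)
  w_coll <- if (nrow(coll)) maf_weights(coll$freq, cfg$weight_beta) else numeric(0)
  structure(list(gene = gene_id, mask = mask_name,
                 test_ids = test$id, collapse_ids = coll$id,
                 weights = w_test,
                 collapse_weight = if (length(w_coll)) max(w_coll) else NA_real_),
            class = "annotation_mask")
}

#' Genotype correlation (LD) matrix
#'
#' Pearson correlations of dosage columns, pairwise-complete, after
#' excluding variants that fail the MAC and missingness filters, with an
#' eigenvalue floor to guarantee positive semi-definiteness.
#'
#' @param geno Dosage matrix (individuals x variants) with column names.
#' @param ids Variant ids to include (default: all columns).
#' @param mac_min Minimum minor allele count (default 3).
#' @param miss_max Maximum missingness fraction (default 0.02).
#' @param eig_floor Eigenvalue floor (default 1e-8); negative or tiny
#'   eigenvalues are raised to `eig_floor * max(eigenvalue)` and the
#'   matrix rescaled to unit diagonal.
#' @return A list of class `ld_matrix` with elements `ids` and `R`.
#' @export
compute_ld <- function(geno, ids = colnames(geno), mac_min = 3L,
                       miss_max = 0.02, eig_floor = 1e-8) {
  stopifnot(is.matrix(geno), !is.null(colnames(geno)))
  G <- geno[, ids, drop = FALSE]
  keep <- vapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]
    miss <- mean(is.na(x))
    mac <- .minor_allele_count(x)
    miss <= miss_max && mac >= mac_min
  }, logical(1))
  G <- G[, keep, drop = FALSE]
  if (ncol(G) < 2L) {
    stop("compute_ld: fewer than 2 variants pass the LD filters")
  }
  nobs <- crossprod(!is.na(G))
  if (any(nobs == 0)) {
    bad <- which(nobs == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("compute_ld: no shared non-missing observations for pair (%s, %s)",
                 colnames(G)[bad[1]], colnames(G)[bad[2]]))
  }
  R <- suppressWarnings(cor(G, use = "pairwise.complete.obs"))
  # zero-variance columns produce NA rows; those cannot be tested jointly
  if (anyNA(R)) stop("compute_ld: undefined correlation (zero-variance column?)")
  R <- .psd_regularize(R, eig_floor)
  structure(list(ids = colnames(G), R = R), class = "ld_matrix")
}

.psd_regularize <- function(R, eig_floor = 1e-8) {
  dn <- dimnames(R)
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE)
  floor_val <- eig_floor * max(ev$values)
  if (min(ev$values) < floor_val) {
    vals <- pmax(ev$values, floor_val)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    R <- cov2cor(R)
  }
  dimnames(R) <- dn
  R
}

.minor_allele_count <- function(x) {
  x <- x[!is.na(x)]
  ac <- sum(x)
  as.integer(min(ac, 2 * length(x) - ac))
}

.check_zwR <- function(z, w, R) {
  m <- length(z)
  if (is.null(w)) w <- rep(1, m)
  if (is.null(R)) R <- diag(m)
  if (inherits(R, "ld_matrix")) R <- R$R
  stopifnot(length(w) == m, all(w > 0), is.matrix(R),
            nrow(R) == m, ncol(R) == m, all(is.finite(z)))
  list(z = as.numeric(z), w = as.numeric(w), R = R)
}

#' Burden test from summary statistics
#'
#' Weighted sum-of-z burden statistic `z_b = w'z / sqrt(w'Rw)` with
#' two-sided normal p-value.
#'
#' @param z Per-variant z-scores (aligned to the same effect alleles).
#' @param w Positive per-variant weights (default equal).
#' @param R LD matrix of the variants (default identity).
#' @return List with `statistic` (z_b) and `p`.
#' @export
burden_test <- function(z, w = NULL, R = NULL) {
  a <- .check_zwR(z, w, R)
  denom <- as.numeric(crossprod(a$w, a$R %*% a$w))
  if (denom <= 0) stop("burden_test: w'Rw <= 0 after regularization")
  zb <- sum(a$w * a$z) / sqrt(denom)
  list(statistic = zb, p = max(2 * pnorm(-abs(zb)), 1e-300))
}

#' SKAT statistic from summary statistics
#'
#' Computes `Q_rho = (1 - rho) * sum((w z)^2) + rho * (sum(w z))^2` and
#' its p-value from the quadratic-form null, `z ~ N(0, R)`.  `rho = 0`
#' is classic SKAT; `rho = 1` is the squared burden statistic.
#'
#' @inheritParams burden_test
#' @param rho Mixing parameter in `[0, 1]`.
#' @return List with `statistic`, `p`, and the kernel eigenvalues
#'   `lambda`.
#' @export
skat <- function(z, w = NULL, R = NULL, rho = 0) {
  stopifnot(length(rho) == 1L, rho >= 0, rho <= 1)
  a <- .check_zwR(z, w, R)
  m <- length(a$z)
  zw <- a$w * a$z
  Q <- (1 - rho) * sum(zw^2) + rho * sum(zw)^2
  if (m == 1L) {
    return(list(statistic = Q, p = max(2 * pnorm(-abs(zw)), 1e-300),
                lambda = a$w^2 * 1))
  }
  Sigma <- a$R * tcrossprod(a$w)          # W R W
  lambda <- .skat_kernel_eigen(Sigma, rho)
  p <- quadform_pvalue(Q, lambda)
  list(statistic = Q, p = as.numeric(p), lambda = lambda)
}

# eigenvalues of A^{1/2} Sigma A^{1/2} with A = (1-rho) I + rho 11'
.skat_kernel_eigen <- function(Sigma, rho) {
  m <- nrow(Sigma)
  if (rho == 0) {
    lambda <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  } else {
    a1 <- sqrt(1 - rho)
    a2 <- (sqrt(1 - rho + m * rho) - a1) / m
    # A^{1/2} = a1 I + a2 J
    rs <- rowSums(Sigma)
    tot <- sum(rs)
    M <- a1^2 * Sigma + a1 * a2 * (outer(rs, rep(1, m)) + outer(rep(1, m), rs)) +
      a2^2 * tot
    lambda <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  }
  lambda[lambda > max(lambda) * 1e-10]
}

#' SKAT-O: optimal-rho combination over a mixing grid
#'
#' Minimum-p combination of [skat()] statistics over `rho_grid`, with
#' the one-dimensional-integration null distribution of the minimum
#' (Lee et al.).  Falls back to a Bonferroni correction over the grid if
#' the integration fails (with a warning).
#'
#' @inheritParams burden_test
#' @param rho_grid Grid of mixing parameters (default the canonical
#'   8-point grid `0, 0.1^2, ..., 0.5^2, 0.5, 1`).
#' @return List with `p`, `p_each` (per-rho p-values), `rho_min` (grid
#'   point attaining the minimum p), and `method`.
#' @export
skat_o <- function(z, w = NULL, R = NULL,
                   rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)) {
  a <- .check_zwR(z, w, R)
  m <- length(a$z)
  stopifnot(length(rho_grid) >= 1L, all(rho_grid >= 0), all(rho_grid <= 1))
  if (m == 1L) {
    p <- max(2 * pnorm(-abs(a$w * a$z) / a$w), 1e-300)
    return(list(p = p, p_each = rep(p, length(rho_grid)),
                rho_min = rho_grid[1], method = "single-variant"))
  }
  # near-singular burden direction: cap rho just below 1 (standard trick)
  grid <- pmin(rho_grid, 0.999)
  Sigma <- a$R * tcrossprod(a$w)
  zw <- a$w * a$z
  p_each <- numeric(length(grid))
  qmin <- numeric(length(grid))
  lambdas <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    rho <- grid[i]
    Q <- (1 - rho) * sum(zw^2) + rho * sum(zw)^2
    lambdas[[i]] <- .skat_kernel_eigen(Sigma, rho)
    p_each[i] <- as.numeric(quadform_pvalue(Q, lambdas[[i]]))
  }
  if (length(grid) == 1L) {
    return(list(p = p_each, p_each = p_each, rho_min = rho_grid[1],
                method = "single-rho"))
  }
  pmin_obs <- min(p_each)
  for (i in seq_along(grid)) qmin[i] <- .liu_quantile(pmin_obs, lambdas[[i]])

  # Lee decomposition: with s = Sigma 1, u = 1'z_w / sqrt(1'Sigma 1) ~ N(0,1),
  # Q_rho ~= tau(rho) u^2 + (1 - rho) eta, eta a quadratic form with
  # eigenvalues of Sigma - zbar zbar' plus a variance inflation for the
  # neglected cross term.
  s <- rowSums(Sigma)
  sum_s <- sum(s)
  zbar <- s / sqrt(sum_s)
  tau <- grid * sum_s + (1 - grid) * sum(s^2) / sum_s
  lam_bar <- eigen(Sigma - tcrossprod(zbar), symmetric = TRUE,
                   only.values = TRUE)$values
  lam_bar <- lam_bar[lam_bar > max(lam_bar) * 1e-10]
  MuQ <- sum(lam_bar)
  VarQ <- 2 * sum(lam_bar^2)
  var_zeta <- 4 * (as.numeric(crossprod(zbar, Sigma %*% zbar)) - sum(zbar^2)^2)
  sd_ratio <- sqrt(VarQ / (VarQ + var_zeta))

  eta_cdf <- function(qv) {
    # variance-adjusted quadratic-form CDF at a vector of quantiles; the
    # closed-form Liu approximation keeps the omnibus integration cheap
    # (the reported per-rho p-values stay on the exact Imhof path)
    vapply(qv, function(qq) {
      if (qq <= 0) return(0)
      q_adj <- (qq - MuQ) * sd_ratio + MuQ
      if (q_adj <= 0) return(0)
      1 - .liu_pvalue(q_adj, lam_bar)
    }, numeric(1))
  }
  integrand <- function(x) {
    qv <- vapply(x, function(xx) min((qmin - tau * xx) / (1 - grid)), numeric(1))
    eta_cdf(qv) * dchisq(x, df = 1)
  }
  p_omni <- tryCatch({
    it <- integrate(integrand, lower = 0, upper = 40, subdivisions = 1000L,
                    rel.tol = 1e-6, abs.tol = 1e-10)
    1 - it$value
  }, error = function(e) NA_real_)
  method <- "lee-integration"
  if (is.na(p_omni) || p_omni <= 0 || p_omni > 1) {
    warning("skat_o: omnibus integration failed; Bonferroni over grid used")
    p_omni <- min(pmin_obs * length(grid), 1)
    method <- "bonferroni-fallback"
  }
  # never report below the attainable minimum corrected scale
  p_omni <- min(p_omni, pmin_obs * length(grid), 1)
  list(p = max(p_omni, 1e-300), p_each = p_each,
       rho_min = rho_grid[which.min(p_each)], method = method)
}

#' Principal-component gene test from summary statistics
#'
#' Projects the weighted z vector onto the leading eigenvectors of the
#' weighted LD kernel `W R W`, keeping the minimal number of components
#' whose eigenvalues reach `var_threshold` of the total variance; the
#' sum of squared standardized scores is chi-square with k df under the
#' null.
#'
#' @inheritParams burden_test
#' @param var_threshold Cumulative variance-explained cutoff in (0, 1].
#' @return List with `statistic`, `df` (number of components `k`), `p`.
#' @export
pca_test <- function(z, w = NULL, R = NULL, var_threshold = 0.85) {
  stopifnot(var_threshold > 0, var_threshold <= 1)
  a <- .check_zwR(z, w, R)
  m <- length(a$z)
  Sigma <- a$R * tcrossprod(a$w)
  ev <- eigen(Sigma, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-8
  if (!any(pos)) stop("pca_test: kernel has no positive eigenvalue")
  vals <- ev$values[pos]
  frac <- cumsum(vals) / sum(vals)
  k <- which(frac >= var_threshold - 1e-12)[1]
  zt <- a$w * a$z
  scores <- as.numeric(crossprod(ev$vectors[, seq_len(k), drop = FALSE], zt))
  Tstat <- sum(scores^2 / vals[seq_len(k)])
  list(statistic = Tstat, df = k,
       p = max(pchisq(Tstat, df = k, lower.tail = FALSE), 1e-300))
}

#' Aggregated Cauchy combination of p-values (ACAT)
#'
#' `T = sum(w * tan((0.5 - p) * pi)) / sum(w)`;
#' `p_combined = 0.5 - atan(T) / pi`.  Inputs at 0 or 1 are clamped to
#' `[1e-15, 1 - 1e-15]` with a warning; tiny p-values use the
#' numerically stable expansion `tan((0.5 - p) pi) ~ 1 / (p pi)`.
#'
#' @param p P-values in (0, 1).
#' @param weights Positive weights (default equal).
#' @return The combined p-value.
#' @export
acat <- function(p, weights = NULL) {
  stopifnot(length(p) >= 1L, all(is.finite(p)))
  if (is.null(weights)) weights <- rep(1, length(p))
  stopifnot(length(weights) == length(p), all(weights > 0))
  eps <- 1e-15
  if (any(p <= 0 | p >= 1)) {
    warning(sprintf("acat: %d p-value(s) clamped to [%g, %g]",
                    sum(p <= 0 | p >= 1), eps, 1 - eps))
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  w <- weights / sum(weights)
  small <- p < 1e-16
  comp <- numeric(length(p))
  comp[small] <- 1 / (p[small] * pi)
  comp[!small] <- tan((0.5 - p[!small]) * pi)
  Tstat <- sum(w * comp)
  out <- if (Tstat > 1e15) 1 / (Tstat * pi) else 0.5 - atan(Tstat) / pi
  min(max(out, 1e-300), 1 - 1e-16)
}

#' Run the full gene-test battery on prepared inputs
#'
#' Applies burden, SKAT (`rho = 0`), SKAT-O, and the PCA test to one
#' gene's aligned `z`, `w`, `R`, and combines SKAT-O and PCA by ACAT-O.
#' If only a single (possibly collapsed) variant is available the
#' regression-based tests are skipped and all p-values reduce to the
#' two-sided single-variant p.
#'
#' @inheritParams burden_test
#' @param cfg A [gene_test_config()].
#' @return A one-row `data.table` with columns `n_variants`, `p_burden`,
#'   `p_skat`, `p_skat_o`, `p_pca`, `p_acat_o`.
#' @export
gene_test <- function(z, w = NULL, R = NULL, cfg = gene_test_config()) {
  m <- length(z)
  if (m == 1L) {
    p1 <- max(2 * pnorm(-abs(z)), 1e-300)
    return(data.table(n_variants = 1L, p_burden = p1, p_skat = NA_real_,
                      p_skat_o = NA_real_, p_pca = NA_real_,
                      p_acat_o = NA_real_))
  }
  bt <- burden_test(z, w, R)
  sk <- skat(z, w, R, rho = 0)
  so <- skat_o(z, w, R, rho_grid = cfg$rho_grid)
  pc <- pca_test(z, w, R, var_threshold = cfg$pca_var_threshold)
  data.table(n_variants = as.integer(m),
             p_burden = bt$p, p_skat = sk$p, p_skat_o = so$p,
             p_pca = pc$p, p_acat_o = acat(c(so$p, pc$p)))
}
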