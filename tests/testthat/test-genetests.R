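# Gene-based tests from summary statistics: masks, LD, and the five
# statistics.

test_that("mask vocabularies are nested and sized as documented", {
  v <- mask_vocabularies
  expect_length(v$LoF, 7)
  expect_true(all(v$LoF %in% v$LoF_missense))
  expect_true(all(v$LoF_missense %in% v$LoF_protein_coding))
  expect_true(all(v$LoF_protein_coding %in% v$all_intragenic))
  expect_true("stop_gained" %in% v$LoF)
  expect_length(v$LoF_missense, 12)
  expect_length(v$LoF_protein_coding, 17)
})

test_that("build_mask counts a toy gene correctly and routes ultra-rares", {
  panel <- data.table::data.table(
    id = paste0("v", 1:9), chrom = "1", pos = 1:9,
    gene = "G1",
    consequence = c(rep("stop_gained", 3), rep("missense_variant", 2),
                    rep("synonymous_variant", 4)))
  ss <- data.table::data.table(id = paste0("v", 1:9),
                               freq = rep(0.005, 9),
                               mac = c(50L, 5L, 50L, 50L, 3L, 50L, 50L,
                                       2L, 50L))
  sizes <- vapply(c("LoF", "LoF_missense", "LoF_protein_coding"),
                  function(mn) {
                    mk <- build_mask(panel, "G1", mn, ss)
                    length(mk$test_ids) + length(mk$collapse_ids)
                  }, numeric(1))
  expect_equal(unname(sizes), c(3, 5, 9))
  mk <- build_mask(panel, "G1", "LoF_protein_coding", ss)
  expect_setequal(mk$collapse_ids, c("v2", "v5", "v8"))
  # a stop_gained variant appears in every mask
  for (mn in mask_names()) {
    expect_true("v1" %in% build_mask(panel, "G1", mn, ss)$test_ids)
  }
  # LoF mask on a synonymous-only gene selects nothing
  panel2 <- data.table::copy(panel)[, consequence := "synonymous_variant"]
  expect_null(build_mask(panel2, "G1", "LoF", ss))
})

test_that("LD matrix: duplicates, filters, and null-correlation scale", {
  set.seed(71)
  n <- 20000
  G <- matrix(rbinom(n * 6, 2, 0.01), n, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  G <- cbind(G, v7 = G[, 1])                    # duplicated column
  ld <- compute_ld(G)
  expect_equal(ld$R["v1", "v7"], 1, tolerance = 1e-6)
  # all other pairs are independent draws: null-scale correlations
  others <- ld$R[setdiff(ld$ids, c("v1", "v7")), setdiff(ld$ids, c("v1", "v7"))]
  expect_lt(max(abs(others[upper.tri(others)])), 0.05)
  # MAC filter: a 2-copy variant is excluded under --mac 3 style filtering
  G2 <- G
  G2[, 2] <- 0L; G2[c(1, 2), 2] <- 1L           # MAC 2
  ld2 <- compute_ld(G2, mac_min = 3)
  expect_false("v2" %in% ld2$ids)
  expect_error(compute_ld(G[, 1, drop = FALSE]), "fewer than 2")
})

test_that("burden test: single variant, cancellation, and LD denominator", {
  expect_equal(burden_test(2.1, 1, matrix(1, 1, 1))$p, 2 * pnorm(-2.1))
  out <- burden_test(c(2, -2), c(1, 1), diag(2))
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
  # perfect LD doubles the variance of the sum
  R <- matrix(1, 2, 2)
  expect_equal(burden_test(c(2, 2), c(1, 1), R)$statistic, 2)
})

test_that("SKAT: degenerate cases and the rho = 1 burden identity", {
  z <- c(1.5, -0.5, 2, 1); w <- c(1, 2, 1, 1.5)
  R <- 0.5 * diag(4) + 0.5
  expect_equal(skat(z, w, R, rho = 1)$p, burden_test(z, w, R)$p,
               tolerance = 1e-6)
  # single variant: two-sided normal p at any rho
  for (rho in c(0, 0.5, 1)) {
    expect_equal(skat(1.7, 1, matrix(1, 1, 1), rho)$p, 2 * pnorm(-1.7),
                 tolerance = 1e-12)
  }
})

test_that("SKAT p matches a large Monte-Carlo draw of the quadratic form", {
  set.seed(73)
  m <- 5
  A <- matrix(rnorm(m * m), m); R <- cov2cor(crossprod(A) + diag(m))
  w <- maf_weights(c(0.001, 0.004, 0.002, 0.008, 0.01))
  z <- as.numeric(chol(R) %*% rnorm(m)) + c(1.5, 0, 0.5, 0, 0)
  sk <- skat(z, w, R, rho = 0)
  ndraw <- 1e6
  L <- chol(R)
  Z <- matrix(rnorm(ndraw * m), ncol = m) %*% L
  Qmc <- rowSums(sweep(Z, 2, w, `*`)^2)
  p_mc <- mean(Qmc > sk$statistic)
  se <- sqrt(max(p_mc, 1 / ndraw) * (1 - p_mc) / ndraw)
  expect_lt(abs(sk$p - p_mc), 3 * se + 1e-8)
})

test_that("SKAT-O: grid dominance, degenerate gene, concentrated signal", {
  z <- c(1.8, 1.9, 2.0, 1.7); w <- rep(1, 4)
  R <- 0.8 * matrix(1, 4, 4); diag(R) <- 1
  so <- skat_o(z, w, R)
  expect_lte(so$p, min(so$p_each) * length(so$p_each) + 1e-12)
  expect_gt(so$p, 0)
  # all-equal z under strong LD: optimum lives near the burden end
  expect_gte(so$rho_min, 0.5)
  expect_lt(abs(log10(so$p / min(so$p_each))), 1)
  # one-variant gene reduces to the two-sided normal p
  expect_equal(skat_o(2.2, 1, matrix(1, 1, 1))$p, 2 * pnorm(-2.2),
               tolerance = 1e-12)
})

test_that("PCA test: identity kernel is chi-square, rank-1 kernel is burden-like", {
  z <- c(1, -2, 0.5)
  out <- pca_test(z, w = rep(1, 3), R = diag(3), var_threshold = 1)
  expect_equal(out$df, 3)
  expect_equal(out$statistic, sum(z^2), tolerance = 1e-10)
  expect_equal(out$p, pchisq(sum(z^2), 3, lower.tail = FALSE),
               tolerance = 1e-10)
  # perfect LD: a single component carrying the burden direction
  R1 <- matrix(1, 3, 3)
  zb <- c(1.2, 1.2, 1.2)
  out1 <- pca_test(zb, w = rep(1, 3), R = R1, var_threshold = 0.85)
  expect_equal(out1$df, 1)
  expect_equal(out1$p, burden_test(zb, rep(1, 3), R1)$p, tolerance = 1e-6)
})

test_that("ACAT: fixed points, tail expansion, clamping", {
  expect_equal(acat(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(acat(rep(0.123, 5)), 0.123, tolerance = 1e-10)
  # closed form evaluated independently of acat()'s branching
  p_direct <- 0.5 - atan(mean(tan((0.5 - c(1e-6, 0.9)) * pi))) / pi
  expect_equal(acat(c(1e-6, 0.9)), p_direct, tolerance = 1e-10)
  expect_equal(p_direct, 2e-6, tolerance = 1e-4)
  expect_warning(p0 <- acat(c(0, 0.5)), "clamped")
  expect_gt(p0, 0)
  # symmetry under equal weights
  expect_equal(acat(c(0.01, 0.2, 0.7)), acat(c(0.7, 0.01, 0.2)),
               tolerance = 1e-12)
  # combined p never beats the best input by more than the count factor
  ps <- c(0.002, 0.3, 0.6)
  expect_gt(acat(ps), min(ps) / length(ps))
})

test_that("all five p-values are invariant to reordering and joint sign flips", {
  set.seed(79)
  m <- 6
  A <- matrix(rnorm(m * m), m); R <- cov2cor(crossprod(A) + diag(m))
  z <- as.numeric(chol(R) %*% rnorm(m)) + 0.8
  w <- maf_weights(runif(m, 1e-4, 0.01))
  base <- gene_test(z, w, R)
  perm <- sample(m)
  permuted <- gene_test(z[perm], w[perm], R[perm, perm])
  flipped <- gene_test(-z, w, R)
  for (col in c("p_burden", "p_skat", "p_skat_o", "p_pca", "p_acat_o")) {
    expect_equal(permuted[[col]], base[[col]], tolerance = 1e-8)
    expect_equal(flipped[[col]], base[[col]], tolerance = 1e-8)
  }
})

test_that("summary-statistic tests match individual-level counterparts", {
  set.seed(83)
  n <- 6000; m <- 6
  maf <- runif(m, 0.003, 0.01)
  G <- ar1_genotypes(n, maf, rho = 0.3, seed = 83)
  X <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  eta <- -1.6 + 0.35 * scale(G[, 2]) + 0.05 * X[, 1]
  y <- rbinom(n, 1, plogis(eta))
  # summary route: package score scan + genotype LD
  ss <- ewas(G, y, X, qc = NULL)
  R <- compute_ld(G, mac_min = 1)$R
  w <- maf_weights(ss$freq)
  # individual-level oracles
  p_b_ind <- oracle_burden_p(G, y, X, w)
  p_b_sum <- burden_test(ss$z, w, R)$p
  expect_lt(abs(log10(p_b_sum / p_b_ind)), 0.12)
  p_s_ind <- oracle_skat_p_mc(G, y, X, w, rho = 0, ndraw = 2e5)
  p_s_sum <- skat(ss$z, w, R, rho = 0)$p
  se <- sqrt(max(p_s_ind, 5e-6) / 2e5)
  expect_lt(abs(p_s_sum - p_s_ind), max(3 * se, 0.15 * p_s_ind))
})
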