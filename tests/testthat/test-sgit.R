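# Shared-genetic-impact-trait construction: phenotypic correlation from
# z-scores, one-factor fit, optimal coefficients, combined statistics.

test_that("phenotypic correlation is recovered from null z-scores", {
  set.seed(61)
  m <- 10000
  P <- matrix(c(1, .4, .1, .4, 1, .25, .1, .25, 1), 3)
  L <- chol(P)
  Z <- matrix(rnorm(m * 3), m, 3) %*% L
  Pest <- estimate_pheno_corr_from_z(Z, truncation = 2)
  expect_equal(diag(Pest), rep(1, 3))
  # attenuation-corrected estimator: within Monte-Carlo error
  expect_lt(max(abs(Pest - P)), 0.05)
  # independent traits: off-diagonals near zero
  Z0 <- matrix(rnorm(m * 3), m, 3)
  P0 <- estimate_pheno_corr_from_z(Z0, truncation = 2)
  expect_lt(max(abs(P0[upper.tri(P0)])), 0.03)
})

test_that("identical traits give unit off-diagonal correlation", {
  set.seed(62)
  z <- rnorm(5000)
  P <- estimate_pheno_corr_from_z(cbind(z, z), truncation = 2)
  expect_equal(P[1, 2], 1, tolerance = 1e-6)
})

test_that("too few null variants raises an informative error", {
  Z <- matrix(rnorm(600, sd = 4), ncol = 3)
  expect_error(estimate_pheno_corr_from_z(Z, truncation = 0.05), "0.05")
})

test_that("one-factor loadings: triad closed form and exact recovery", {
  # exchangeable case: all off-diagonals 0.81 -> lambda 0.9
  G <- matrix(0.81, 3, 3); diag(G) <- 1
  expect_equal(unname(fit_one_factor(G)), rep(0.9, 3), tolerance = 1e-12)
  # triad arithmetic: (0.72, 0.63, 0.56) -> lambda_1 = 0.9
  G2 <- diag(3)
  G2[1, 2] <- G2[2, 1] <- 0.72
  G2[1, 3] <- G2[3, 1] <- 0.63
  G2[2, 3] <- G2[3, 2] <- 0.56
  lam <- fit_one_factor(G2)
  expect_equal(unname(lam[1]), sqrt(0.72 * 0.63 / 0.56), tolerance = 1e-12)
  expect_equal(unname(lam[1]), 0.9, tolerance = 1e-12)
  # rank-1 structure is recovered exactly (K = 4 least-squares path)
  lam4 <- c(0.9, 0.7, 0.5, 0.8)
  G4 <- tcrossprod(lam4); diag(G4) <- 1
  expect_equal(unname(fit_one_factor(G4)), lam4, tolerance = 1e-6)
  # non-positive off-diagonal: unidentified
  G2[1, 2] <- G2[2, 1] <- -0.1
  expect_error(fit_one_factor(G2), "unidentified")
})

test_that("SGIT coefficients: symmetry, zero-loading exclusion, normalization", {
  # exchangeable traits get equal coefficients
  G <- matrix(0.81, 3, 3); diag(G) <- 1
  P <- matrix(0.3, 3, 3); diag(P) <- 1
  tp <- trait_panel(c("A", "B", "C"), rep(0.1, 3), G, P)
  w <- sgit_coefficients(tp)
  expect_equal(unname(w$a[1]), unname(w$a[2]), tolerance = 1e-10)
  expect_equal(unname(w$a[2]), unname(w$a[3]), tolerance = 1e-10)
  expect_equal(w$norm, 1, tolerance = 1e-10)
  # a trait with zero loading and orthogonal phenotypes contributes nothing
  tp2 <- trait_panel(c("A", "B", "C"), rep(0.1, 3), G, diag(3))
  w2 <- sgit_coefficients(tp2, lambda = c(0.9, 0.9, 0))
  expect_equal(unname(w2$a[3]), 0, tolerance = 1e-12)
})

test_that("closed-form coefficients equal brute-force maximization", {
  for (i in 1:20) {
    rp <- random_trait_panel()
    w <- sgit_coefficients(rp$panel, lambda = rp$lambda)
    gamma <- rp$lambda * sqrt(rp$panel$h2)
    a_bf <- oracle_sgit_direction(rp$panel$P, gamma, seed = i)
    expect_equal(unname(w$a), unname(a_bf), tolerance = 1e-3)
  }
})

test_that("combination heritability: scalar formula and dominance over inputs", {
  # hand-computed 2-trait example
  h2 <- c(0.2, 0.1)
  G <- matrix(c(1, 0.8, 0.8, 1), 2)
  P <- matrix(c(1, 0.3, 0.3, 1), 2)
  tp <- trait_panel(c("A", "B"), h2, G, P)
  a <- c(0.6, 0.5)
  C <- G * outer(sqrt(h2), sqrt(h2))
  manual <- as.numeric(t(a) %*% C %*% a / (t(a) %*% P %*% a))
  expect_equal(sgit_h2(tp, a), manual, tolerance = 1e-12)
  # single trait: combination h2 collapses to that trait's h2
  expect_equal(sgit_h2(tp, c(1, 0)), 0.2, tolerance = 1e-12)
  # default-style panel: the optimal combination is at least as heritable
  # as every input trait
  G3 <- matrix(0.9, 3, 3); diag(G3) <- 1
  P3 <- matrix(c(1, .16, .10, .16, 1, .08, .10, .08, 1), 3)
  tp3 <- trait_panel(c("CBP", "dorsalgia", "IDD"), c(0.12, 0.114, 0.08),
                     G3, P3)
  w3 <- sgit_coefficients(tp3)
  expect_gte(w3$h2_sgit, max(tp3$h2))
})

test_that("SGIT z-scores: identity weights, null variance, synergy", {
  set.seed(67)
  m <- 10000
  P <- matrix(c(1, .2, .1, .2, 1, .15, .1, .15, 1), 3)
  L <- chol(P)
  Z <- matrix(rnorm(m * 3), m, 3) %*% L
  mk_ss <- function(zcol) data.table::data.table(
    id = paste0("v", seq_len(m)), freq = rep(0.005, m), mac = 50L,
    z = zcol, n = 20000L)
  ss <- lapply(1:3, function(k) mk_ss(Z[, k]))
  tp <- trait_panel(c("A", "B", "C"), c(.1, .1, .1),
                    {G <- matrix(.81, 3, 3); diag(G) <- 1; G}, P)
  # a = (1, 0, 0): SGIT z equals trait-1 z
  w1 <- list(a = c(1, 0, 0), norm = 1)
  class(w1) <- "sgit_weights"
  out1 <- sgit_summary_stats(ss, w1, P = NULL)
  expect_equal(out1$z, Z[, 1], tolerance = 1e-12)
  # optimal weights: null z_S has unit variance
  w <- sgit_coefficients(tp)
  out <- sgit_summary_stats(ss, w, P = P)
  expect_gt(var(out$z), 0.97)
  expect_lt(var(out$z), 1.03)
  # equal signal in all traits amplifies beyond any single trait
  ss2 <- lapply(1:3, function(k) mk_ss(rep(2, m)))
  out2 <- sgit_summary_stats(ss2, w, P = P)
  expect_gt(out2$z[1], 2)
})

test_that("allele-frequency misalignment across traits is an error", {
  mk <- function(f) data.table::data.table(id = "v1", freq = f, mac = 10L,
                                           z = 1, n = 1000L)
  w <- list(a = c(0.5, 0.5), norm = 1)
  class(w) <- "sgit_weights"
  expect_error(sgit_summary_stats(list(mk(0.01), mk(0.4)), w),
               "frequency mismatch")
})
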