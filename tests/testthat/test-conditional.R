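# COJO-style selection and conditional re-scoring.

test_that("empty conditioning set reproduces marginal statistics exactly", {
  ss <- data.table::data.table(id = c("a", "b"), freq = c(0.01, 0.005),
                               z = c(2.5, -1.2), n = c(10000L, 10000L))
  R <- diag(2); dimnames(R) <- list(c("a", "b"), c("a", "b"))
  out <- conditional_summary(c("a", "b"), character(0), R, ss)
  expect_identical(out$z_cond, out$z_marg)
  expect_identical(out$b_cond, out$b_marg)
  expect_identical(out$p_cond, out$p_marg)
})

test_that("zero LD with the conditioning set leaves statistics unchanged", {
  ids <- c("t", "c1", "c2")
  R <- diag(3); dimnames(R) <- list(ids, ids)
  R["c1", "c2"] <- R["c2", "c1"] <- 0.3
  ss <- data.table::data.table(id = ids, freq = rep(0.01, 3),
                               z = c(3, 4, -2), n = rep(20000L, 3))
  out <- conditional_summary("t", c("c1", "c2"), R, ss)
  expect_equal(out$z_cond, out$z_marg, tolerance = 1e-12)
})

test_that("self-conditioning zeroes the target", {
  ids <- c("t", "c1")
  R <- matrix(c(1, .5, .5, 1), 2, dimnames = list(ids, ids))
  ss <- data.table::data.table(id = ids, freq = rep(0.01, 2),
                               z = c(3, 4), n = rep(20000L, 2))
  out <- conditional_summary("t", c("t", "c1"), R, ss)
  expect_equal(out$b_cond, 0)
  expect_equal(out$z_cond, 0)
  expect_equal(out$p_cond, 1)
})

test_that("stepwise selection keeps one of two perfectly correlated signals", {
  ids <- c("s1", "s2", "w1")
  R <- diag(3); dimnames(R) <- list(ids, ids)
  R["s1", "s2"] <- R["s2", "s1"] <- 1
  ss <- data.table::data.table(id = ids, pos = c(100L, 200L, 300L),
                               freq = rep(0.01, 3),
                               z = c(6, 6, 0.5),
                               p = 2 * pnorm(-abs(c(6, 6, 0.5))),
                               n = rep(20000L, 3))
  sel <- cojo_select(ss, R, p_threshold = 1e-4)
  expect_length(sel, 1)
  expect_true(sel %in% c("s1", "s2"))
})

test_that("two independent planted signals are both recovered", {
  set.seed(91)
  n <- 15000
  maf <- rep(0.05, 12)
  G <- ar1_genotypes(n, maf, rho = 0.4, seed = 91)
  y <- rbinom(n, 1, plogis(-1.8 + 0.35 * G[, 3] + 0.35 * G[, 10]))
  ss <- ewas(G, y, qc = NULL)
  ss[, pos := seq_len(.N) * 100L]
  R <- compute_ld(G, mac_min = 1)$R
  sel <- cojo_select(ss, R, p_threshold = 1e-4)
  expect_setequal(sel, c("v3", "v10"))
})

test_that("conditional effects match the full joint logistic model", {
  set.seed(97)
  n <- 20000
  maf <- runif(8, 0.05, 0.2)      # common variants keep the oracle stable
  G <- ar1_genotypes(n, maf, rho = 0.5, seed = 97)
  X <- cbind(age = rnorm(n))
  y <- rbinom(n, 1, plogis(-1.2 + 0.12 * G[, 2] + 0.1 * G[, 6]))
  ss <- ewas(G, y, X, qc = NULL)
  R <- compute_ld(G, mac_min = 1)$R
  conditioning <- c("v6")
  for (target in c("v2", "v5")) {
    out <- conditional_summary(target, conditioning, R, ss)
    zj <- oracle_joint_z(y, X, G, target, conditioning)
    if (abs(zj) < 4 && abs(zj) > 0.5) {
      expect_lt(abs(out$z_cond - zj) / abs(zj), 0.05)
    }
  }
})

test_that("conditioning on a correlated external signal attenuates the gene, independent signals do not", {
  set.seed(101)
  n <- 12000
  m <- 10                                 # v1..v5 external, v6..v10 in-gene
  reps <- 8
  att <- inv <- logical(reps)
  for (r in seq_len(reps)) {
    # tight AR chain: the external causal v5 sits in strong LD (r^2 ~ 0.8)
    # with the first in-gene variants
    G <- ar1_genotypes(n, rep(0.05, m), rho = 0.95, seed = 200 + r)
    y <- rbinom(n, 1, plogis(-1.5 + 0.3 * G[, 5]))
    ss <- ewas(G, y, qc = NULL)
    ss[, pos := c(1:5 * 100L, 10000L + 1:5 * 100L)]
    R <- compute_ld(G, mac_min = 1)$R
    res <- conditional_gene_test(paste0("v", 6:10), c(10000L, 11000L),
                                 ss, R, w = rep(1, 5))
    att[r] <- length(res$conditioning) > 0 &&
      res$conditional_test$p_acat_o >= res$marginal_test$p_acat_o
    # independent external signal: uncorrelated genotypes
    G2 <- cbind(ar1_genotypes(n, rep(0.05, 5), rho = 0.95, seed = 300 + r),
                ar1_genotypes(n, rep(0.05, 5), rho = 0.95, seed = 400 + r))
    colnames(G2) <- paste0("v", 1:10)
    y2 <- rbinom(n, 1, plogis(-1.5 + 0.3 * G2[, 5]))
    ss2 <- ewas(G2, y2, qc = NULL)
    ss2[, pos := c(1:5 * 100L, 10000L + 1:5 * 100L)]
    R2 <- compute_ld(G2, mac_min = 1)$R
    res2 <- conditional_gene_test(paste0("v", 6:10), c(10000L, 11000L),
                                  ss2, R2, w = rep(1, 5))
    inv[r] <- abs(log10(res2$conditional_test$p_acat_o /
                          res2$marginal_test$p_acat_o)) < 0.35
  }
  expect_gte(sum(att), reps - 2)
  expect_gte(sum(inv), reps - 2)
})

test_that("selection result is invariant to input row order", {
  set.seed(103)
  n <- 8000
  G <- ar1_genotypes(n, rep(0.02, 8), rho = 0.3, seed = 103)
  y <- rbinom(n, 1, plogis(-1.5 + 0.4 * G[, 2]))
  ss <- ewas(G, y, qc = NULL)
  ss[, pos := seq_len(.N) * 50L]
  R <- compute_ld(G, mac_min = 1)$R
  s1 <- cojo_select(ss, R, p_threshold = 1e-3)
  s2 <- cojo_select(ss[sample(.N)], R, p_threshold = 1e-3)
  expect_identical(s1, s2)
})
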