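# Independent oracles.  These deliberately re-derive every quantity
# from raw data (or by brute force / Monte Carlo) without touching the
# package's summary-statistic code paths.

# Monte-Carlo tail probability of Q = sum lambda_k chi^2_1
mc_quadform_p <- function(q, lambda, ndraw = 1e6, seed = 99) {
  set.seed(seed)
  m <- length(lambda)
  draws <- matrix(stats::rchisq(ndraw * m, df = 1), ncol = m) %*% lambda
  mean(draws > q)
}

# null logistic fit pieces computed from scratch with stats::glm
.oracle_null <- function(y, X) {
  df <- data.frame(y = y, X)
  fit <- stats::glm(y ~ ., family = binomial(), data = df)
  mu <- stats::fitted(fit)
  D <- mu * (1 - mu)
  Xd <- stats::model.matrix(fit)
  list(mu = mu, D = D, X = Xd)
}

# individual-level covariate-adjusted score pieces for a genotype block:
# U_j = g_j'(y - mu),  V = G'DG - G'DX (X'DX)^{-1} X'DG
oracle_scores <- function(G, y, X) {
  nl <- .oracle_null(y, X)
  U <- as.numeric(crossprod(G, y - nl$mu))
  DX <- nl$X * nl$D
  A <- crossprod(nl$X, DX)
  B <- crossprod(DX, G)
  V <- crossprod(G, G * nl$D) - t(B) %*% solve(A, B)
  list(U = U, V = (V + t(V)) / 2)
}

# individual-level weighted burden p: the summary statistic weights the
# per-variant z-scores, so its individual-level counterpart is the
# score test of the w/sd(U)-weighted dosage sum
oracle_burden_p <- function(G, y, X, w) {
  sc <- oracle_scores(G, y, X)
  wt <- w / sqrt(diag(sc$V))
  zb <- sum(wt * sc$U) / sqrt(as.numeric(crossprod(wt, sc$V %*% wt)))
  2 * stats::pnorm(-abs(zb))
}

# individual-level SKAT at mixing rho, null law by Monte Carlo so the
# oracle shares no analytic machinery with the package
oracle_skat_p_mc <- function(G, y, X, w, rho = 0, ndraw = 2e5, seed = 17) {
  sc <- oracle_scores(G, y, X)
  wt <- w / sqrt(diag(sc$V))        # weights on the z scale
  z <- sc$U / sqrt(diag(sc$V))
  Q <- (1 - rho) * sum((wt * z)^2) + rho * sum(wt * z)^2
  Rv <- stats::cov2cor(sc$V)
  set.seed(seed)
  L <- chol(Rv + diag(1e-10, nrow(Rv)))
  Zs <- matrix(stats::rnorm(ndraw * length(z)), ncol = length(z)) %*% L
  Zw <- sweep(Zs, 2, wt, `*`)
  Qs <- (1 - rho) * rowSums(Zw^2) + rho * rowSums(Zw)^2
  mean(Qs > Q)
}

# Wald z of the target coefficient in the full joint logistic model
oracle_joint_z <- function(y, X, G, target, conditioning) {
  df <- data.frame(y = y, X,
                   tgt = G[, target],
                   G[, conditioning, drop = FALSE])
  fit <- stats::glm(y ~ ., family = binomial(), data = df)
  s <- summary(fit)$coefficients
  s["tgt", "z value"]
}

# brute-force maximizer of the SGIT objective (a'gamma)^2 / (a'Pa)
oracle_sgit_direction <- function(P, gamma, n_starts = 25, seed = 3) {
  set.seed(seed)
  obj <- function(a) -sum(a * gamma)^2 / as.numeric(crossprod(a, P %*% a))
  best <- NULL
  for (s in seq_len(n_starts)) {
    a0 <- stats::rnorm(length(gamma))
    o <- stats::optim(a0, obj, method = "BFGS")
    if (is.null(best) || o$value < best$value) best <- o
  }
  a <- best$par / sqrt(as.numeric(crossprod(best$par, P %*% best$par)))
  if (a[which.max(abs(a))] < 0) a <- -a
  a
}

# random valid trait panel for property tests
random_trait_panel <- function(K = 3) {
  repeat {
    lam <- stats::runif(K, 0.3, 0.99)
    G <- tcrossprod(lam); diag(G) <- 1
    P <- stats::cov2cor(crossprod(matrix(stats::rnorm(2 * K * K), ncol = K)) / (2 * K) +
                          diag(K))
    h2 <- stats::runif(K, 0.02, 0.4)
    ok <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) > 0.05
    if (ok) return(list(panel = trait_panel(paste0("T", 1:K), h2, G, P),
                        lambda = lam))
  }
}
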