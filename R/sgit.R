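# Construction of the shared genetic impact trait (SGIT): a linear
# combination a'T of K genetically correlated traits whose coefficients
# maximize the proportion of the shared genetic component in the
# combination's genetic background.  Under a single-common-factor model
# of the genetic correlation matrix (loadings lambda), the shared
# genetic covariance between the combination and the factor is a'gamma
# with gamma_k = lambda_k sqrt(h2_k); maximizing (a'gamma)^2 / (a'Pa)
# (a generalized Rayleigh quotient with rank-1 numerator) gives
# a = P^{-1} gamma up to scale.  Normalizing to a'Pa = 1 makes the
# combination's z-score simply a'z.

#' Trait panel: heritabilities and correlation structure
#'
#' @param traits Trait names (length K).
#' @param h2 SNP heritabilities in `[0, 1)`.
#' @param G K x K genetic correlation matrix.
#' @param P K x K phenotypic correlation matrix.
#' @return An object of class `trait_panel`.
#' @export
trait_panel <- function(traits, h2, G, P) {
  K <- length(traits)
  stopifnot(length(h2) == K, all(h2 >= 0 & h2 < 1),
            is.matrix(G), all(dim(G) == K),
            is.matrix(P), all(dim(P) == K))
  for (M in list(G = G, P = P)) {
    if (max(abs(M - t(M))) > 1e-8 || max(abs(diag(M) - 1)) > 1e-8) {
      stop("trait_panel: correlation matrices must be symmetric with unit diagonal")
    }
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("trait_panel: correlation matrix not positive semi-definite")
    }
  }
  dimnames(G) <- dimnames(P) <- list(traits, traits)
  structure(list(traits = traits, h2 = setNames(h2, traits), G = G, P = P),
            class = "trait_panel")
}

#' Estimate the phenotypic correlation matrix from z-scores
#'
#' Stephens-style summary-level estimator: under the null the z-scores
#' of the K traits at a variant are N(0, P) with P the phenotypic
#' correlation matrix, so the correlation of z across putatively null
#' variants (|z| below `truncation` in every trait) estimates P.
#' Restricting to the box `|z| < truncation` attenuates correlations in
#' a known way; the estimator inverts the exact truncated
#' bivariate-normal attenuation curve (computed by quadrature) so the
#' returned matrix is unbiased for the untruncated correlation.
#'
#' @param z_matrix Variants x traits matrix of z-scores.
#' @param truncation Null-variant |z| threshold (default 2).
#' @param min_null Minimum number of surviving null variants.
#' @return A symmetric unit-diagonal positive semi-definite matrix.
#' @export
estimate_pheno_corr_from_z <- function(z_matrix, truncation = 2,
                                       min_null = 100L) {
  z_matrix <- as.matrix(z_matrix)
  stopifnot(ncol(z_matrix) >= 2L, truncation > 0)
  keep <- rowSums(!is.finite(z_matrix)) == 0L &
    rowSums(abs(z_matrix) >= truncation) == 0L
  if (sum(keep) < min_null) {
    stop(sprintf("estimate_pheno_corr_from_z: only %d variants with |z| < %g in all traits (need >= %d)",
                 sum(keep), truncation, min_null))
  }
  P <- cor(z_matrix[keep, , drop = FALSE])
  P <- (P + t(P)) / 2
  for (i in seq_len(nrow(P) - 1L)) {
    for (j in (i + 1L):ncol(P)) {
      P[i, j] <- P[j, i] <- .detruncate_corr(P[i, j], truncation)
    }
  }
  ev <- eigen(P, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    vals <- pmax(ev$values, 1e-10)
    P <- cov2cor(ev$vectors %*% (vals * t(ev$vectors)))
  }
  diag(P) <- 1
  P
}

# correlation of a standard bivariate normal restricted to the box
# |z1| < t, |z2| < t, by Simpson quadrature
.trunc_corr <- function(rho, t, n_grid = 121L) {
  if (abs(rho) < 1e-12) return(0)
  if (abs(rho) > 1 - 1e-9) return(sign(rho))
  x <- seq(-t, t, length.out = n_grid)
  wts <- rep(c(2, 4), length.out = n_grid); wts[c(1, n_grid)] <- 1
  wts <- wts * (x[2] - x[1]) / 3
  W <- outer(wts, wts)
  X <- outer(x, rep(1, n_grid)); Y <- t(X)
  dens <- exp(-(X^2 - 2 * rho * X * Y + Y^2) / (2 * (1 - rho^2)))
  mass <- sum(W * dens)
  exy <- sum(W * X * Y * dens) / mass
  ex2 <- sum(W * X^2 * dens) / mass
  exy / ex2
}

# invert the attenuation: find rho with .trunc_corr(rho, t) = r_obs
.detruncate_corr <- function(r_obs, t) {
  if (!is.finite(r_obs) || abs(r_obs) < 1e-12) return(r_obs)
  s <- sign(r_obs); r <- abs(r_obs)
  if (r >= .trunc_corr(0.9995, t)) return(s * min(r, 1))
  s * uniroot(function(rho) .trunc_corr(rho, t) - r,
              lower = 0, upper = 0.9995, tol = 1e-8)$root
}

#' Fit a single-common-factor model to a genetic correlation matrix
#'
#' For K = 3 the loadings have the closed triad form
#' `lambda_i = sqrt(g_ij g_ik / g_jk)`; for K > 3 they are found by
#' least squares on the off-diagonals.  Loadings exceeding 1 (Heywood
#' cases) are clipped to `[0, 1]` with a warning.
#'
#' @param G Genetic correlation matrix with positive off-diagonals.
#' @return Vector of loadings `lambda` (named if `G` has dimnames).
#' @export
fit_one_factor <- function(G) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G), nrow(G) >= 3L)
  K <- nrow(G)
  off <- G[upper.tri(G)]
  if (any(off <= 0)) {
    stop("fit_one_factor: non-positive off-diagonal genetic correlation; ",
         "single-factor model unidentified")
  }
  if (K == 3L) {
    lambda <- c(sqrt(G[1, 2] * G[1, 3] / G[2, 3]),
                sqrt(G[1, 2] * G[2, 3] / G[1, 3]),
                sqrt(G[1, 3] * G[2, 3] / G[1, 2]))
  } else {
    obj <- function(l) {
      M <- tcrossprod(l)
      sum((G[upper.tri(G)] - M[upper.tri(M)])^2)
    }
    init <- sqrt(pmin(rowMeans(G) - 1 / K, 0.99))
    lambda <- stats::optim(init, obj, method = "L-BFGS-B",
                           lower = 1e-6, upper = 2)$par
  }
  if (any(lambda > 1)) {
    warning(sprintf("fit_one_factor: Heywood case, %d loading(s) clipped to 1",
                    sum(lambda > 1)))
    lambda <- pmin(lambda, 1)
  }
  setNames(lambda, rownames(G))
}

#' Optimal combination coefficients for the shared genetic impact trait
#'
#' Maximizes the proportion of shared genetic background in the
#' combination, `(a'gamma)^2 / (a'Pa)` with
#' `gamma_k = lambda_k sqrt(h2_k)`; the maximizer is `a = P^{-1} gamma`,
#' normalized to `a'Pa = 1` (unit phenotypic variance for the
#' combination) and sign-fixed so the largest-|a| trait is positive.
#'
#' @param panel A [trait_panel()].
#' @param lambda Factor loadings; by default fitted from `panel$G` via
#'   [fit_one_factor()].
#' @return An object of class `sgit_weights`: list with `a`, `lambda`,
#'   `gamma`, `norm` (`a'Pa`, equal to 1), `h2_sgit`.
#' @export
sgit_coefficients <- function(panel, lambda = NULL) {
  stopifnot(inherits(panel, "trait_panel"))
  if (is.null(lambda)) lambda <- fit_one_factor(panel$G)
  K <- length(panel$traits)
  stopifnot(length(lambda) == K)
  gamma <- as.numeric(lambda) * sqrt(as.numeric(panel$h2))
  P <- panel$P
  a0 <- tryCatch(solve(P, gamma),
                 error = function(e) stop("sgit_coefficients: singular phenotypic correlation matrix"))
  nrm <- as.numeric(crossprod(a0, P %*% a0))
  if (nrm <= 0) stop("sgit_coefficients: degenerate combination")
  a <- a0 / sqrt(nrm)
  if (a[which.max(abs(a))] < 0) a <- -a
  a <- setNames(as.numeric(a), panel$traits)
  w <- structure(list(a = a, lambda = setNames(as.numeric(lambda), panel$traits),
                      gamma = setNames(gamma, panel$traits),
                      norm = as.numeric(crossprod(a, P %*% a))),
                 class = "sgit_weights")
  w$h2_sgit <- sgit_h2(panel, w)
  w
}

#' Heritability of a linear combination of traits
#'
#' `h2 = a'Ca / a'Pa` with genetic covariance
#' `C_ij = g_ij sqrt(h2_i h2_j)` of the standardized traits.
#'
#' @param panel A [trait_panel()].
#' @param weights An `sgit_weights` object or a coefficient vector.
#' @return Heritability of the combination, in `[0, 1)`.
#' @export
sgit_h2 <- function(panel, weights) {
  stopifnot(inherits(panel, "trait_panel"))
  a <- if (inherits(weights, "sgit_weights")) weights$a else as.numeric(weights)
  h2 <- as.numeric(panel$h2)
  C <- panel$G * outer(sqrt(h2), sqrt(h2))
  as.numeric(crossprod(a, C %*% a) / crossprod(a, panel$P %*% a))
}

#' Summary statistics for the shared genetic impact trait
#'
#' Combines the per-trait z-scores row-wise: `z_S = a'z / sqrt(a'Pa)`
#' (with the `a'Pa = 1` normalization this is just `a'z`), with
#' `p = 2 Phi(-|z_S|)`.  Rows must be aligned on variant id and effect
#' allele across traits; misaligned rows raise an error rather than
#' being flipped silently.
#'
#' @param sumstats_list Named list (one element per trait, in panel
#'   order) of summary-statistic tables with columns `id`, `freq`, `z`,
#'   `n` (as produced by [ewas()]).
#' @param weights An `sgit_weights` object.
#' @param P Phenotypic correlation matrix (used to renormalize if the
#'   weights are not already `a'Pa = 1`).
#' @param freq_tol Maximum allowed effect-allele frequency discrepancy
#'   across traits before rows are declared misaligned.
#' @return A summary-statistic `data.table` for the combination (`id`,
#'   `freq`, `mac`, `b`, `se`, `z`, `p`, `n`, `flag`).
#' @export
sgit_summary_stats <- function(sumstats_list, weights, P = NULL,
                               freq_tol = 0.05) {
  stopifnot(is.list(sumstats_list), length(sumstats_list) >= 2L)
  a <- weights$a
  K <- length(a)
  stopifnot(length(sumstats_list) == K)
  denom <- if (is.null(P)) sqrt(weights$norm) else
    sqrt(as.numeric(crossprod(a, P %*% a)))
  ids <- Reduce(intersect, lapply(sumstats_list, function(s) s$id))
  if (!length(ids)) stop("sgit_summary_stats: no shared variant ids")
  ss <- lapply(sumstats_list, function(s) {
    s <- as.data.table(s)[match(ids, id)]
    s
  })
  fr <- vapply(ss, function(s) s$freq, numeric(length(ids)))
  fr <- matrix(fr, ncol = K)
  spread <- apply(fr, 1L, function(x) diff(range(x, na.rm = TRUE)))
  if (any(spread > freq_tol, na.rm = TRUE)) {
    bad <- ids[which(spread > freq_tol)[1]]
    stop(sprintf("sgit_summary_stats: effect-allele frequency mismatch across traits at %s; check allele alignment", bad))
  }
  zmat <- matrix(vapply(ss, function(s) s$z, numeric(length(ids))), ncol = K)
  zs <- as.numeric(zmat %*% a) / denom
  nmin <- do.call(pmin, c(lapply(ss, function(s) as.numeric(s$n)), na.rm = TRUE))
  out <- data.table(
    id = ids, freq = rowMeans(fr, na.rm = TRUE), mac = ss[[1]]$mac,
    b = zs / sqrt(pmax(nmin, 1)), se = 1 / sqrt(pmax(nmin, 1)),
    z = zs, p = pmax(2 * pnorm(-abs(zs)), 1e-300),
    n = as.integer(round(nmin)),
    flag = ifelse(is.finite(zs), "ok", "missing_component"))
  out[!is.finite(zs), `:=`(z = NA_real_, p = NA_real_, b = NA_real_)]
  out[]
}
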