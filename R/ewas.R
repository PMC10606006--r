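# Single-variant association scan.  The primary statistic is the
# covariate-adjusted logistic score test: one null model fit per trait,
# then per-variant score and variance in closed form.  Score tests stay
# stable down to a handful of carriers, which is why they are preferred
# over Wald statistics for ultra-rare variants; an optional saddlepoint
# correction guards the extreme case-control imbalance of the rarest
# trait.

#' Variant quality-control configuration
#'
#' @param maf_min Minimum minor allele frequency (default `5e-6`,
#'   applied as `>=`).
#' @param missingness_max Maximum per-variant missing fraction
#'   (default 0.02).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(maf_min = 5e-6, missingness_max = 0.02) {
  stopifnot(maf_min >= 0, maf_min < 0.5,
            missingness_max >= 0, missingness_max <= 1)
  structure(list(maf_min = maf_min, missingness_max = missingness_max),
            class = "qc_config")
}

#' Filter variants on MAF and missingness
#'
#' @param geno Dosage matrix (individuals x variants).
#' @param qc A [qc_config()].
#' @param verbose Log a one-line filter report via `message()`.
#' @return The genotype matrix restricted to surviving variants, with a
#'   `"qc_report"` attribute (counts removed per rule).
#' @export
qc_filter <- function(geno, qc = qc_config(), verbose = FALSE) {
  stopifnot(is.matrix(geno))
  m <- ncol(geno)
  miss <- colMeans(is.na(geno))
  maf <- vapply(seq_len(m), function(j) {
    x <- geno[, j][!is.na(geno[, j])]
    if (!length(x)) return(0)
    f <- mean(x) / 2
    min(f, 1 - f)
  }, numeric(1))
  fail_miss <- miss > qc$missingness_max
  fail_maf <- maf < qc$maf_min
  keep <- !(fail_miss | fail_maf)
  report <- c(n_input = m, n_kept = sum(keep),
              n_fail_missingness = sum(fail_miss), n_fail_maf = sum(fail_maf))
  if (verbose) {
    message(sprintf("qc_filter: kept %d/%d variants (%d failed missingness > %g, %d failed MAF < %g)",
                    report["n_kept"], m, report["n_fail_missingness"],
                    qc$missingness_max, report["n_fail_maf"], qc$maf_min))
  }
  out <- geno[, keep, drop = FALSE]
  attr(out, "qc_report") <- report
  out
}

#' Fit the null logistic model for a binary trait
#'
#' One fit per trait; the returned object carries everything the score
#' test needs (residuals, working weights, projection pieces).
#'
#' @param status 0/1 vector.
#' @param covars Covariate matrix or data.frame (an intercept is added).
#' @return An object of class `null_model`.
#' @export
fit_null_model <- function(status, covars = NULL) {
  ok <- !is.na(status)
  y <- status[ok]
  stopifnot(all(y %in% c(0L, 1L)), sum(y) >= 1, sum(1 - y) >= 1)
  X <- if (is.null(covars)) matrix(1, length(y), 1) else {
    Xm <- as.matrix(covars)[ok, , drop = FALSE]
    cbind(`(Intercept)` = 1, Xm)
  }
  if (qr(X)$rank < ncol(X)) stop("fit_null_model: covariate matrix not full rank")
  fit <- glm.fit(X, y, family = binomial())
  mu <- fit$fitted.values
  W <- mu * (1 - mu)
  XW <- X * W
  XtWX_inv <- solve(crossprod(X, XW))
  structure(list(y = y, mu = mu, resid = y - mu, W = W, X = X, XW = XW,
                 XtWX_inv = XtWX_inv, keep = which(ok), n = length(y)),
            class = "null_model")
}

#' Logistic score test for a single variant
#'
#' Score `U = g'(y - mu)`, variance
#' `V = g'Wg - g'WX (X'WX)^{-1} X'Wg` from the null fit; `z = U/sqrt(V)`,
#' `beta = U/V` (the one-step score-scale log-odds effect),
#' `se = 1/sqrt(V)`.  Missing dosages are dropped (complete-case for the
#' variant, with the score recomputed on the subset).  Degenerate
#' dosages yield a flagged record with missing p, never a silent value.
#'
#' @param dosage Numeric dosage vector in `{0, 1, 2, NA}`.
#' @param null_model A [fit_null_model()] object (alternatively pass
#'   `status` + `covars` to fit on the fly).
#' @param status,covars Used only when `null_model` is `NULL`.
#' @param spa Apply a saddlepoint correction to the score p-value
#'   (useful under strong case-control imbalance).
#' @param id Variant identifier copied into the record.
#' @return A one-row `data.table` summary-statistic record: `id`,
#'   `freq` (effect/alt allele), `mac`, `b`, `se`, `z`, `p`, `n`,
#'   `flag` (`"ok"`, `"zero_variance"`, or `"separation"`).
#' @export
single_variant_test <- function(dosage, null_model = NULL, status = NULL,
                                covars = NULL, spa = FALSE, id = NA_character_) {
  if (is.null(null_model)) null_model <- fit_null_model(status, covars)
  nm <- null_model
  g <- as.numeric(dosage)[nm$keep]
  ok <- !is.na(g)
  flagged <- function(flag, freq = NA_real_, mac = NA_integer_, n = NA_integer_) {
    data.table(id = id, freq = freq, mac = mac, b = NA_real_, se = NA_real_,
               z = NA_real_, p = NA_real_, n = n, flag = flag)
  }
  n_eff <- sum(ok)
  if (n_eff < 2L) return(flagged("zero_variance"))
  freq <- mean(g[ok]) / 2
  mac <- .minor_allele_count(g[ok])
  if (var(g[ok]) == 0) {
    return(flagged("zero_variance", freq = freq, mac = mac, n = n_eff))
  }
  if (all(ok)) {
    U <- sum(g * nm$resid)
    gW <- g * nm$W
    xc <- crossprod(nm$X, gW)                   # X'Wg
    V <- sum(gW * g) - as.numeric(crossprod(xc, nm$XtWX_inv %*% xc))
  } else {
    # complete-case refit of the projection for this variant
    ys <- nm$y[ok]
    if (sum(ys) < 1 || sum(1 - ys) < 1) return(flagged("separation"))
    Xs <- nm$X[ok, , drop = FALSE]
    fit <- glm.fit(Xs, ys, family = binomial())
    mu <- fit$fitted.values
    W <- mu * (1 - mu)
    gs <- g[ok]
    U <- sum(gs * (ys - mu))
    gW <- gs * W
    xc <- crossprod(Xs, gW)
    V <- sum(gW * gs) -
      as.numeric(crossprod(xc, solve(crossprod(Xs, Xs * W), xc)))
  }
  if (!is.finite(V) || V <= 0) return(flagged("separation", freq, mac, n_eff))
  zstat <- U / sqrt(V)
  pval <- 2 * pnorm(-abs(zstat))
  if (spa) {
    ps <- .spa_pvalue(g[ok], if (all(ok)) nm$mu else mu, U)
    if (is.finite(ps)) {
      pval <- ps
      zstat <- sign(U) * qnorm(pval / 2, lower.tail = FALSE)
    }
  }
  data.table(id = id, freq = freq, mac = mac,
             b = U / V, se = 1 / sqrt(V), z = zstat,
             p = max(pval, 1e-300), n = n_eff, flag = "ok")
}

# saddlepoint p-value for the score U = sum g_i (y_i - mu_i) with
# y_i ~ Bernoulli(mu_i) (fastSPA-style, covariates through mu only)
.spa_pvalue <- function(g, mu, U) {
  nz <- g != 0
  g <- g[nz]; mu <- mu[nz]
  K <- function(t) sum(log(1 - mu + mu * exp(t * g))) - t * sum(g * mu)
  K1 <- function(t) {
    e <- mu * exp(t * g)
    sum(g * e / (1 - mu + e)) - sum(g * mu)
  }
  K2 <- function(t) {
    e <- mu * exp(t * g)
    p1 <- e / (1 - mu + e)
    sum(g^2 * p1 * (1 - p1))
  }
  tail_p <- function(q) {
    root <- tryCatch(uniroot(function(t) K1(t) - q, c(-50, 50),
                             tol = 1e-10, extendInt = "yes"),
                     error = function(e) NULL)
    if (is.null(root)) return(NA_real_)
    zeta <- root$root
    if (abs(zeta) < 1e-5) return(NA_real_)
    w <- sign(zeta) * sqrt(max(2 * (zeta * q - K(zeta)), 0))
    v <- zeta * sqrt(K2(zeta))
    pnorm(w + log(v / w) / w, lower.tail = (q < 0))
  }
  p1 <- tail_p(abs(U)); p2 <- tail_p(-abs(U))
  if (is.na(p1) || is.na(p2)) return(NA_real_)
  min(p1 + p2, 1)
}

#' Exome-wide association scan
#'
#' Applies [qc_filter()] then the vectorized logistic score test to all
#' variants for one binary trait.
#'
#' @param geno Dosage matrix (individuals x variants, named columns).
#' @param status 0/1 phenotype vector, aligned to `geno` rows.
#' @param covars Covariate matrix/data.frame.
#' @param qc A [qc_config()], or `NULL` to skip filtering.
#' @param spa Saddlepoint-correct the per-variant p-values.
#' @return A `data.table` of summary-statistic records (one per
#'   surviving variant): `id`, `freq`, `mac`, `b`, `se`, `z`, `p`, `n`,
#'   `flag`.
#' @export
ewas <- function(geno, status, covars = NULL, qc = qc_config(), spa = FALSE) {
  stopifnot(is.matrix(geno), length(status) == nrow(geno))
  if (!is.null(qc)) geno <- qc_filter(geno, qc)
  if (ncol(geno) == 0L) {
    return(data.table(id = character(0), freq = numeric(0), mac = integer(0),
                      b = numeric(0), se = numeric(0), z = numeric(0),
                      p = numeric(0), n = integer(0), flag = character(0)))
  }
  nm <- fit_null_model(status, covars)
  has_na <- colSums(is.na(geno)) > 0L
  out <- vector("list", 2L)
  if (any(!has_na) && !spa) {
    out[[1]] <- score_scan(geno[, !has_na, drop = FALSE], nm)
  } else if (any(!has_na)) {
    cols <- which(!has_na)
    out[[1]] <- rbindlist(lapply(cols, function(j)
      single_variant_test(geno[, j], nm, spa = spa, id = colnames(geno)[j])))
  }
  if (any(has_na)) {
    cols <- which(has_na)
    out[[2]] <- rbindlist(lapply(cols, function(j)
      single_variant_test(geno[, j], nm, spa = spa, id = colnames(geno)[j])))
  }
  res <- rbindlist(out[!vapply(out, is.null, logical(1))])
  res[match(colnames(geno), res$id)]
}

#' Vectorized logistic score scan against a prebuilt null model
#'
#' Fast path for complete (no-missing) dosage matrices: all per-variant
#' scores and variances in a handful of matrix products.  Used by
#' [ewas()] internally and directly by large simulation studies where
#' the same null model is reused across many variant blocks.
#'
#' @param geno Complete dosage matrix (individuals x variants).
#' @param null_model A [fit_null_model()] object for the same
#'   individuals.
#' @return A summary-statistic `data.table` (same columns as [ewas()]).
#' @export
score_scan <- function(geno, null_model) {
  nm <- null_model
  G <- geno[nm$keep, , drop = FALSE]
  storage.mode(G) <- "double"
  U <- as.numeric(crossprod(G, nm$resid))
  C <- crossprod(nm$XW, G)                       # p x m
  V <- colSums(nm$W * G^2) - colSums(C * (nm$XtWX_inv %*% C))
  cs <- colSums(G)
  freq <- cs / (2 * nrow(G))
  mac <- as.integer(round(pmin(cs, 2 * nrow(G) - cs)))
  bad <- !is.finite(V) | V <= 1e-12 | mac == 0L
  zstat <- ifelse(bad, NA_real_, U / sqrt(V))
  data.table(
    id = colnames(G), freq = freq, mac = mac,
    b = ifelse(bad, NA_real_, U / V),
    se = ifelse(bad, NA_real_, 1 / sqrt(V)),
    z = zstat,
    p = ifelse(bad, NA_real_, pmax(2 * pnorm(-abs(zstat)), 1e-300)),
    n = nrow(G),
    flag = ifelse(bad, "zero_variance", "ok"))
}

#' Collapse ultra-rare variants into a single pseudo-variant
#'
#' Dominance-style recoding across a set of collapsing variants:
#' individuals homozygous for the rare allele at one or more variants
#' are coded 2, heterozygous carriers 1, non-carriers 0 (missing at
#' every variant gives `NA`).  The recoding is idempotent and
#' order-independent.
#'
#' @param geno Dosage matrix restricted to the collapsing variants
#'   (minor-allele dosage in `{0, 1, 2, NA}`).
#' @return Integer pseudo-dosage vector, one entry per individual.
#' @export
collapse_ultra_rare <- function(geno) {
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = 1L)
  if (ncol(geno) == 0L) stop("collapse_ultra_rare: empty variant set")
  all_na <- rowSums(!is.na(geno)) == 0L
  g <- geno
  g[is.na(g)] <- 0L
  out <- as.integer(apply(g, 1L, max))
  out[all_na] <- NA_integer_
  out
}
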