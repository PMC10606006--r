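# Null tail probabilities for quadratic forms in normal variables,
# Q = sum_k lambda_k chi^2_1.  These arise as the null law of every
# variance-component statistic in the gene tests (SKAT, SKAT-O kernels).
#
# Primary route is Imhof's exact characteristic-function inversion,
# integrated with stats::integrate.  Two fallbacks are kept: the Liu
# et al. four-moment chi-square approximation (also used to invert
# quantiles inside SKAT-O), and the Kuonen saddlepoint approximation,
# which is preferred in the far right tail where oscillatory
# integration loses relative accuracy.

#' Upper tail probability of a weighted sum of 1-df chi-squares
#'
#' Computes `P(Q > q)` where `Q = sum(lambda * X_k)` with independent
#' `X_k ~ chi^2_1`.  This is the null distribution of the quadratic-form
#' statistics used by [skat()] and [skat_o()].
#'
#' @param q Observed statistic (scalar).
#' @param lambda Numeric vector of non-negative kernel eigenvalues
#'   (eigenvalues below `max(lambda) * 1e-12` are dropped).
#' @param method `"auto"` (Imhof with saddlepoint refinement in the far
#'   tail and Liu as last resort), or one of `"imhof"`, `"saddlepoint"`,
#'   `"liu"` to force a route.
#' @return A p-value in `(0, 1]`.  The chosen route is recorded in the
#'   `"method"` attribute.
#' @export
quadform_pvalue <- function(q, lambda, method = c("auto", "imhof", "saddlepoint", "liu")) {
  method <- match.arg(method)
  stopifnot(is.numeric(q), length(q) == 1L, is.finite(q), is.numeric(lambda))
  lambda <- lambda[is.finite(lambda)]
  if (!length(lambda) || max(lambda) <= 0) {
    stop("quadform_pvalue: no positive eigenvalues")
  }
  lambda <- lambda[lambda > max(lambda) * 1e-12]
  if (q <= 0) {
    return(structure(1, method = "degenerate"))
  }
  if (length(lambda) == 1L) {
    p <- pchisq(q / lambda, df = 1, lower.tail = FALSE)
    return(structure(max(p, 1e-300), method = "exact"))
  }
  if (method == "liu") {
    return(structure(.liu_pvalue(q, lambda), method = "liu"))
  }
  if (method == "saddlepoint") {
    return(structure(.saddlepoint_pvalue(q, lambda), method = "saddlepoint"))
  }
  if (method == "imhof") {
    p <- .imhof_pvalue(q, lambda, tail_tol = 1e-10)
    return(structure(min(max(p, 1e-300), 1), method = "imhof"))
  }
  # auto: a Liu pre-estimate routes moderate p to Imhof (absolute
  # truncation error far below p) and the tail to the saddlepoint,
  # whose relative accuracy does not degrade as p -> 0.
  p_liu <- .liu_pvalue(q, lambda)
  if (p_liu >= 5e-4) {
    # absolute accuracy only needs to be a small fraction of p itself
    p <- tryCatch(.imhof_pvalue(q, lambda,
                                tail_tol = max(1e-9, 1e-4 * p_liu)),
                  error = function(e) NA_real_)
    used <- "imhof"
  } else {
    p <- .saddlepoint_pvalue(q, lambda)
    used <- "saddlepoint"
  }
  if (is.na(p) || p <= 0 || p > 1) {
    ps <- .saddlepoint_pvalue(q, lambda)
    if (is.finite(ps) && ps > 0 && ps <= 1) {
      p <- ps
      used <- "saddlepoint"
    } else {
      p <- p_liu
      used <- "liu"
    }
  }
  structure(min(max(p, 1e-300), 1), method = used)
}

.imhof_pvalue <- function(q, lambda, rel.tol = 1e-6, tail_tol = 1e-8) {
  integrand <- function(u) {
    lu <- outer(lambda, u)                      # m x length(u)
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
    logrho <- 0.25 * colSums(log1p(lu^2))
    out <- sin(theta) / (u * exp(logrho))
    out[u == 0] <- 0.5 * (sum(lambda) - q)      # limit at u -> 0
    out
  }
  # The oscillatory tail defeats adaptive quadrature on (0, Inf); cut at
  # a point where the monotone envelope 1/(u rho(u)) makes the remaining
  # tail negligible, then integrate the finite range.
  # truncation point: the remaining tail of the monotone envelope
  # 1/(u rho(u)) integrates to roughly envelope(U) * U / (m/2)
  m2 <- length(lambda) / 2
  envelope <- function(u) 1 / (u * exp(0.25 * sum(log1p(lambda^2 * u^2))))
  upper <- 10
  while (upper < 1e5 && envelope(upper) * upper / m2 > tail_tol * pi) {
    upper <- upper * 2
  }
  it <- integrate(integrand, lower = 0, upper = upper,
                  rel.tol = rel.tol, abs.tol = tail_tol,
                  subdivisions = 1000L, stop.on.error = FALSE)
  # the truncated tail is below the tolerance, so a subdivision-capped
  # result is still usable; only genuine failures are rejected
  accepted <- c("OK", "roundoff error was detected",
                "maximum number of subdivisions reached")
  if (!it$message %in% accepted) {
    # a spurious divergence flag from heavy oscillation: retry once with
    # a shorter range and looser tolerance before giving up
    it <- integrate(integrand, lower = 0, upper = min(upper, 2000),
                    rel.tol = 1e-5, abs.tol = 1e-6,
                    subdivisions = 1000L, stop.on.error = FALSE)
    if (!it$message %in% accepted) {
      stop("imhof integration failed: ", it$message)
    }
  }
  0.5 + it$value / pi
}

# Kuonen (1999) saddlepoint approximation via the Lugannani-Rice formula.
.saddlepoint_pvalue <- function(q, lambda) {
  mu <- sum(lambda)
  if (abs(q - mu) < 1e-10 * mu) return(0.5)
  K <- function(t) -0.5 * sum(log1p(-2 * t * lambda))
  K1 <- function(t) sum(lambda / (1 - 2 * t * lambda))
  K2 <- function(t) 2 * sum(lambda^2 / (1 - 2 * t * lambda)^2)
  tmax <- 1 / (2 * max(lambda)) * (1 - 1e-10)
  root <- tryCatch(
    uniroot(function(t) K1(t) - q, lower = -1e4, upper = tmax,
            tol = .Machine$double.eps^0.5, extendInt = "no"),
    error = function(e) NULL)
  if (is.null(root)) return(NA_real_)
  zeta <- root$root
  w <- sign(zeta) * sqrt(max(2 * (zeta * q - K(zeta)), 0))
  v <- zeta * sqrt(K2(zeta))
  if (abs(zeta) < 1e-8 || w == 0) return(0.5)
  pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

# Liu et al. (2009) moment-matched noncentral chi-square approximation.
.liu_parameters <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  list(c1 = c1, c2 = c2, l = l, d = d, mux = l + d, sigx = sqrt(2) * a)
}

.liu_pvalue <- function(q, lambda) {
  pp <- .liu_parameters(lambda)
  tstar <- (q - pp$c1) / sqrt(2 * pp$c2)
  max(pchisq(tstar * pp$sigx + pp$mux, df = pp$l, ncp = pp$d,
             lower.tail = FALSE), 1e-300)
}

# Upper-tail quantile of the Liu approximation; used by SKAT-O to turn
# the minimum p over the rho grid back into per-rho statistic quantiles.
.liu_quantile <- function(p, lambda) {
  pp <- .liu_parameters(lambda)
  xstar <- qchisq(p, df = pp$l, ncp = pp$d, lower.tail = FALSE)
  pp$c1 + (xstar - pp$mux) / pp$sigx * sqrt(2 * pp$c2)
}
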