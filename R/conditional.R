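# Approximate conditional analysis from summary statistics, in the
# manner of conditional-and-joint (COJO) selection: stepwise index
# variant selection in a window around the gene, then conditional
# re-scoring of the in-gene variants on the selected variants that lie
# outside the gene.  All arithmetic is on the standardized-genotype
# scale, where the marginal effect is b* = z / sqrt(2 f (1-f) (n + z^2))
# and conditioning reduces to LD algebra on z.

#' Conditional-analysis configuration
#'
#' @param window Distance in bp beyond the gene borders searched for
#'   index variants (default 1 Mb).
#' @param r2_cutoff Collinearity guard: candidates with `r^2` above this
#'   value to any selected variant are skipped (default 0.9).
#' @param ridge Ridge added to the conditioning LD block if it is
#'   ill-conditioned.
#' @return An object of class `conditional_config`.
#' @export
conditional_config <- function(window = 1e6, r2_cutoff = 0.9, ridge = 1e-6) {
  stopifnot(window > 0, r2_cutoff > 0, r2_cutoff < 1)
  structure(list(window = window, r2_cutoff = r2_cutoff, ridge = ridge),
            class = "conditional_config")
}

#' Standardized-scale effect from a summary-statistic record
#'
#' `b* = z / sqrt(2 f (1 - f) (n + z^2))`, the per-SD effect implied by
#' the z-score and allele frequency; its standard error is `b*/z`.
#'
#' @param z z-score. @param freq Effect-allele frequency. @param n Sample size.
#' @return Numeric vector of standardized effects.
#' @export
standardized_beta <- function(z, freq, n) {
  z / sqrt(2 * freq * (1 - freq) * (n + z^2))
}

#' Stepwise selection of index variants in a window
#'
#' Seeds with the window's minimum-p variant if it passes `p_threshold`,
#' then repeatedly adds the variant with the smallest conditional
#' p-value below the threshold, skipping candidates whose `r^2` with any
#' selected variant exceeds the collinearity cutoff.  Ties are broken by
#' position, then id.
#'
#' @param sumstats Summary statistics for the window variants (`id`,
#'   `z`, `p`, `pos` column or a `panel` lookup).
#' @param ld An [compute_ld()] object or correlation matrix covering the
#'   window variants (ids must match).
#' @param p_threshold Selection threshold (the pipeline uses the
#'   minimum p within the gene being conditioned).
#' @param cfg A [conditional_config()].
#' @param pos Optional named vector of positions for tie-breaking.
#' @return Character vector of selected index variant ids (possibly
#'   empty).
#' @export
cojo_select <- function(sumstats, ld, p_threshold, cfg = conditional_config(),
                        pos = NULL) {
  ss <- as.data.table(sumstats)
  R <- if (inherits(ld, "ld_matrix")) ld$R else ld
  ids <- if (inherits(ld, "ld_matrix")) ld$ids else colnames(R)
  ss <- ss[id %in% ids & is.finite(z)]
  if (!nrow(ss)) stop("cojo_select: no overlap between sumstats and LD ids")
  if (is.null(pos)) {
    pos <- if ("pos" %in% names(ss)) setNames(ss$pos, ss$id) else
      setNames(seq_len(nrow(ss)), ss$id)
  }
  # deterministic candidate order: p, then position, then id
  setorderv(ss, "id")
  R <- R[ss$id, ss$id, drop = FALSE]
  zvec <- setNames(ss$z, ss$id)
  selected <- character(0)
  repeat {
    cand <- setdiff(ss$id, selected)
    if (!length(cand)) break
    if (length(selected)) {
      keep <- vapply(cand, function(v)
        max(R[v, selected]^2) <= cfg$r2_cutoff, logical(1))
      cand <- cand[keep]
      if (!length(cand)) break
      zc <- vapply(cand, function(v) {
        .conditional_z(zvec[v], zvec[selected],
                       R[v, selected, drop = FALSE],
                       R[selected, selected, drop = FALSE], cfg$ridge)
      }, numeric(1))
    } else {
      zc <- zvec[cand]
    }
    pc <- 2 * pnorm(-abs(zc))
    ord <- order(pc, pos[cand], cand)
    best <- cand[ord[1]]
    if (pc[match(best, cand)] > p_threshold) break
    selected <- c(selected, best)
  }
  selected
}

.conditional_z <- function(z_t, z_c, R_tc, R_cc, ridge = 1e-6) {
  R_cc <- as.matrix(R_cc)
  sol <- tryCatch(solve(R_cc, as.numeric(z_c)), error = function(e) NULL)
  hsol <- tryCatch(solve(R_cc, as.numeric(R_tc)), error = function(e) NULL)
  if (is.null(sol) || is.null(hsol)) {
    R_cc <- R_cc + diag(ridge, nrow(R_cc))
    sol <- solve(R_cc, as.numeric(z_c))
    hsol <- solve(R_cc, as.numeric(R_tc))
  }
  h <- as.numeric(R_tc %*% hsol)
  if (h >= 1 - 1e-10) return(0)
  (z_t - as.numeric(R_tc %*% sol)) / sqrt(1 - h)
}

#' Conditional summary statistics for target variants
#'
#' Joint-model re-scoring of each target on the conditioning set using
#' LD: on the standardized scale
#' `b_cond = (b_t - R_tc R_cc^{-1} b_c) / (1 - R_tc R_cc^{-1} R_ct)` and
#' `z_cond = (z_t - R_tc R_cc^{-1} z_c) / sqrt(1 - R_tc R_cc^{-1} R_ct)`.
#' An empty conditioning set returns the marginal statistics unchanged;
#' a target inside the conditioning set gets conditional beta 0 and
#' p 1.
#'
#' @param targets Ids of the variants to re-score.
#' @param conditioning Ids of the conditioning variants (may be empty).
#' @param ld LD matrix object or correlation matrix covering both sets.
#' @param sumstats Summary statistics containing all involved ids
#'   (`id`, `freq`, `z`, `n`).
#' @param cfg A [conditional_config()].
#' @return `data.table` with `id`, `freq`, `b_marg`, `z_marg`, `p_marg`,
#'   `b_cond`, `se_cond`, `z_cond`, `p_cond` (standardized scale).
#' @export
conditional_summary <- function(targets, conditioning, ld, sumstats,
                                cfg = conditional_config()) {
  ss <- as.data.table(sumstats)
  R <- if (inherits(ld, "ld_matrix")) ld$R else ld
  stopifnot(all(targets %in% ss$id), all(conditioning %in% ss$id))
  need <- union(targets, conditioning)
  if (!all(need %in% colnames(R))) {
    stop("conditional_summary: LD matrix does not cover all required variants")
  }
  tt <- ss[match(targets, id)]
  bstar <- standardized_beta(tt$z, tt$freq, tt$n)
  out <- data.table(id = targets, freq = tt$freq,
                    b_marg = bstar, z_marg = tt$z,
                    p_marg = pmax(2 * pnorm(-abs(tt$z)), 1e-300))
  if (!length(conditioning)) {
    out[, `:=`(b_cond = b_marg, se_cond = b_marg / z_marg,
               z_cond = z_marg, p_cond = p_marg)]
    return(out[])
  }
  cc <- ss[match(conditioning, id)]
  z_c <- cc$z
  R_cc <- R[conditioning, conditioning, drop = FALSE]
  z_cond <- b_cond <- se_cond <- numeric(length(targets))
  for (i in seq_along(targets)) {
    v <- targets[i]
    if (v %in% conditioning) {
      z_cond[i] <- 0; b_cond[i] <- 0; se_cond[i] <- NA_real_
      next
    }
    R_tc <- R[v, conditioning, drop = FALSE]
    zci <- .conditional_z(out$z_marg[i], z_c, R_tc, R_cc, cfg$ridge)
    z_cond[i] <- zci
    n_i <- tt$n[i]
    se_cond[i] <- 1 / sqrt(2 * out$freq[i] * (1 - out$freq[i]) *
                             (n_i + zci^2))
    b_cond[i] <- zci * se_cond[i]
  }
  out[, `:=`(b_cond = b_cond, se_cond = se_cond, z_cond = z_cond,
             p_cond = pmax(2 * pnorm(-abs(z_cond)), 1e-300))]
  out[]
}

#' Conditional gene-based test
#'
#' Runs the COJO-style selection in the gene's +/- window, conditions
#' the in-gene mask variants on the selected variants lying outside the
#' gene, and re-runs the gene-test battery on the conditional z-scores
#' (with the gene's own LD matrix).  With an empty conditioning set the
#' conditional results equal the marginal results exactly.
#'
#' @param gene_ids In-gene (mask) variant ids, aligned with `w`.
#' @param region `c(start, end)` of the gene (1-based inclusive).
#' @param sumstats Window summary statistics (`id`, `pos`, `freq`, `z`,
#'   `p`, `n`).
#' @param ld LD over the window variants (must cover gene + selected).
#' @param w Per-variant weights for the gene test.
#' @param cfg A [conditional_config()].
#' @param test_cfg A [gene_test_config()].
#' @return List with `conditioning` (selected external ids),
#'   `conditional` (per-variant [conditional_summary()] table),
#'   `marginal_test`, `conditional_test` (one-row [gene_test()]
#'   tables).
#' @export
conditional_gene_test <- function(gene_ids, region, sumstats, ld, w = NULL,
                                  cfg = conditional_config(),
                                  test_cfg = gene_test_config()) {
  ss <- as.data.table(sumstats)
  stopifnot(all(c("id", "pos", "z", "n", "freq") %in% names(ss)),
            all(gene_ids %in% ss$id))
  R <- if (inherits(ld, "ld_matrix")) ld$R else ld
  win <- ss[pos >= region[1] - cfg$window & pos <= region[2] + cfg$window &
              id %in% colnames(R)]
  p_threshold <- min(ss[id %in% gene_ids, pmax(2 * pnorm(-abs(z)), 1e-300)])
  sel <- cojo_select(win, R[win$id, win$id, drop = FALSE], p_threshold, cfg,
                     pos = setNames(win$pos, win$id))
  external <- setdiff(sel, ss[pos >= region[1] & pos <= region[2], id])
  cond <- conditional_summary(gene_ids, external, R, ss, cfg)
  Rg <- R[gene_ids, gene_ids, drop = FALSE]
  marg <- gene_test(cond$z_marg, w, Rg, test_cfg)
  cond_test <- if (!length(external)) copy(marg) else
    gene_test(cond$z_cond, w, Rg, test_cfg)
  list(conditioning = external, conditional = cond,
       marginal_test = marg, conditional_test = cond_test)
}
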