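# End-to-end orchestration: simulate (or load) a cohort, run the
# per-trait EWAS, build the SGIT summary statistics, test every gene
# under the four annotation masks (plus the LoF burden), and send
# significant genes through the conditional stage.

#' Bonferroni significance and suggestive thresholds
#'
#' `significant = alpha / n_genes`; `suggestive = 10 * significant`.
#' With the conventional 20,000 genes and `alpha = 0.05` this gives
#' `2.5e-6` and `2.5e-5`.
#'
#' @param n_genes Number of genes assumed tested (default 20000).
#' @param alpha Family-wise error rate (default 0.05).
#' @return Named list with `significant` and `suggestive`.
#' @export
significance_thresholds <- function(n_genes = 20000L, alpha = 0.05) {
  stopifnot(n_genes >= 1, alpha > 0, alpha < 1)
  sig <- alpha / n_genes
  list(significant = sig, suggestive = 10 * sig)
}

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic cohort (or
#'   `NULL` when a cohort is supplied to [run_pipeline()] directly).
#' @param qc A [qc_config()].
#' @param gene_cfg A [gene_test_config()].
#' @param cond_cfg A [conditional_config()].
#' @param masks Annotation masks to test (default all four).
#' @param n_genes_bonferroni Gene count used for the Bonferroni
#'   thresholds (default 20000, the fixed convention; set
#'   `bonferroni_observed = TRUE` to use the observed gene count
#'   instead).
#' @param alpha Family-wise error rate.
#' @param bonferroni_observed Use the observed number of genes for the
#'   thresholds instead of `n_genes_bonferroni`.
#' @param conditional Run the conditional stage on significant genes.
#' @param pheno_corr_truncation |z| threshold for the null-variant
#'   phenotypic-correlation estimator.
#' @param out_dir Optional directory where all stage outputs are
#'   persisted as TSV/.ma files.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), qc = qc_config(),
                            gene_cfg = gene_test_config(),
                            cond_cfg = conditional_config(),
                            masks = mask_names(),
                            n_genes_bonferroni = 20000L, alpha = 0.05,
                            bonferroni_observed = FALSE,
                            conditional = TRUE,
                            pheno_corr_truncation = 2,
                            out_dir = NULL) {
  stopifnot(all(masks %in% mask_names()), alpha > 0, alpha < 1)
  structure(list(sim = sim, qc = qc, gene_cfg = gene_cfg,
                 cond_cfg = cond_cfg, masks = masks,
                 n_genes_bonferroni = as.integer(n_genes_bonferroni),
                 alpha = alpha, bonferroni_observed = bonferroni_observed,
                 conditional = conditional,
                 pheno_corr_truncation = pheno_corr_truncation,
                 out_dir = out_dir),
            class = "pipeline_config")
}

.config_hash <- function(cfg) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}

.covar_matrix <- function(phenotypes) {
  ph <- as.data.table(phenotypes)
  cols <- intersect(c("sex", "age", "batch", paste0("PC", 1:10)), names(ph))
  as.matrix(ph[, ..cols])
}

# Per-gene, per-mask test inputs: individually testable variants plus
# the collapsed ultra-rare pseudo-variant, with z per trait and SGIT.
.prepare_mask <- function(gene_id, mask_name, panel, geno, sumstats_list,
                          null_models, a_weights, gene_cfg) {
  ss1 <- sumstats_list[[1]]
  mk <- build_mask(panel, gene_id, mask_name, ss1, gene_cfg)
  if (is.null(mk)) return(NULL)
  ids <- mk$test_ids
  K <- length(sumstats_list)
  pseudo <- NULL
  if (length(mk$collapse_ids)) {
    pd <- collapse_ultra_rare(geno[, mk$collapse_ids, drop = FALSE])
    zc <- vapply(seq_len(K), function(k) {
      rec <- single_variant_test(pd, null_models[[k]],
                                 id = paste0(gene_id, "_", mask_name, "_collapsed"))
      rec$z
    }, numeric(1))
    if (all(is.finite(zc))) {
      pseudo <- list(dosage = pd, z = zc,
                     z_sgit = sum(a_weights * zc),
                     weight = mk$collapse_weight)
    }
  }
  m_real <- length(ids)
  m_tot <- m_real + as.integer(!is.null(pseudo))
  if (m_tot < 1L) return(NULL)
  zmat <- matrix(NA_real_, m_tot, K)
  if (m_real) {
    for (k in seq_len(K)) {
      zmat[seq_len(m_real), k] <- sumstats_list[[k]]$z[match(ids, sumstats_list[[k]]$id)]
    }
  }
  w <- mk$weights
  dos <- geno[, ids, drop = FALSE]
  if (!is.null(pseudo)) {
    zmat[m_tot, ] <- pseudo$z
    w <- c(w, pseudo$weight)
    dos <- cbind(dos, pseudo$dosage)
    colnames(dos)[m_tot] <- paste0(gene_id, "_", mask_name, "_collapsed")
  }
  z_sgit <- as.numeric(zmat %*% a_weights)
  keep <- rowSums(!is.finite(zmat)) == 0L
  if (!any(keep)) return(NULL)
  list(ids = colnames(dos)[keep], z = zmat[keep, , drop = FALSE],
       z_sgit = z_sgit[keep], w = w[keep],
       dosage = dos[, keep, drop = FALSE],
       n_collapsed = length(mk$collapse_ids))
}

.mask_ld <- function(prep, gene_cfg) {
  m <- length(prep$ids)
  if (m == 1L) return(matrix(1, 1, 1, dimnames = list(prep$ids, prep$ids)))
  # LD filters apply to the real variants; the collapsed pseudo-variant
  # is always retained (it is the whole point of the collapsing path)
  keep <- vapply(seq_len(m), function(j) {
    x <- prep$dosage[, j]
    grepl("_collapsed$", prep$ids[j]) ||
      (mean(is.na(x)) <= gene_cfg$ld_miss_max &&
         .minor_allele_count(x) >= gene_cfg$ld_mac_min)
  }, logical(1))
  if (sum(keep) < 2L) keep <- rep(TRUE, m)
  R <- suppressWarnings(cor(prep$dosage[, keep, drop = FALSE],
                            use = "pairwise.complete.obs"))
  if (anyNA(R)) R[is.na(R)] <- 0
  diag(R) <- 1
  R <- .psd_regularize(R, gene_cfg$eig_floor)
  dimnames(R) <- list(prep$ids[keep], prep$ids[keep])
  attr(R, "keep") <- keep
  R
}

#' Run all gene-based tests for a cohort
#'
#' For every gene x mask x trait (the K original traits plus the SGIT
#' combination): collapse the mask's ultra-rare variants, assemble
#' `z`/`w`/`R`, and run the test battery; the per-gene LoF burden
#' (all LoF variants collapsed into one pseudo-variant, single-variant
#' tested) is computed alongside.
#'
#' @param cohort List with `panel`, `geno` (QC'd), `phenotypes`.
#' @param sumstats_list Named per-trait summary statistics ([ewas()]).
#' @param sgit_ss SGIT summary statistics ([sgit_summary_stats()]).
#' @param weights An `sgit_weights` object.
#' @param gene_cfg A [gene_test_config()].
#' @param masks Masks to test.
#' @return List with `results` (gene x trait x mask `data.table`),
#'   `lof_burden` (gene x trait), `skipped` (gene/mask skip reasons),
#'   and `mask_inputs` (per gene/mask prepared inputs, for the
#'   conditional stage).
#' @export
run_gene_tests <- function(cohort, sumstats_list, sgit_ss, weights,
                           gene_cfg = gene_test_config(),
                           masks = mask_names()) {
  panel <- as.data.table(cohort$panel)
  geno <- cohort$geno
  traits <- names(sumstats_list)
  K <- length(traits)
  covars <- .covar_matrix(cohort$phenotypes)
  null_models <- lapply(traits, function(tr)
    fit_null_model(cohort$phenotypes[[tr]], covars))
  names(null_models) <- traits
  a <- weights$a
  genes <- unique(panel$gene[!is.na(panel$gene)])
  res <- list(); skipped <- list(); lofb <- list(); inputs <- list()
  for (g in genes) {
    for (mk in masks) {
      prep <- .prepare_mask(g, mk, panel, geno, sumstats_list, null_models,
                            a, gene_cfg)
      if (is.null(prep)) {
        skipped[[length(skipped) + 1L]] <- data.table(
          gene = g, mask = mk, reason = "no testable variants")
        next
      }
      R <- .mask_ld(prep, gene_cfg)
      keep <- attr(R, "keep") %||% rep(TRUE, length(prep$ids))
      inputs[[paste(g, mk, sep = "|")]] <- prep
      for (k in seq_len(K + 1L)) {
        zk <- if (k <= K) prep$z[keep, k] else prep$z_sgit[keep]
        tr <- if (k <= K) traits[k] else "SGIT"
        gt <- gene_test(zk, prep$w[keep], R, gene_cfg)
        res[[length(res) + 1L]] <- data.table(gene = g, trait = tr,
                                              mask = mk,
                                              n_collapsed = prep$n_collapsed,
                                              gt)
      }
    }
    # LoF burden: all LoF variants of the gene collapsed into one
    lof_ids <- panel[gene == g &
                       consequence %in% mask_vocabularies$LoF &
                       id %in% colnames(geno), id]
    lof_ids <- intersect(lof_ids,
                         sumstats_list[[1]]$id[sumstats_list[[1]]$freq <= gene_cfg$maf_max])
    if (length(lof_ids)) {
      pd <- collapse_ultra_rare(geno[, lof_ids, drop = FALSE])
      zl <- vapply(seq_len(K), function(k)
        single_variant_test(pd, null_models[[k]], id = paste0(g, "_LoF_burden"))$z,
        numeric(1))
      if (all(is.finite(zl))) {
        zs <- c(zl, sum(a * zl))
        lofb[[length(lofb) + 1L]] <- data.table(
          gene = g, trait = c(traits, "SGIT"), n_lof = length(lof_ids),
          p_lof_burden = pmax(2 * pnorm(-abs(zs)), 1e-300))
      }
    }
  }
  list(results = rbindlist(res),
       lof_burden = if (length(lofb)) rbindlist(lofb) else
         data.table(gene = character(0), trait = character(0),
                    n_lof = integer(0), p_lof_burden = numeric(0)),
       skipped = if (length(skipped)) rbindlist(skipped) else
         data.table(gene = character(0), mask = character(0),
                    reason = character(0)),
       mask_inputs = inputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign significance tiers and sort a result table
#'
#' @param results Gene-test results (needs `gene` and `p_acat_o`).
#' @param thresholds From [significance_thresholds()].
#' @return The table with a `tier` column
#'   (`significant`/`suggestive`/`none`), sorted by each gene's minimum
#'   ACAT-O p.
#' @export
report <- function(results, thresholds = significance_thresholds()) {
  res <- copy(as.data.table(results))
  if (!nrow(res)) {
    res[, tier := character(0)]
    return(res[])
  }
  res[, tier := ifelse(!is.finite(p_acat_o), "none",
                       ifelse(p_acat_o <= thresholds$significant, "significant",
                              ifelse(p_acat_o <= thresholds$suggestive,
                                     "suggestive", "none")))]
  res[, .min_p := min(c(p_acat_o, Inf), na.rm = TRUE), by = gene]
  setorder(res, .min_p, gene, trait, mask)
  res[, .min_p := NULL]
  res[]
}

#' Run the full multi-trait gene-based pipeline
#'
#' Stage 1: per-trait EWAS and SGIT summary statistics (phenotypic
#' correlations estimated from null-variant z-scores; heritabilities and
#' genetic correlations taken from the simulation truth).  Stage 2:
#' gene-based tests for every gene x mask x trait, plus LoF burden.
#' Stage 3: approximate conditional analysis of every gene crossing the
#' significance threshold.  Rerunning with the same config reproduces
#' every number bit-for-bit.
#'
#' @param cfg A [pipeline_config()].
#' @param cohort Optional pre-built cohort (output of
#'   [simulate_cohort()]); by default one is simulated from `cfg$sim`.
#' @return List of class `sgit_pipeline` with elements `report`,
#'   `gene_results`, `lof_burden`, `skipped`, `sumstats` (per trait),
#'   `sgit_sumstats`, `weights`, `trait_panel`, `thresholds`,
#'   `conditional`, `metadata`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cohort)) cohort <- simulate_cohort(cfg$sim)
  sim <- cohort$truth$cfg %||% cfg$sim
  traits <- sim$traits
  covars <- .covar_matrix(cohort$phenotypes)

  geno_qc <- qc_filter(cohort$geno, cfg$qc)
  sumstats <- lapply(traits, function(tr)
    ewas(geno_qc, cohort$phenotypes[[tr]], covars, qc = NULL))
  names(sumstats) <- traits

  zmat <- do.call(cbind, lapply(sumstats, function(s) s$z))
  P <- tryCatch(
    estimate_pheno_corr_from_z(zmat, truncation = cfg$pheno_corr_truncation),
    error = function(e) {
      # small panels: fall back to the direct phenotype correlation
      stats_mat <- as.matrix(as.data.table(cohort$phenotypes)[, ..traits])
      cov2cor(cov(stats_mat))
    })
  dimnames(P) <- list(traits, traits)
  G <- tcrossprod(sim$factor_loadings)
  diag(G) <- 1
  dimnames(G) <- list(traits, traits)
  tp <- trait_panel(traits, sim$h2, G, P)
  wts <- sgit_coefficients(tp, lambda = sim$factor_loadings)
  sgit_ss <- sgit_summary_stats(sumstats, wts, P = tp$P)

  qc_cohort <- list(panel = cohort$panel, geno = geno_qc,
                    phenotypes = cohort$phenotypes)
  gt <- run_gene_tests(qc_cohort, sumstats, sgit_ss, wts,
                       gene_cfg = cfg$gene_cfg, masks = cfg$masks)
  n_bonf <- if (cfg$bonferroni_observed)
    length(unique(gt$results$gene)) else cfg$n_genes_bonferroni
  thr <- significance_thresholds(max(n_bonf, 1L), cfg$alpha)
  rep_tab <- report(gt$results, thr)

  conditional <- NULL
  if (cfg$conditional) {
    conditional <- .conditional_stage(rep_tab, gt, cohort, geno_qc, sumstats,
                                      sgit_ss, thr, cfg)
  } else {
    rep_tab <- copy(rep_tab)
  }

  meta <- list(config_hash = .config_hash(cfg), seed = sim$seed,
               package_version = as.character(utils::packageVersion("sgitrare")),
               n_individuals = nrow(cohort$geno),
               n_variants_qc = ncol(geno_qc),
               n_genes = length(unique(cohort$panel$gene[!is.na(cohort$panel$gene)])))
  out <- list(report = rep_tab, gene_results = gt$results,
              lof_burden = gt$lof_burden, skipped = gt$skipped,
              sumstats = sumstats, sgit_sumstats = sgit_ss, weights = wts,
              trait_panel = tp, thresholds = thr, conditional = conditional,
              metadata = meta)
  class(out) <- "sgit_pipeline"
  if (!is.null(cfg$out_dir)) .persist_pipeline(out, cohort, cfg)
  out
}

.conditional_stage <- function(rep_tab, gt, cohort, geno_qc, sumstats,
                               sgit_ss, thr, cfg) {
  sig <- rep_tab[tier == "significant"]
  if (!nrow(sig)) return(list())
  panel <- as.data.table(cohort$panel)
  regions <- attr(cohort$panel, "gene_regions")
  out <- list()
  for (i in seq_len(nrow(sig))) {
    g <- sig$gene[i]; tr <- sig$trait[i]; mk <- sig$mask[i]
    prep <- gt$mask_inputs[[paste(g, mk, sep = "|")]]
    if (is.null(prep)) next
    real <- !grepl("_collapsed$", prep$ids)
    if (sum(real) < 2L) next        # pseudo-only genes keep marginal stats
    gene_ids <- prep$ids[real]
    reg <- regions[regions$gene == g, ]
    ss_tr <- if (tr == "SGIT") sgit_ss else sumstats[[tr]]
    ss_tr <- as.data.table(ss_tr)
    ss_tr[, pos := panel$pos[match(id, panel$id)]]
    win_ids <- panel[pos >= reg$start - cfg$cond_cfg$window &
                       pos <= reg$end + cfg$cond_cfg$window &
                       id %in% ss_tr$id[is.finite(ss_tr$z)] &
                       id %in% colnames(geno_qc), id]
    if (length(win_ids) < 2L) next
    Rwin <- suppressWarnings(cor(geno_qc[, win_ids, drop = FALSE],
                                 use = "pairwise.complete.obs"))
    Rwin[is.na(Rwin)] <- 0; diag(Rwin) <- 1
    Rwin <- .psd_regularize(Rwin, cfg$gene_cfg$eig_floor)
    dimnames(Rwin) <- list(win_ids, win_ids)
    cres <- conditional_gene_test(
      intersect(gene_ids, win_ids), c(reg$start, reg$end),
      ss_tr[id %in% win_ids], Rwin,
      w = prep$w[real][match(intersect(gene_ids, win_ids), gene_ids)],
      cfg = cfg$cond_cfg, test_cfg = cfg$gene_cfg)
    out[[paste(g, tr, mk, sep = "|")]] <- c(
      list(gene = g, trait = tr, mask = mk), cres)
  }
  out
}

.persist_pipeline <- function(out, cohort, cfg) {
  dir <- cfg$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tr in names(out$sumstats)) {
    write_ma(out$sumstats[[tr]], file.path(dir, paste0("ewas_", tr, ".ma")),
             panel = cohort$panel)
  }
  write_ma(out$sgit_sumstats, file.path(dir, "ewas_SGIT.ma"),
           panel = cohort$panel)
  rep_out <- copy(out$report)
  rep_out[, config_hash := out$metadata$config_hash]
  fwrite(rep_out, file.path(dir, "gene_report.tsv"), sep = "\t")
  fwrite(out$lof_burden, file.path(dir, "lof_burden.tsv"), sep = "\t")
  fwrite(out$skipped, file.path(dir, "skipped_genes.tsv"), sep = "\t")
  write_trait_panel(out$trait_panel, file.path(dir, "trait_panel.yaml"))
  invisible(dir)
}

#' Combine report tables from runs with identical configuration
#'
#' Refuses to combine tables whose recorded `config_hash` columns
#' disagree.
#'
#' @param ... Report `data.table`s carrying a `config_hash` column.
#' @return The row-bound table.
#' @export
combine_reports <- function(...) {
  tabs <- list(...)
  hashes <- unique(unlist(lapply(tabs, function(t) unique(t$config_hash))))
  if (length(hashes) > 1L) {
    stop("combine_reports: refusing to combine outputs with different config hashes")
  }
  rbindlist(tabs)
}
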