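# File interchange.  Genotypes travel as VCF 4.2 (GT field, "./."
# missing; read back through vcfR), phenotypes/covariates and
# annotations as TSV, gene regions as 0-based half-open BED, summary
# statistics in the GCTA-COJO ".ma" dialect
# (SNP A1 A2 freq b se p N) plus extension columns (MAC gene
# consequence), and trait panels as YAML.

#' Write a cohort to plain-text fixture files
#'
#' @param geno Dosage matrix (individuals x variants).
#' @param panel Variant table (needs `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `consequence`; `gene_regions` attribute used for the BED).
#' @param phenotypes Phenotype/covariate `data.table` (first column
#'   `id`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the file paths written
#'   (`vcf`, `phenotypes`, `annotations`, `bed`).
#' @export
write_fixtures <- function(geno, panel, phenotypes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             bed = file.path(dir, "genes.bed"))
  write_genotypes_vcf(geno, panel, paths["vcf"])
  fwrite(as.data.table(phenotypes), paths["phenotypes"], sep = "\t")
  fwrite(as.data.table(panel)[, .(id, gene, consequence)],
         paths["annotations"], sep = "\t")
  regions <- attr(panel, "gene_regions")
  if (!is.null(regions)) {
    bed <- as.data.table(regions)[, .(chrom, start = start - 1L, end, name = gene)]
    fwrite(bed, paths["bed"], sep = "\t", col.names = FALSE)
  }
  invisible(paths)
}

#' Write genotypes as a minimal VCF 4.2 file
#'
#' GT-only records; missing dosage encoded `./.`.
#'
#' @inheritParams write_fixtures
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(geno, panel, path) {
  panel <- as.data.table(panel)
  stopifnot(all(colnames(geno) == panel$id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sgitrare",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno)), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  if (nrow(panel)) {
    body <- vapply(seq_len(nrow(panel)), function(j) {
      g <- geno[, j]
      gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
      paste(c(panel$chrom[j], panel$pos[j], panel$id[j], panel$ref[j],
              panel$alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a GT-only VCF into a dosage matrix
#'
#' @param path VCF path.
#' @return Integer dosage matrix (individuals x variants), `NA` for
#'   `./.`, with a `"sites"` attribute (`data.table` of `id`, `chrom`,
#'   `pos`, `ref`, `alt`).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  sites <- data.table(id = vcfR::getID(v), chrom = vcfR::getCHROM(v),
                      pos = vcfR::getPOS(v), ref = vcfR::getREF(v),
                      alt = vcfR::getALT(v))
  if (nrow(v@gt) == 0L) {
    inds <- colnames(v@gt)[-1]
    G <- matrix(integer(0), nrow = length(inds), ncol = 0,
                dimnames = list(inds, NULL))
    attr(G, "sites") <- sites
    return(G)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), sites$id))
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
            "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  for (j in seq_len(nrow(gt))) dos[, j] <- unname(code[gt[j, ]])
  attr(dos, "sites") <- sites
  dos
}

.ma_core_cols <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")

#' Write summary statistics in the COJO ".ma" dialect
#'
#' Columns `SNP A1 A2 freq b se p N` (bit-exact header names), plus
#' extension columns `MAC`, `gene`, `consequence` when available.  A1 is
#' the effect (alt) allele.
#'
#' @param sumstats Table from [ewas()] or [sgit_summary_stats()].
#' @param path Output path.
#' @param panel Optional variant table supplying alleles/gene/
#'   consequence.
#' @return Invisibly, `path`.
#' @export
write_ma <- function(sumstats, path, panel = NULL) {
  ss <- as.data.table(sumstats)
  out <- data.table(SNP = ss$id, A1 = NA_character_, A2 = NA_character_,
                    freq = ss$freq, b = ss$b, se = ss$se, p = ss$p, N = ss$n)
  out[, MAC := ss$mac]
  if (!is.null(panel)) {
    panel <- as.data.table(panel)
    idx <- match(out$SNP, panel$id)
    out[, `:=`(A1 = panel$alt[idx], A2 = panel$ref[idx],
               gene = panel$gene[idx], consequence = panel$consequence[idx])]
  }
  fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read a COJO ".ma" summary-statistic file
#'
#' @param path File path.
#' @return A `data.table` with the package's internal column names
#'   (`id`, `freq`, `b`, `se`, `p`, `n`, `z`, plus any extension
#'   columns).
#' @export
read_ma <- function(path) {
  ss <- fread(path)
  missing_cols <- setdiff(.ma_core_cols, names(ss))
  if (length(missing_cols)) {
    stop(sprintf("read_ma: %s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  setnames(ss, c("SNP", "N"), c("id", "n"))
  if ("MAC" %in% names(ss)) setnames(ss, "MAC", "mac")
  ss[, z := b / se]
  ss[]
}

#' Read gene regions from a BED file
#'
#' @param path 0-based half-open BED (`chrom start end name`).
#' @return `data.table` with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_gene_bed <- function(path) {
  bed <- fread(path, header = FALSE,
               col.names = c("chrom", "start", "end", "gene")[1:4])
  bed[, .(gene, chrom = as.character(chrom), start = start + 1L, end = end)]
}

#' Write / read a trait panel as YAML
#'
#' @param panel A [trait_panel()].
#' @param path YAML path.
#' @return `write_trait_panel` returns `path` invisibly;
#'   `read_trait_panel` returns a [trait_panel()].
#' @export
write_trait_panel <- function(panel, path) {
  stopifnot(inherits(panel, "trait_panel"))
  yaml::write_yaml(list(traits = panel$traits,
                        h2 = as.numeric(panel$h2),
                        G = lapply(seq_len(nrow(panel$G)), function(i) as.numeric(panel$G[i, ])),
                        P = lapply(seq_len(nrow(panel$P)), function(i) as.numeric(panel$P[i, ]))),
                   path)
  invisible(path)
}

#' @rdname write_trait_panel
#' @export
read_trait_panel <- function(path) {
  y <- yaml::read_yaml(path)
  K <- length(y$traits)
  G <- do.call(rbind, lapply(y$G, as.numeric))
  P <- do.call(rbind, lapply(y$P, as.numeric))
  trait_panel(y$traits, as.numeric(y$h2), G, P)
}
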