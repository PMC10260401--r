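#' Write a simulated cohort to standard file formats
#'
#' Emits genotypes as an uncompressed VCF v4.2 (biallelic SNPs, GT field,
#' PASS filter, records sorted by position), expression as a BED-like
#' table (chrom, 0-based half-open interval containing the TSS, gene id,
#' one column per sample), covariates / global ancestry / per-gene local
#' ancestry as TSVs with headers, and the simulation truth table.
#' Numeric expression values are written with full precision so a
#' read-back round trip is exact. Variants masked from the typed panel
#' by the expression simulation are not written to the VCF.
#'
#' @param cohort An `admixed_cohort`.
#' @param expression Optional `expression_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_cohort <- function(cohort, expression = NULL, dir) {
  stopifnot(inherits(cohort, "admixed_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- cohort$panel
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    expression = file.path(dir, "expression.bed"),
    covariates = file.path(dir, "covariates.tsv"),
    global_ancestry = file.path(dir, "global_ancestry.tsv"),
    local_ancestry = file.path(dir, "local_ancestry.tsv"),
    truth = file.path(dir, "truth.tsv")
  )

  keep <- typed_variants(cohort, expression)
  ord <- keep[order(panel$chrom[keep], panel$pos[keep])]
  gt_code <- c("0/0", "0/1", "1/1")
  n <- length(cohort$sample_id)

  con <- file(paths$vcf, "w")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=admixqtl",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", cohort$sample_id), collapse = "\t")
  ), con)
  gt <- matrix(gt_code[cohort$dosage[, ord, drop = FALSE] + 1L],
               nrow = n)
  body <- paste(panel$chrom[ord], panel$pos[ord], panel$variant_id[ord],
                "A", "B", ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  close(con)

  fmt <- function(x) sprintf("%.17g", x)

  if (!is.null(expression)) {
    ex <- expression$expr
    gi <- panel$genes[match(rownames(ex), panel$genes$gene_id), , drop = FALSE]
    bed <- data.frame(`#chr` = gi$chrom,
                      start = gi$tss - 1L,
                      end = gi$tss,
                      gene_id = gi$gene_id,
                      check.names = FALSE, stringsAsFactors = FALSE)
    vals <- matrix(fmt(ex), nrow = nrow(ex), ncol = ncol(ex))
    colnames(vals) <- cohort$sample_id
    data.table::fwrite(cbind(bed, as.data.frame(vals, check.names = FALSE)),
                       paths$expression, sep = "\t", quote = FALSE)
    tr <- expression$truth
    for (cn in names(tr)) if (is.numeric(tr[[cn]])) tr[[cn]] <- fmt(tr[[cn]])
    data.table::fwrite(tr, paths$truth, sep = "\t", quote = FALSE)
  }

  cov <- cbind(sample_id = cohort$sample_id, cohort$covariates)
  cov$age <- fmt(cov$age)
  data.table::fwrite(cov, paths$covariates, sep = "\t", quote = FALSE)

  th <- as.data.frame(apply(cohort$theta, 2, fmt))
  names(th) <- panel$pop_labels
  data.table::fwrite(cbind(sample_id = cohort$sample_id, th),
                     paths$global_ancestry, sep = "\t", quote = FALSE)

  la <- do.call(rbind, lapply(seq_len(nrow(panel$genes)), function(g) {
    d <- as.data.frame(cohort$local_anc[, g, , drop = TRUE])
    names(d) <- panel$pop_labels
    cbind(gene_id = panel$genes$gene_id[g], sample_id = cohort$sample_id, d)
  }))
  data.table::fwrite(la, paths$local_ancestry, sep = "\t", quote = FALSE)

  invisible(paths)
}

#' Read back a cohort written by [write_cohort()]
#'
#' Genotypes are parsed with `vcfR`; expression, covariates and ancestry
#' tables with `data.table`. Returns plain matrices/data frames keyed to
#' the written sample and variant ids.
#'
#' @param dir Directory produced by [write_cohort()].
#' @return List with `dosage`, `variant_pos` (data.frame), `expr`,
#'   `gene_info`, `covariates`, `theta`, `local_anc` (long data.frame),
#'   and `truth` (NULL if absent).
#' @export
read_cohort <- function(dir) {
  vcf_path <- file.path(dir, "genotypes.vcf")
  if (!file.exists(vcf_path)) stop("no genotypes.vcf under ", dir)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt == "0/1" | gt == "1/0"] <- 1L
  dos[gt == "1/1"] <- 2L
  dosage <- t(dos)
  fix <- vcfR::getFIX(v)
  variant_pos <- data.frame(variant_id = fix[, "ID"], chrom = fix[, "CHROM"],
                            pos = as.integer(fix[, "POS"]),
                            ref = fix[, "REF"], alt = fix[, "ALT"],
                            stringsAsFactors = FALSE)

  out <- list(dosage = dosage, variant_pos = variant_pos)

  bed_path <- file.path(dir, "expression.bed")
  if (file.exists(bed_path)) {
    bed <- data.table::fread(bed_path, sep = "\t", data.table = FALSE)
    out$gene_info <- bed[, 1:4]
    names(out$gene_info) <- c("chrom", "start", "end", "gene_id")
    expr <- as.matrix(bed[, -(1:4), drop = FALSE])
    rownames(expr) <- bed$gene_id
    out$expr <- expr
  }
  cov_path <- file.path(dir, "covariates.tsv")
  if (file.exists(cov_path))
    out$covariates <- data.table::fread(cov_path, data.table = FALSE)
  ga_path <- file.path(dir, "global_ancestry.tsv")
  if (file.exists(ga_path)) {
    ga <- data.table::fread(ga_path, data.table = FALSE)
    out$theta <- as.matrix(ga[, -1, drop = FALSE])
    rownames(out$theta) <- ga$sample_id
  }
  la_path <- file.path(dir, "local_ancestry.tsv")
  if (file.exists(la_path))
    out$local_anc <- data.table::fread(la_path, data.table = FALSE)
  tr_path <- file.path(dir, "truth.tsv")
  out$truth <- if (file.exists(tr_path))
    data.table::fread(tr_path, data.table = FALSE) else NULL
  out
}
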