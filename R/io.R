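## Readers and writers for the plain-text interchange formats: gene
## annotation TSV/GTF, PLINK .bim/.fam text, dosage TSV, GWAS summary TSV,
## and the association output table.

#' Read a gene annotation table
#'
#' Tab-delimited with header columns `gene_id`, `chrom`, `tss` and
#' optionally `strand`; or a GTF/GFF file (requires rtracklayer), from
#' which the TSS is taken strand-aware (start on `+`, end on `-`) per gene.
#'
#' @param path input file.
#' @return data.frame with `gene_id`, `chrom`, `strand`, `tss`.
#' @export
readGeneAnnotation <- function(path) {
  if (grepl("\\.(gtf|gff|gff3)(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type %in% c("gene", "transcript")]
    if (any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                  end(gr), start(gr))
    out <- data.frame(gene_id = gr$gene_id, chrom = as.character(seqnames(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      tss = tss, stringsAsFactors = FALSE)
    return(.checkGenes(out[!duplicated(out$gene_id), , drop = FALSE]))
  }
  tb <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"strand" %in% names(tb)) tb$strand <- "+"
  .checkGenes(tb)[, c("gene_id", "chrom", "strand", "tss")]
}

#' Read variant records
#'
#' Accepts a PLINK `.bim` (six whitespace-separated columns: chrom, snp id,
#' cM, position, allele 1, allele 2; allele 1 is taken as the counted
#' effect allele, PLINK's convention) or a headered TSV with `snp_id`,
#' `chrom`, `pos`, `allele_effect`, `allele_other`.
#'
#' @param path input file.
#' @return data.frame of variant records.
#' @export
readVariants <- function(path) {
  if (grepl("\\.bim$", path, ignore.case = TRUE)) {
    tb <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tb) < 6L) stop(".bim file must have 6 columns")
    out <- data.frame(snp_id = as.character(tb[[2L]]),
                      chrom = as.character(tb[[1L]]), pos = tb[[4L]],
                      allele_effect = as.character(tb[[5L]]),
                      allele_other = as.character(tb[[6L]]),
                      stringsAsFactors = FALSE)
    return(.checkVariants(out))
  }
  .checkVariants(utils::read.delim(path, header = TRUE,
                                   stringsAsFactors = FALSE))
}

#' Construct a GenotypeData object
#'
#' @param dosages samples x variants numeric matrix of effect-allele
#'   dosages in `[0, 2]`; column names must match `variants$snp_id` (set
#'   from it when absent).
#' @param variants variant record data.frame (see [readVariants()]).
#' @return a [GenotypeData].
#' @export
genotypeData <- function(dosages, variants) {
  variants <- .checkVariants(variants)
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$snp_id
  new("GenotypeData", dosages = dosages, variants = variants)
}

#' Read a dosage matrix with its variant records
#'
#' The dosage file is a headered TSV: first column `sample_id`, remaining
#' columns one per SNP (names are SNP ids), values in `[0, 2]` with `NA`
#' for missing.
#'
#' @param dosagePath dosage TSV.
#' @param variantPath variant file for [readVariants()].
#' @return a [GenotypeData].
#' @export
readDosages <- function(dosagePath, variantPath) {
  tb <- utils::read.delim(dosagePath, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(tb)[1L] != "sample_id")
    stop("dosage file must start with a sample_id column")
  X <- as.matrix(tb[, -1L, drop = FALSE])
  rownames(X) <- tb$sample_id
  storage.mode(X) <- "double"
  variants <- readVariants(variantPath)
  idx <- match(colnames(X), variants$snp_id)
  if (anyNA(idx))
    stop("dosage column(s) missing from variant file: ",
         paste(utils::head(colnames(X)[is.na(idx)], 3L), collapse = ", "))
  genotypeData(X, variants[idx, , drop = FALSE])
}

#' Read GWAS summary statistics
#'
#' Tab-delimited with header; required columns `SNP`, `CHR`, `POS`, `A1`
#' (effect allele), `A2`, and either `Z` or the pair `BETA`/`SE` from
#' which `Z = BETA/SE` is derived; optional `N`, `P`. Lower-case synonyms
#' (`snp_id`, `effect_allele`, ...) are also accepted.
#'
#' @param path input TSV.
#' @return data.frame with `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `z`, `n`, `p`.
#' @export
readGwasSummary <- function(path) {
  tb <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(tb)) return(tb[[nm]])
    NULL
  }
  out <- data.frame(
    snp_id = pick("SNP", "snp_id"), stringsAsFactors = FALSE)
  if (is.null(out$snp_id)) stop("summary statistics lack column: SNP")
  chrom <- pick("CHR", "chrom"); pos <- pick("POS", "pos")
  a1 <- pick("A1", "effect_allele"); a2 <- pick("A2", "other_allele")
  for (v in c("CHR", "POS", "A1", "A2")) {
    got <- switch(v, CHR = chrom, POS = pos, A1 = a1, A2 = a2)
    if (is.null(got)) stop("summary statistics lack column: ", v)
  }
  out$chrom <- as.character(chrom); out$pos <- pos
  out$effect_allele <- as.character(a1); out$other_allele <- as.character(a2)
  z <- pick("Z", "z")
  if (is.null(z)) {
    beta <- pick("BETA", "beta"); se <- pick("SE", "se")
    if (is.null(beta) || is.null(se))
      stop("summary statistics lack column: Z (and no BETA/SE pair to derive it)")
    z <- beta / se
  }
  if (!is.numeric(z)) stop("Z column is not numeric")
  out$z <- z
  nCol <- pick("N", "n"); out$n <- if (is.null(nCol)) NA_real_ else nCol
  pCol <- pick("P", "p"); out$p <- if (is.null(pCol)) NA_real_ else pCol
  out
}

#' Write the segment association table
#'
#' TSV with columns `segment_id`, `chrom`, `start` (BED), `end`,
#' `n_snps_used`, `sigma_s`, `Z`, `P`, `P_adj`, `nearest_gene`,
#' `significant`.
#'
#' @param assoc association data.frame.
#' @param segments the [SegmentSet] tested (supplies coordinates).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeAssociation <- function(assoc, segments, path) {
  gr <- segmentRanges(segments)
  idx <- match(assoc$segment_id, gr$segment_id)
  out <- data.frame(
    segment_id = assoc$segment_id,
    chrom = as.character(seqnames(gr))[idx],
    start = start(gr)[idx] - 1L, end = end(gr)[idx],
    n_snps_used = assoc$n_snps_used, sigma_s = assoc$sigma_s,
    Z = assoc$Z, P = assoc$p, P_adj = assoc$p_adj,
    nearest_gene = assoc$nearest_gene, significant = assoc$significant,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
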