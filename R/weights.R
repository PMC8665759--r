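## Openness weight handling and segment openness scores.

#' Load a per-SNP openness weight table
#'
#' Reads a tab-delimited table of predicted allelic openness effects (one
#' row per SNP: the weight \eqn{w_j} and the allele it refers to), filtered
#' to one cell type when a `cell_type` column is present.
#'
#' @param path TSV with header columns `snp_id`, `effect_allele`, `weight`
#'   and optionally `cell_type`.
#' @param cellType requested cell type; required when the file carries a
#'   `cell_type` column, ignored (with the label still recorded) otherwise.
#' @return an [OpennessWeights] object.
#' @export
loadWeights <- function(path, cellType = NULL) {
  tb <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("snp_id", "effect_allele", "weight")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0L)
    stop("weight file lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(tb$weight))
    stop("weight column is not numeric")
  if ("cell_type" %in% names(tb)) {
    avail <- unique(tb$cell_type)
    if (is.null(cellType))
      stop("file holds multiple cell types; choose one of: ",
           paste(avail, collapse = ", "))
    if (!cellType %in% avail)
      stop("cell type '", cellType, "' not in file; available: ",
           paste(avail, collapse = ", "))
    tb <- tb[tb$cell_type == cellType, need, drop = FALSE]
  } else {
    if (is.null(cellType)) cellType <- "unspecified"
    tb <- tb[, need, drop = FALSE]
  }
  if (anyDuplicated(tb$snp_id))
    stop("duplicate snp_id in weight file: ",
         tb$snp_id[anyDuplicated(tb$snp_id)][1L])
  new("OpennessWeights", cellType = cellType,
      table = tb[, need, drop = FALSE])
}

#' In-memory constructor for openness weights
#'
#' @param snpId,effectAllele,weight parallel vectors.
#' @param cellType cell-type label.
#' @return an [OpennessWeights] object.
#' @export
opennessWeights <- function(snpId, effectAllele, weight,
                            cellType = "unspecified") {
  new("OpennessWeights", cellType = cellType,
      table = data.frame(snp_id = as.character(snpId),
                         effect_allele = as.character(effectAllele),
                         weight = as.numeric(weight),
                         stringsAsFactors = FALSE))
}

.isAmbiguous <- function(a1, a2) {
  p <- paste(a1, a2)
  p %in% c("A T", "T A", "C G", "G C")
}

#' Harmonize weight alleles to the dosage coding
#'
#' Aligns each weight to the allele the dosage matrix counts: if the weight
#' refers to the dosage effect allele it is kept; if to the other allele
#' its sign is flipped; if to neither, the SNP is dropped. Strand-ambiguous
#' SNPs (A/T, C/G) are dropped by default because their orientation cannot
#' be verified against the weight table.
#'
#' @param weights an [OpennessWeights].
#' @param variants data.frame with `snp_id`, `allele_effect`,
#'   `allele_other` describing the dosage coding.
#' @param allowAmbiguous keep strand-ambiguous SNPs (flagged) instead of
#'   dropping them.
#' @return data.frame (`snp_id`, `weight`, `flipped`, `ambiguous`) of SNPs
#'   with a usable signed weight; drop counts by reason are attached as
#'   attribute `"drops"`.
#' @export
harmonizeAlleles <- function(weights, variants, allowAmbiguous = FALSE) {
  stopifnot(is(weights, "OpennessWeights"))
  variants <- as.data.frame(variants)
  tb <- weights@table
  idx <- match(tb$snp_id, variants$snp_id)
  drops <- c(not_in_variants = sum(is.na(idx)))
  keep <- !is.na(idx)
  tb <- tb[keep, , drop = FALSE]
  v <- variants[idx[keep], , drop = FALSE]
  matchEffect <- tb$effect_allele == v$allele_effect
  matchOther <- tb$effect_allele == v$allele_other
  ambiguous <- .isAmbiguous(v$allele_effect, v$allele_other)
  usable <- matchEffect | matchOther
  drops <- c(drops, allele_mismatch = sum(!usable))
  if (!allowAmbiguous) {
    drops <- c(drops, strand_ambiguous = sum(ambiguous & usable))
    usable <- usable & !ambiguous
  } else {
    drops <- c(drops, strand_ambiguous = 0L)
  }
  out <- data.frame(
    snp_id = tb$snp_id[usable],
    weight = ifelse(matchEffect[usable], tb$weight[usable], -tb$weight[usable]),
    flipped = matchOther[usable],
    ambiguous = ambiguous[usable],
    stringsAsFactors = FALSE
  )
  attr(out, "drops") <- drops
  out
}

.imputeMissing <- function(X) {
  nas <- which(colSums(is.na(X)) > 0L)
  for (j in nas) {
    col <- X[, j]
    mu <- mean(col, na.rm = TRUE)
    if (!is.finite(mu)) mu <- 0
    col[is.na(col)] <- mu
    X[, j] <- col
  }
  X
}

#' Compute per-individual segment openness scores
#'
#' Evaluates \eqn{O_{i,s} = \sum_{j \in \Omega_s} w_j X_{ij}} for every
#' sample i and segment s. Missing dosages are mean-imputed per SNP first.
#' SNPs in a segment without a harmonized weight contribute 0 and are
#' counted; a segment in which no SNP carries a weight yields a zero column
#' flagged degenerate.
#'
#' @param genotypes a [GenotypeData].
#' @param w harmonized signed weights as returned by [harmonizeAlleles()]
#'   (data.frame with `snp_id`, `weight`), or a named numeric vector.
#' @param segments a [SegmentSet] with SNPs assigned.
#' @return an [OpennessMatrix] (samples x segments).
#' @export
computeOpenness <- function(genotypes, w, segments) {
  stopifnot(is(genotypes, "GenotypeData"), is(segments, "SegmentSet"))
  if (is.data.frame(w)) w <- stats::setNames(w$weight, w$snp_id)
  X <- .imputeMissing(genotypes@dosages)
  segSnps <- segmentSnps(segments)
  ids <- segmentIds(segments)
  n <- nrow(X)
  O <- matrix(0, nrow = n, ncol = length(ids),
              dimnames = list(rownames(X), ids))
  nUsed <- integer(length(ids))
  for (s in seq_along(ids)) {
    snps <- segSnps[[s]]
    snps <- snps[snps %in% colnames(X) & snps %in% names(w)]
    nUsed[s] <- length(snps)
    if (length(snps) > 0L)
      O[, s] <- X[, snps, drop = FALSE] %*% w[snps]
  }
  new("OpennessMatrix", scores = O,
      degenerate = nUsed == 0L, nSnpsUsed = nUsed)
}

.readPeaks <- function(peaks) {
  if (is(peaks, "GRanges")) return(peaks)
  if (is.character(peaks) && length(peaks) == 1L) {
    if (requireNamespace("rtracklayer", quietly = TRUE))
      return(rtracklayer::import(peaks, format = "BED"))
    bed <- utils::read.table(peaks, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)[, 1:3]
    return(GRanges(bed[[1L]], IRanges(bed[[2L]] + 1L, bed[[3L]])))
  }
  stop("peaks must be a GRanges or a BED file path")
}

#' Peak-resampling enrichment of openness weights
#'
#' Tests whether variants inside a set of peaks (e.g. histone-modification
#' or DNase peaks) carry larger openness weights than random variants: the
#' observed statistic is the mean weight of in-peak variants, the null is
#' built by drawing the same number of variants without replacement from
#' all variants `nResample` times (default 10000), and the empirical
#' one-sided p-value is `(1 + #{null >= observed}) / (nResample + 1)`.
#'
#' @param weights an [OpennessWeights].
#' @param peaks BED file path or GRanges of peak intervals.
#' @param variants data.frame with `snp_id`, `chrom`, `pos` for every
#'   weighted variant.
#' @param nResample number of resampling draws, >= 100.
#' @param seed integer seed; the test is reproducible given the seed.
#' @return list with `observed` (mean in-peak weight), `p` (empirical
#'   p-value), `nInPeak`, `nResample`, and `nullMeans`.
#' @export
peakEnrichment <- function(weights, peaks, variants, nResample = 10000L,
                           seed = 1L) {
  stopifnot(is(weights, "OpennessWeights"))
  if (nResample < 100L) stop("nResample must be >= 100")
  variants <- .checkVariants(variants)
  peaks <- .readPeaks(peaks)
  tb <- weights@table
  idx <- match(variants$snp_id, tb$snp_id)
  variants <- variants[!is.na(idx), , drop = FALSE]
  wAll <- tb$weight[idx[!is.na(idx)]]
  vgr <- GRanges(.stripChr(variants$chrom), IRanges(variants$pos, width = 1L))
  pgr <- GRanges(.stripChr(seqnames(peaks)), IRanges(start(peaks), end(peaks)))
  ## benign when peaks and variants share no chromosome: zero overlaps
  inPeak <- S4Vectors::queryHits(suppressWarnings(findOverlaps(vgr, pgr)))
  inPeak <- unique(inPeak)
  k <- length(inPeak)
  if (k == 0L) stop("no weighted variant falls inside the peaks")
  observed <- mean(wAll[inPeak])
  m <- length(wAll)
  set.seed(as.integer(seed))
  nullMeans <- vapply(seq_len(nResample), function(i) {
    mean(wAll[sample.int(m, k)])
  }, numeric(1))
  p <- (1 + sum(nullMeans >= observed)) / (nResample + 1)
  list(observed = observed, p = p, nInPeak = k,
       nResample = as.integer(nResample), nullMeans = nullMeans)
}
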