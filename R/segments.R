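## Regulatory-region construction and segment tiling.
##
## Conventions used throughout: variant positions are 1-based (as in .bim
## files); segments are reported in BED-style 0-based half-open coordinates
## [a, b) and stored internally as 1-based closed GRanges [a+1, b]. A
## variant at 1-based position p lies in [a, b) iff a < p <= b — i.e. its
## 0-based position p-1 satisfies a <= p-1 < b. This gives every boundary
## base an unambiguous owner.

.checkGenes <- function(genes) {
  if (is.null(genes) || nrow(as.data.frame(genes)) == 0L) stop("no genes")
  genes <- as.data.frame(genes)
  need <- c("gene_id", "chrom", "tss")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0L)
    stop("gene annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation: ",
         genes$gene_id[anyDuplicated(genes$gene_id)][1L])
  if (any(genes$tss < 1)) stop("tss positions must be >= 1")
  genes
}

.checkVariants <- function(variants) {
  variants <- as.data.frame(variants)
  need <- c("snp_id", "chrom", "pos")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0L)
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(variants$snp_id))
    stop("duplicate snp_id: ", variants$snp_id[anyDuplicated(variants$snp_id)][1L])
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  variants
}

.segIdFromRanges <- function(gr) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr) - 1L, end(gr))
}

newSegmentSet <- function(gr, snps = NULL, stats = list()) {
  if (is.null(gr$segment_id)) gr$segment_id <- .segIdFromRanges(gr)
  if (is.null(snps)) snps <- CharacterList(rep(list(character(0)), length(gr)))
  new("SegmentSet", ranges = gr, snps = snps, stats = stats)
}

#' Build TSS-anchored regulatory regions
#'
#' Places a symmetric window of `flank` bp on each side of every gene's
#' transcription start site (default 100 kb, covering most regulatory
#' variants), clips at the chromosome start, and merges overlapping windows
#' on the same chromosome into their union so that each SNP is tested once.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss` (1-based)
#'   and optionally `strand`.
#' @param flank half-window size in bp, default 100000.
#' @return a sorted [GenomicRanges::GRanges] of merged regulatory intervals;
#'   in BED terms each gene contributes `[tss - flank, tss + flank)`.
#' @examples
#' genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 1e6)
#' buildRegulatoryRegions(genes, flank = 1e5)
#' @export
buildRegulatoryRegions <- function(genes, flank = 100000L) {
  genes <- .checkGenes(genes)
  if (length(flank) != 1L || !is.finite(flank) || flank <= 0)
    stop("flank must be a single positive number of base pairs")
  start0 <- pmax(1, genes$tss - flank)
  end0 <- genes$tss + flank
  gr <- GRanges(genes$chrom, IRanges(start = start0 + 1, end = end0))
  sort(reduce(gr))
}

#' Tile intervals into fixed-length segments
#'
#' Cuts each interval left-to-right into windows of exactly `segLen` bp
#' (default 5 kb); a shorter terminal window is kept and flagged `short`.
#' Window ids are deterministic `"<chrom>:<bed_start>-<bed_end>"`.
#'
#' @param intervals GRanges of (merged) regulatory intervals, e.g. from
#'   [buildRegulatoryRegions()].
#' @param segLen segment length in bp; 2500, 5000 and 10000 are the usual
#'   sensitivity settings, 5000 the default.
#' @return a [SegmentSet] with empty SNP sets.
#' @export
tileSegments <- function(intervals, segLen = 5000L) {
  if (length(segLen) != 1L || !is.finite(segLen) || segLen <= 0)
    stop("segLen must be a single positive number of base pairs")
  intervals <- sort(reduce(intervals))
  win <- unlist(slidingWindows(intervals, width = segLen, step = segLen))
  mcols(win) <- NULL
  win$segment_id <- .segIdFromRanges(win)
  win$short <- width(win) < segLen
  newSegmentSet(win, stats = list(seg_len = segLen, n_intervals = length(intervals)))
}

#' Tile variants into segments holding a fixed number of SNPs
#'
#' Variable-length alternative to [tileSegments()]: consecutive runs of `k`
#' SNPs (per chromosome, in position order) form one segment each; the last
#' run may hold fewer. `k = 20` mirrors the median SNP count of a 5 kb
#' segment. Segment bounds are the half-open span from the previous
#' boundary (just before the run's first SNP for the first run) to the last
#' SNP position, so consecutive segments abut.
#'
#' @param variants data.frame with `snp_id`, `chrom`, `pos` (1-based).
#' @param k SNPs per segment, default 20.
#' @return a [SegmentSet] with SNP sets already filled.
#' @export
tileSegmentsBySnpCount <- function(variants, k = 20L) {
  if (length(k) != 1L || !is.finite(k) || k < 1) stop("k must be >= 1")
  variants <- .checkVariants(variants)
  if (nrow(variants) == 0L)
    return(newSegmentSet(GRanges(), stats = list(k = k)))
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  pieces <- split(variants, variants$chrom)
  grl <- list(); snpl <- list()
  for (chrom in names(pieces)) {
    v <- pieces[[chrom]]
    idx <- split(seq_len(nrow(v)), ceiling(seq_len(nrow(v)) / k))
    last <- vapply(idx, function(i) v$pos[i[length(i)]], numeric(1))
    start0 <- c(v$pos[1L] - 1L, last[-length(last)])
    grl[[chrom]] <- GRanges(chrom, IRanges(start = start0 + 1, end = last))
    snpl[[chrom]] <- lapply(idx, function(i) v$snp_id[i])
  }
  gr <- sort(do.call(c, unname(grl)))
  ## re-order snp lists to match sorted ranges
  allSnps <- do.call(c, unname(lapply(names(pieces), function(ch) snpl[[ch]])))
  key <- do.call(c, unname(lapply(names(pieces), function(ch) {
    .segIdFromRanges(grl[[ch]])
  })))
  gr$segment_id <- .segIdFromRanges(gr)
  gr$short <- FALSE
  snps <- CharacterList(allSnps[match(gr$segment_id, key)])
  gr$n_snps <- lengths(snps)
  newSegmentSet(gr, snps, stats = list(k = k, n_snps_assigned = nrow(variants)))
}

#' Assign variants to segments
#'
#' Fills the SNP set \eqn{\Omega_s} of each segment: each variant lands in
#' the unique segment whose BED interval `[a, b)` satisfies `a < pos <= b`
#' (assignment by position only). Variants falling outside every segment
#' are left unassigned and counted in the returned object's `stats`.
#' Segments left empty are retained but flagged with `n_snps = 0`; the
#' association step skips them.
#'
#' @param segments a [SegmentSet].
#' @param variants data.frame with `snp_id`, `chrom`, `pos`.
#' @return the [SegmentSet] with SNP sets and an `n_snps` metadata column.
#' @export
assignSnps <- function(segments, variants) {
  stopifnot(is(segments, "SegmentSet"))
  variants <- .checkVariants(variants)
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  gr <- segments@ranges
  vgr <- GRanges(variants$chrom, IRanges(variants$pos, width = 1L))
  hits <- findOverlaps(vgr, gr)
  snps <- unname(S4Vectors::splitAsList(
    variants$snp_id[S4Vectors::queryHits(hits)],
    factor(S4Vectors::subjectHits(hits), levels = seq_along(gr))
  ))
  snps <- CharacterList(as.list(snps))
  gr$n_snps <- lengths(snps)
  nUnassigned <- nrow(variants) - length(hits)
  if (nUnassigned > 0L)
    message(nUnassigned, " variant(s) fell outside all segments")
  stats <- segments@stats
  stats$n_snps_assigned <- length(hits)
  stats$n_snps_unassigned <- nUnassigned
  stats$n_empty_segments <- sum(lengths(snps) == 0L)
  newSegmentSet(gr, snps, stats)
}

#' Coordinates of the HLA region (hg19)
#'
#' chr6:28,477,797-33,448,354 — conventionally excluded from heritability
#' analyses because of its atypical LD structure and genetic architecture.
#'
#' @return a length-1 GRanges (1-based, closed).
#' @export
hlaRegion <- function() {
  GRanges("chr6", IRanges(28477797L, 33448354L))
}

.stripChr <- function(x) sub("^chr", "", as.character(x))

#' Drop segments overlapping a genomic region
#'
#' Removes every segment overlapping the given interval by at least one bp.
#' `region = "HLA_hg19"` (the default) uses the built-in [hlaRegion()]
#' coordinates. Chromosome names are compared with the `"chr"` prefix
#' stripped, so `"6"` and `"chr6"` match.
#'
#' @param segments a [SegmentSet].
#' @param region `"HLA_hg19"`, or a length-1 GRanges, or `NULL` when
#'   `chrom`/`start`/`end` are given.
#' @param chrom,start,end explicit 1-based closed interval, used when
#'   `region` is NULL.
#' @return the filtered [SegmentSet]; the number removed is recorded in its
#'   `stats`.
#' @export
excludeRegion <- function(segments, region = "HLA_hg19",
                          chrom = NULL, start = NULL, end = NULL) {
  stopifnot(is(segments, "SegmentSet"))
  if (is.null(region)) {
    if (is.null(chrom) || is.null(start) || is.null(end))
      stop("provide region or chrom/start/end")
    if (start > end) stop("invalid interval: start > end")
    region <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)))
  } else if (identical(region, "HLA_hg19")) {
    region <- hlaRegion()
  }
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  gr <- segments@ranges
  sameChrom <- .stripChr(seqnames(gr)) == .stripChr(seqnames(region))
  drop <- sameChrom & start(gr) <= end(region) & end(gr) >= start(region)
  stats <- segments@stats
  stats$n_excluded_region <- sum(drop)
  newSegmentSet(gr[!drop], segments@snps[!drop], stats)
}

#' Map segments to their nearest gene
#'
#' Tags each segment with the gene whose TSS is closest to the segment
#' midpoint; ties are broken by lexicographically smallest `gene_id`. The
#' distance is reported alongside. Segments on a chromosome without any
#' annotated gene get `NA` with a warning.
#'
#' @param segments a [SegmentSet].
#' @param genes data.frame with `gene_id`, `chrom`, `tss`.
#' @return the [SegmentSet] with `nearest_gene` and `nearest_gene_dist`
#'   metadata columns.
#' @export
mapToNearestGene <- function(segments, genes) {
  stopifnot(is(segments, "SegmentSet"))
  genes <- .checkGenes(genes)
  gr <- segments@ranges
  ## midpoint in bp of the BED interval [a, b): (a + b) / 2
  mid <- (start(gr) - 1 + end(gr)) / 2
  chromSeg <- .stripChr(seqnames(gr))
  chromGene <- .stripChr(genes$chrom)
  nearest <- rep(NA_character_, length(gr))
  dist <- rep(NA_real_, length(gr))
  for (ch in unique(chromSeg)) {
    segIdx <- which(chromSeg == ch)
    gIdx <- which(chromGene == ch)
    if (length(gIdx) == 0L) {
      warning("no gene on chromosome ", ch, "; nearest_gene is NA")
      next
    }
    g <- genes[gIdx, , drop = FALSE]
    g <- g[order(g$gene_id), , drop = FALSE]  # tie-break: smallest gene_id wins
    for (i in segIdx) {
      d <- abs(g$tss - mid[i])
      j <- which.min(d)  # first minimum = smallest gene_id among ties
      nearest[i] <- g$gene_id[j]
      dist[i] <- d[j]
    }
  }
  gr$nearest_gene <- nearest
  gr$nearest_gene_dist <- dist
  newSegmentSet(gr, segments@snps, segments@stats)
}

#' Write segments as a 6-column BED-style table
#'
#' Columns: chrom, BED start, BED end, segment_id, n_snps, nearest_gene.
#'
#' @param segments a [SegmentSet].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSegmentsBed <- function(segments, path) {
  gr <- segments@ranges
  n <- if (is.null(gr$n_snps)) lengths(segments@snps) else gr$n_snps
  gene <- if (is.null(gr$nearest_gene)) rep(".", length(gr)) else
    ifelse(is.na(gr$nearest_gene), ".", gr$nearest_gene)
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = end(gr), segment_id = gr$segment_id,
                   n_snps = n, nearest_gene = gene)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
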