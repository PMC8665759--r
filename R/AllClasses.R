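#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges granges seqnames start end width
#'   findOverlaps reduce slidingWindows
#' @importFrom tools md5sum
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' SegmentSet: tiled genomic windows with their SNP content
#'
#' A set of disjoint genomic segments — the unit of openness-weighted
#' association testing. Segments are stored as a [GenomicRanges::GRanges]
#' (1-based, closed; the equivalent 0-based half-open BED coordinates are
#' `start - 1` / `end`) together with one character vector of SNP ids per
#' segment (the set \eqn{\Omega_s}). A variant with 1-based position `p`
#' belongs to the segment with BED bounds `[a, b)` iff `a < p <= b`.
#'
#' Metadata columns on the ranges carry `segment_id`, `n_snps` once SNPs are
#' assigned, and `nearest_gene` / `nearest_gene_dist` once genes are mapped.
#' `stats` holds bookkeeping from construction (e.g. unassigned-SNP counts).
#'
#' @slot ranges GRanges of the segments, sorted, pairwise disjoint per
#'   chromosome.
#' @slot snps CharacterList parallel to `ranges`; SNP ids per segment,
#'   ordered by position.
#' @slot stats list of construction bookkeeping.
#' @seealso [tileSegments()], [assignSnps()], [mapToNearestGene()]
#' @export
setClass("SegmentSet",
  slots = c(ranges = "GRanges", snps = "CharacterList", stats = "list"),
  prototype = prototype(stats = list())
)

setValidity("SegmentSet", function(object) {
  gr <- object@ranges
  if (length(gr) != length(object@snps))
    return("ranges and snps must be parallel")
  if (length(gr) == 0L) return(TRUE)
  if (is.null(gr$segment_id) || anyDuplicated(gr$segment_id))
    return("segment_id must be present and unique")
  ## disjoint within chromosome
  hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hits) > 0L) return("segments overlap")
  snps <- unlist(object@snps, use.names = FALSE)
  if (anyDuplicated(snps)) return("a SNP is assigned to more than one segment")
  TRUE
})

#' OpennessWeights: per-SNP predicted openness effects for one cell type
#'
#' Holds the allelic openness effect \eqn{w_j} predicted for each SNP in a
#' given cell type (e.g. deltaSVM scores on DNase I hypersensitivity), keyed
#' by SNP id and tagged with the allele the effect refers to. Weights are
#' signed: positive means the effect allele opens chromatin.
#'
#' @slot cellType single cell-type label.
#' @slot table data.frame with columns `snp_id`, `effect_allele`, `weight`.
#' @seealso [loadWeights()], [harmonizeAlleles()]
#' @export
setClass("OpennessWeights",
  slots = c(cellType = "character", table = "data.frame")
)

setValidity("OpennessWeights", function(object) {
  tb <- object@table
  need <- c("snp_id", "effect_allele", "weight")
  if (!all(need %in% names(tb)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$snp_id))
    return(sprintf("duplicate snp_id: %s",
                   tb$snp_id[anyDuplicated(tb$snp_id)][1L]))
  if (nrow(tb) > 0L && !all(is.finite(tb$weight)))
    return("weights must be finite")
  if (length(object@cellType) != 1L) return("cellType must be length 1")
  TRUE
})

#' GenotypeData: dosage matrix plus variant records
#'
#' Genotypes of `n` samples at `m` variants as effect-allele dosages in
#' `[0, 2]` (missing allowed as `NA`). Variant records provide the
#' coordinates and allele coding that all harmonization refers to.
#'
#' @slot dosages numeric matrix, samples in rows, variants in columns;
#'   column names are SNP ids.
#' @slot variants data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele_effect`, `allele_other`, rows parallel to dosage columns.
#' @seealso [readDosages()], [simulateGenotypes()]
#' @export
setClass("GenotypeData",
  slots = c(dosages = "matrix", variants = "data.frame")
)

setValidity("GenotypeData", function(object) {
  v <- object@variants
  need <- c("snp_id", "chrom", "pos", "allele_effect", "allele_other")
  if (!all(need %in% names(v)))
    return(sprintf("variants must have columns %s", paste(need, collapse = ", ")))
  if (ncol(object@dosages) != nrow(v))
    return("dosage columns and variant rows must be parallel")
  if (!identical(colnames(object@dosages), as.character(v$snp_id)))
    return("dosage column names must equal variants$snp_id")
  d <- object@dosages
  if (length(d) > 0L) {
    rng <- range(d, na.rm = TRUE)
    if (is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 2))
      return("dosages must lie in [0, 2]")
  }
  TRUE
})

#' LDBlock: per-segment LD matrix and dosage standard deviations
#'
#' The linkage-disequilibrium correlation matrix \eqn{R} of the SNPs in one
#' segment, plus the per-SNP dosage standard deviations
#' \eqn{\hat\sigma_j}, both estimated from a reference genotype panel.
#' These are the only LD quantities the summary-statistic segment test
#' needs; no matrix inversion is ever performed.
#'
#' @slot segmentId the segment this block belongs to.
#' @slot snpIds SNP ids, ordering matches rows/cols of `R` and `sd`.
#' @slot R symmetric correlation matrix with unit diagonal, entries clipped
#'   to `[-1, 1]`.
#' @slot sd nonnegative per-SNP dosage standard deviations.
#' @seealso [ldFromGenotypes()], [segmentSd()], [owasSummary()]
#' @export
setClass("LDBlock",
  slots = c(segmentId = "character", snpIds = "character",
            R = "matrix", sd = "numeric")
)

setValidity("LDBlock", function(object) {
  k <- length(object@snpIds)
  if (!all(dim(object@R) == c(k, k))) return("R dimensions must match snpIds")
  if (length(object@sd) != k) return("sd length must match snpIds")
  if (k == 0L) return(TRUE)
  if (any(!is.finite(object@R))) return("R must be finite")
  if (max(abs(object@R - t(object@R))) > 1e-8) return("R must be symmetric")
  if (max(abs(diag(object@R) - 1)) > 1e-8) return("R must have unit diagonal")
  if (max(abs(object@R)) > 1 + 1e-8) return("R entries must lie in [-1, 1]")
  if (any(object@sd < 0)) return("sd must be nonnegative")
  TRUE
})

#' OpennessMatrix: per-individual, per-segment openness scores
#'
#' The matrix \eqn{O_{i,s} = \sum_{j \in \Omega_s} w_j X_{ij}} of weighted
#' dosage sums, samples in rows and segments in columns. Columns in which no
#' SNP carried a weight are flagged degenerate and skipped by the
#' association step.
#'
#' @slot scores numeric matrix, samples x segments, finite.
#' @slot degenerate logical per segment: no weighted SNP contributed.
#' @slot nSnpsUsed integer per segment: SNPs that carried a weight.
#' @seealso [computeOpenness()], [owasIndividual()]
#' @export
setClass("OpennessMatrix",
  slots = c(scores = "matrix", degenerate = "logical", nSnpsUsed = "integer")
)

setValidity("OpennessMatrix", function(object) {
  s <- ncol(object@scores)
  if (length(object@degenerate) != s || length(object@nSnpsUsed) != s)
    return("degenerate and nSnpsUsed must have one entry per segment column")
  if (length(object@scores) > 0L && any(!is.finite(object@scores)))
    return("scores must be finite")
  TRUE
})
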