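#' Accessors for openwas classes
#'
#' Small accessor generics: `segmentRanges()` returns the GRanges of a
#' [SegmentSet], `segmentIds()` its ids, `segmentSnps()` the per-segment SNP
#' id lists, `nSegments()` its length; `cellType()` and `weightTable()` read
#' an [OpennessWeights]; `dosages()` and `variantInfo()` read a
#' [GenotypeData]; `scores()` reads an [OpennessMatrix].
#'
#' @param x an openwas object.
#' @return the slot content; see Details of each class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("segmentRanges", function(x) standardGeneric("segmentRanges"))
#' @rdname accessors
#' @export
setGeneric("segmentIds", function(x) standardGeneric("segmentIds"))
#' @rdname accessors
#' @export
setGeneric("segmentSnps", function(x) standardGeneric("segmentSnps"))
#' @rdname accessors
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))
#' @rdname accessors
#' @export
setGeneric("weightTable", function(x) standardGeneric("weightTable"))
#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setMethod("segmentRanges", "SegmentSet", function(x) x@ranges)
#' @rdname accessors
#' @export
setMethod("segmentIds", "SegmentSet", function(x) x@ranges$segment_id)
#' @rdname accessors
#' @export
setMethod("segmentSnps", "SegmentSet", function(x) {
  out <- x@snps
  names(out) <- x@ranges$segment_id
  out
})
#' @rdname accessors
#' @export
setMethod("nSegments", "SegmentSet", function(x) length(x@ranges))
#' @rdname accessors
#' @export
setMethod("cellType", "OpennessWeights", function(x) x@cellType)
#' @rdname accessors
#' @export
setMethod("weightTable", "OpennessWeights", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosages)
#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeData", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("scores", "OpennessMatrix", function(x) x@scores)

setMethod("show", "SegmentSet", function(object) {
  gr <- object@ranges
  cat(sprintf("SegmentSet with %d segments on %d chromosome(s)\n",
              length(gr), length(unique(as.character(seqnames(gr))))))
  n <- sum(lengths(object@snps))
  cat(sprintf("  SNPs assigned: %d; segments with SNPs: %d\n",
              n, sum(lengths(object@snps) > 0L)))
  if (!is.null(gr$nearest_gene))
    cat(sprintf("  nearest genes mapped: %d\n", sum(!is.na(gr$nearest_gene))))
  invisible(object)
})

setMethod("show", "OpennessWeights", function(object) {
  cat(sprintf("OpennessWeights: %d SNPs, cell type '%s'\n",
              nrow(object@table), object@cellType))
  if (nrow(object@table) > 0L)
    cat(sprintf("  weight range: [%.4g, %.4g]\n",
                min(object@table$weight), max(object@table$weight)))
  invisible(object)
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d samples x %d variants\n",
              nrow(object@dosages), ncol(object@dosages)))
  miss <- mean(is.na(object@dosages))
  if (is.finite(miss) && miss > 0)
    cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(object)
})

setMethod("show", "LDBlock", function(object) {
  cat(sprintf("LDBlock '%s': %d SNPs\n", object@segmentId,
              length(object@snpIds)))
  invisible(object)
})

setMethod("show", "OpennessMatrix", function(object) {
  cat(sprintf("OpennessMatrix: %d samples x %d segments (%d degenerate)\n",
              nrow(object@scores), ncol(object@scores),
              sum(object@degenerate)))
  invisible(object)
})
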