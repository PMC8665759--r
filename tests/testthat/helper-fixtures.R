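# In-code fixtures shared across test files. Everything is generated at
# test time from fixed seeds; nothing is read from disk.

# simple iid dosage panel with evenly spaced variants on one chromosome
randomGenotypes <- function(n, m, seed = 1L, chrom = "chr1",
                            posStart = 1000000L, spacing = 250L,
                            missing = 0) {
  set.seed(seed)
  X <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(0.49, 0.42, 0.09)),
              n, m)
  if (missing > 0) X[sample(length(X), round(missing * length(X)))] <- NA
  ids <- sprintf("snp%06d", seq_len(m))
  v <- data.frame(snp_id = ids, chrom = chrom,
                  pos = posStart + (seq_len(m) - 1L) * spacing,
                  allele_effect = "A", allele_other = "G",
                  stringsAsFactors = FALSE)
  dimnames(X) <- list(sprintf("ind%04d", seq_len(n)), ids)
  genotypeData(X, v)
}

unitWeights <- function(variants, values = 1) {
  data.frame(snp_id = variants$snp_id,
             weight = rep_len(values, nrow(variants)),
             stringsAsFactors = FALSE)
}

# per-SNP marginal-regression z-scores: the oracle route for building GWAS
# summary statistics from an individual-level cohort
marginalZOracle <- function(X, y) {
  vapply(seq_len(ncol(X)), function(j) {
    f <- stats::lm(y ~ X[, j])
    summary(f)$coefficients[2L, "t value"]
  }, numeric(1))
}

expect_segment_bed <- function(seg, chrom, start0, end0) {
  gr <- segmentRanges(seg)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), chrom)
  expect_equal(GenomicRanges::start(gr) - 1L, as.integer(start0))
  expect_equal(GenomicRanges::end(gr), as.integer(end0))
}
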