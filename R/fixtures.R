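## Synthetic fixture bundles and end-to-end pipeline orchestration. The
## fixture generator makes every other module testable without downloads:
## it writes an internally consistent set of genes, variants, dosages,
## weights, summary statistics, peaks, phenotype and truth, regenerable
## byte-identically from its seed.

.marginalZ <- function(X, y) {
  ## per-SNP z from marginal regression of y on each dosage column
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  sxx <- colSums(Xc^2)
  sxy <- as.vector(crossprod(Xc, yc))
  syy <- sum(yc^2)
  r2 <- ifelse(sxx > 0, sxy^2 / (sxx * syy), 0)
  tstat <- ifelse(sxx > 0, sign(sxy) * sqrt(pmax(r2, 0) * (n - 2) /
                                              pmax(1 - r2, 1e-300)), 0)
  tstat
}

.fixtureParams <- function(profile) {
  switch(profile,
    tiny = list(nGenes = 20L, m = 2000L, n = 500L, flank = 100000L,
                segLen = 5000L, blockSize = 50L, rho = 0.5,
                groupProps = c(0.005, 0.015, 0.08),
                groupH2 = c(0.5, 0.2, 0.1), gwasN = 500L),
    paper_like = list(nGenes = 20L, m = 2000L, n = 500L, flank = 100000L,
                      segLen = 5000L, blockSize = 50L, rho = 0.5,
                      groupProps = c(0.005, 0.015, 0.08),
                      groupH2 = c(0.5, 0.2, 0.1), gwasN = 10000L),
    stop("unknown fixture profile: ", profile)
  )
}

#' Generate a synthetic fixture bundle
#'
#' Writes a complete, internally consistent input set to `outdir`: gene
#' annotation, variant records, a dosage matrix, openness weights, GWAS
#' summary statistics, peak intervals (covering the top-weight decile of
#' variants, i.e. with planted enrichment), a phenotype, per-SNP truth
#' (effect sizes and heritability groups) and a JSON manifest echoing seed
#' and parameters. Both profiles use 20 genes / 2000 SNPs / 500 samples
#' with AR(1) block LD; `"tiny"` computes GWAS z-scores by marginal
#' regression on the simulated cohort, `"paper_like"` draws them from the
#' LD-aware z-score model at GWAS sample size 10000 with group proportions
#' 0.5%/1.5%/8% and heritabilities 0.5/0.2/0.1.
#'
#' @param profile `"tiny"` or `"paper_like"`.
#' @param seed integer seed; identical seed gives byte-identical files.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the file `paths`, the `params`, and the
#'   in-memory `truth`.
#' @export
makeFixture <- function(profile = c("tiny", "paper_like"), seed = 1L,
                        outdir) {
  profile <- match.arg(profile)
  par <- .fixtureParams(profile)
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  set.seed(as.integer(seed))
  ## genes every 250 kb on chr1 -> mostly disjoint 200 kb windows
  genes <- data.frame(
    gene_id = sprintf("GENE%03d", seq_len(par$nGenes)), chrom = "chr1",
    strand = rep(c("+", "-"), length.out = par$nGenes),
    tss = 200000L + (seq_len(par$nGenes) - 1L) * 250000L)
  perGene <- par$m / par$nGenes
  pos <- as.vector(vapply(genes$tss, function(t) {
    as.integer(t - par$flank + seq_len(perGene) * floor(2 * par$flank / (perGene + 1)))
  }, integer(perGene)))
  geno <- simulateGenotypes(
    ldModel("ar1_blocks", blockSizes = par$blockSize, rho = par$rho),
    n = par$n, mafs = stats::runif(par$m, 0.05, 0.5),
    seed = sample.int(2^31 - 1L, 1L))
  variants <- geno@variants
  variants$pos <- pos
  variants$chrom <- "chr1"
  geno <- genotypeData(geno@dosages, variants)
  w <- stats::rnorm(par$m)
  labels <- assignGroups(w, par$groupProps)
  eff <- drawEffects(labels, par$groupH2, seed = sample.int(2^31 - 1L, 1L))
  y <- simulatePhenotype(geno, eff$beta, h2Total = sum(par$groupH2),
                         seed = sample.int(2^31 - 1L, 1L))
  if (profile == "tiny") {
    z <- .marginalZ(.imputeMissing(geno@dosages), y)
  } else {
    ld <- simulateLD(ldModel("ar1_blocks", blockSizes = par$blockSize,
                             rho = par$rho), par$m)
    ## z-score model operates on the standardized scale; rescale beta
    sdX <- apply(geno@dosages, 2L, stats::sd)
    z <- simulateZscores(ld, eff$beta * sdX, n = par$gwasN,
                         seed = sample.int(2^31 - 1L, 1L))
  }
  paths <- list(
    genes = file.path(outdir, "genes.tsv"),
    variants = file.path(outdir, "variants.tsv"),
    dosages = file.path(outdir, "dosages.tsv"),
    weights = file.path(outdir, "weights.tsv"),
    sumstats = file.path(outdir, "sumstats.tsv"),
    peaks = file.path(outdir, "peaks.bed"),
    phenotype = file.path(outdir, "phenotype.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    manifest = file.path(outdir, "manifest.json"))
  wt <- function(d, p, col = TRUE) utils::write.table(
    d, p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = col)
  wt(genes, paths$genes)
  wt(variants, paths$variants)
  wt(data.frame(sample_id = rownames(geno@dosages), geno@dosages,
                check.names = FALSE), paths$dosages)
  wt(data.frame(snp_id = variants$snp_id, effect_allele = variants$allele_effect,
                weight = w, cell_type = "synthetic"), paths$weights)
  wt(data.frame(SNP = variants$snp_id, CHR = variants$chrom,
                POS = variants$pos, A1 = variants$allele_effect,
                A2 = variants$allele_other, Z = z, N = par$gwasN),
     paths$sumstats)
  ## peaks: 200 bp windows centered on the top-weight decile of variants
  top <- variants[order(-w)[seq_len(par$m %/% 10L)], , drop = FALSE]
  peak <- reduce(GRanges(top$chrom, IRanges(pmax(top$pos - 100L, 1L),
                                            top$pos + 100L)))
  wt(data.frame(chrom = as.character(seqnames(peak)), start = start(peak) - 1L,
                end = end(peak)), paths$peaks, col = FALSE)
  wt(data.frame(sample_id = rownames(geno@dosages), phenotype = as.vector(y)),
     paths$phenotype)
  wt(data.frame(snp_id = variants$snp_id, beta = eff$beta, group = labels,
                weight = w), paths$truth)
  manifest <- list(profile = profile, seed = as.integer(seed), params = par,
                   files = lapply(paths[names(paths) != "manifest"], basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(paths = paths, params = par,
                 truth = list(beta = eff$beta, labels = labels,
                              tau = eff$tau, groupH2 = par$groupH2,
                              weights = w)))
}

#' Run the segment-association pipeline end to end
#'
#' Orchestrates segmentation, weight harmonization, LD estimation,
#' association testing, multiple-testing adjustment and nearest-gene
#' mapping from a configuration list, writing the association table, the
#' segment BED and a JSON manifest with parameters and stage-by-stage SNP
#' accounting (`snps read = snps used + drops by reason` holds by
#' construction and is re-asserted before writing).
#'
#' @param config list with paths `genes`, `variants`, `dosages` (LD
#'   reference / cohort), `weights`, and `sumstats` (summary mode) or
#'   `phenotype` (individual mode); options `mode` ("summary", the
#'   default, or "individual"), `cellType`, `flank` (1e5), `segLen`
#'   (5000), `segMode` ("bp" or "snp_count"), `snpCountK` (20),
#'   `excludeHla` (FALSE for synthetic data), `unweighted` (FALSE),
#'   `adjust` ("bonferroni"), `alpha` (0.05), `seed`, and `outdir`.
#' @return invisibly, the manifest list (also written to
#'   `outdir/manifest.json`); the association table goes to
#'   `outdir/association.tsv`, segments to `outdir/segments.bed`.
#' @export
runPipeline <- function(config) {
  defaults <- list(mode = "summary", cellType = NULL, flank = 100000L,
                   segLen = 5000L, segMode = "bp", snpCountK = 20L,
                   excludeHla = FALSE, unweighted = FALSE,
                   adjust = "bonferroni", alpha = 0.05, seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("genes", "variants", "dosages", "weights", "outdir"))
    if (is.null(config[[nm]])) stop("config lacks required entry: ", nm)
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)

  genes <- readGeneAnnotation(config$genes)
  variants <- readVariants(config$variants)
  if (config$segMode == "snp_count") {
    segments <- tileSegmentsBySnpCount(variants, config$snpCountK)
  } else {
    regions <- buildRegulatoryRegions(genes, config$flank)
    segments <- suppressMessages(
      assignSnps(tileSegments(regions, config$segLen), variants))
  }
  if (isTRUE(config$excludeHla))
    segments <- excludeRegion(segments, "HLA_hg19")
  segments <- mapToNearestGene(segments, genes)

  weights <- loadWeights(config$weights, config$cellType)
  harmonizedW <- harmonizeAlleles(weights, variants)
  geno <- readDosages(config$dosages, config$variants)
  blocks <- ldFromGenotypes(geno, segments)

  counts <- list(
    n_variants = nrow(variants),
    n_segments = nSegments(segments),
    n_segments_empty = sum(lengths(segmentSnps(segments)) == 0L),
    weights_read = nrow(weightTable(weights)),
    weights_harmonized = nrow(harmonizedW),
    weights_drops = as.list(attr(harmonizedW, "drops")))

  if (config$mode == "summary") {
    if (is.null(config$sumstats)) stop("config lacks required entry: sumstats")
    gwasRaw <- readGwasSummary(config$sumstats)
    gwas <- harmonizeGwas(gwasRaw, variants)
    counts$gwas_read <- nrow(gwasRaw)
    counts$gwas_harmonized <- nrow(gwas)
    counts$gwas_drops <- as.list(attr(gwas, "drops"))
    stopifnot(counts$gwas_read ==
                counts$gwas_harmonized + sum(attr(gwas, "drops")))
    assoc <- if (isTRUE(config$unweighted))
      unweightedAssociation(gwas, blocks, segments)
    else owasSummary(gwas, harmonizedW, blocks, segments)
    counts$segment_snp_drops <- as.list(attr(assoc, "drops"))
  } else if (config$mode == "individual") {
    if (is.null(config$phenotype)) stop("config lacks required entry: phenotype")
    ph <- utils::read.delim(config$phenotype, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "phenotype") %in% names(ph)))
      stop("phenotype file needs columns sample_id, phenotype")
    y <- ph$phenotype[match(rownames(dosages(geno)), ph$sample_id)]
    if (anyNA(y)) stop("phenotype missing for some genotyped samples")
    O <- computeOpenness(geno, harmonizedW, segments)
    assoc <- owasIndividual(O, y, segments = segments)
  } else stop("unknown mode: ", config$mode)

  assoc <- adjustPvalues(assoc, method = config$adjust, alpha = config$alpha)
  counts$segments_tested <- sum(!is.na(assoc$p))
  counts$segments_skipped <- sum(is.na(assoc$p))
  stopifnot(counts$n_segments == counts$segments_tested + counts$segments_skipped)

  assocPath <- file.path(config$outdir, "association.tsv")
  bedPath <- file.path(config$outdir, "segments.bed")
  writeAssociation(assoc, segments, assocPath)
  writeSegmentsBed(segments, bedPath)
  inputs <- config[c("genes", "variants", "dosages", "weights")]
  if (config$mode == "summary") inputs$sumstats <- config$sumstats
  if (config$mode == "individual") inputs$phenotype <- config$phenotype
  manifest <- list(
    package_version = as.character(utils::packageVersion("openwas")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c(names(inputs), "outdir"))],
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    counts = counts,
    outputs = list(association = basename(assocPath),
                   segments = basename(bedPath)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message(sprintf("tested %d/%d segments; %d significant at alpha=%g (%s)",
                  counts$segments_tested, counts$n_segments,
                  sum(assoc$significant, na.rm = TRUE), config$alpha,
                  config$adjust))
  invisible(manifest)
}
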