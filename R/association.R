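## Segment-level association tests: exact regression route from
## individual-level data, and the summary-statistic approximation that only
## needs GWAS z-scores plus an LD reference.

.assocFrame <- function(segment_id, Z, p, n_snps_used, sigma_s, note,
                        nearest_gene = NA_character_) {
  data.frame(segment_id = segment_id, Z = Z, p = p, p_adj = NA_real_,
             significant = NA, n_snps_used = n_snps_used,
             sigma_s = sigma_s, nearest_gene = nearest_gene,
             note = note, stringsAsFactors = FALSE)
}

.attachGenes <- function(assoc, segments) {
  if (is.null(segments)) return(assoc)
  gr <- segmentRanges(segments)
  if (!is.null(gr$nearest_gene))
    assoc$nearest_gene <- gr$nearest_gene[match(assoc$segment_id, gr$segment_id)]
  assoc
}

#' Segment association from individual-level data
#'
#' For each segment s, fits the linear phenotype model
#' \eqn{Y = \alpha + O_s \gamma_s + \epsilon} by ordinary least squares
#' (binary phenotypes are fitted with the same linear model on 0/1) and
#' reports \eqn{Z_s = \hat\gamma_s / se(\hat\gamma_s)} with a two-sided
#' p-value from the standard normal reference. Covariates, when given, are
#' residualized out of both Y and the openness scores (Frisch–Waugh), with
#' degrees of freedom adjusted accordingly, so estimates and standard
#' errors match the full joint regression.
#'
#' Zero-variance openness columns are skipped with note
#' `"degenerate openness"`. A numerically perfect fit is reported at the
#' smallest positive double with note `"saturated"`.
#'
#' @param openness an [OpennessMatrix] or a plain samples x segments matrix.
#' @param y numeric phenotype vector (quantitative, or 0/1 for binary).
#' @param covariates optional numeric matrix of covariates (no intercept
#'   column; one is always included).
#' @param segments optional [SegmentSet] used to propagate nearest-gene
#'   annotations into the result.
#' @return data.frame with one row per segment: `segment_id`, `Z`, `p`,
#'   `p_adj` (NA until [adjustPvalues()]), `significant`, `n_snps_used`,
#'   `sigma_s` (sample sd of the openness scores), `nearest_gene`, `note`.
#' @export
owasIndividual <- function(openness, y, covariates = NULL, segments = NULL) {
  if (is(openness, "OpennessMatrix")) {
    O <- openness@scores
    nUsed <- openness@nSnpsUsed
  } else {
    O <- as.matrix(openness)
    nUsed <- rep(NA_integer_, ncol(O))
  }
  y <- as.numeric(y)
  n <- nrow(O)
  if (length(y) != n) stop("phenotype length must match sample count")
  if (n < 30L) stop("need at least 30 samples for the normal reference")
  ids <- colnames(O)
  if (is.null(ids)) ids <- sprintf("seg%04d", seq_len(ncol(O)))
  sigma <- apply(O, 2L, stats::sd)
  q <- 0L
  if (!is.null(covariates)) {
    W <- cbind(1, as.matrix(covariates))
    q <- ncol(W) - 1L
    qrW <- qr(W)
    y <- qr.resid(qrW, y)
    O <- qr.resid(qrW, O)
  } else {
    y <- y - mean(y)
    O <- sweep(O, 2L, colMeans(O))
  }
  df <- n - 2L - q
  Sxx <- colSums(O^2)
  Sxy <- as.vector(crossprod(O, y))
  Syy <- sum(y^2)
  eps <- .Machine$double.eps
  degenerate <- Sxx <= n * eps * max(1, mean(abs(Sxx)))
  gamma <- ifelse(degenerate, NA_real_, Sxy / Sxx)
  rss <- pmax(Syy - Sxy^2 / Sxx, 0)
  saturated <- !degenerate & rss <= Syy * 1e-12
  se <- sqrt((rss / df) / Sxx)
  Z <- gamma / se
  Z[saturated] <- sign(gamma[saturated]) * .Machine$double.xmax^0.25
  p <- 2 * stats::pnorm(-abs(Z))
  p <- pmax(p, .Machine$double.xmin)
  note <- rep("", length(ids))
  note[degenerate] <- "degenerate openness"
  note[saturated] <- "saturated"
  Z[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  out <- .assocFrame(ids, Z, p, nUsed, sigma, note)
  .attachGenes(out, segments)
}

#' Estimate per-segment LD blocks from reference genotypes
#'
#' Computes, for every non-empty segment, the SNP correlation matrix R and
#' the per-SNP dosage standard deviations from a reference genotype panel
#' (missing dosages mean-imputed). R entries are defensively clipped to
#' `[-1, 1]`; a zero-variance SNP gets zero off-diagonal correlation.
#'
#' @param genotypes a [GenotypeData] serving as LD reference.
#' @param segments a [SegmentSet] with SNPs assigned.
#' @return named list of [LDBlock], one per segment with at least one SNP
#'   present in the panel.
#' @export
ldFromGenotypes <- function(genotypes, segments) {
  stopifnot(is(genotypes, "GenotypeData"), is(segments, "SegmentSet"))
  X <- .imputeMissing(genotypes@dosages)
  segSnps <- segmentSnps(segments)
  ids <- segmentIds(segments)
  blocks <- list()
  for (s in seq_along(ids)) {
    snps <- segSnps[[s]]
    snps <- snps[snps %in% colnames(X)]
    if (length(snps) == 0L) next
    Xs <- X[, snps, drop = FALSE]
    sds <- apply(Xs, 2L, stats::sd)
    R <- suppressWarnings(stats::cor(Xs))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    R[R > 1] <- 1; R[R < -1] <- -1
    R <- (R + t(R)) / 2
    blocks[[ids[s]]] <- new("LDBlock", segmentId = ids[s], snpIds = snps,
                            R = R, sd = unname(sds))
  }
  blocks
}

#' Standard deviation of a segment openness score from LD
#'
#' Evaluates the quadratic-form identity
#' \eqn{\hat\sigma_s = \sqrt{\sum_{j,k} w_j w_k \hat\sigma_j \hat\sigma_k
#' R_{jk}}} — the sample sd of \eqn{O_s} expressed through the per-SNP sds
#' and the LD matrix, with no genotypes needed. Returns 0 iff the weights
#' (or all sds) vanish.
#'
#' @param w numeric weights: either named by SNP id (matched to the block,
#'   absent SNPs treated as 0) or unnamed in block order.
#' @param block an [LDBlock].
#' @return the nonnegative scalar \eqn{\hat\sigma_s}.
#' @export
segmentSd <- function(w, block) {
  stopifnot(is(block, "LDBlock"))
  k <- length(block@snpIds)
  if (!is.null(names(w))) {
    wv <- numeric(k)
    idx <- match(block@snpIds, names(w))
    wv[!is.na(idx)] <- w[idx[!is.na(idx)]]
  } else {
    if (length(w) != k) stop("unnamed w must match block SNP count")
    wv <- as.numeric(w)
  }
  ws <- wv * block@sd
  v <- as.numeric(crossprod(ws, block@R %*% ws))
  if (!is.finite(v))
    stop("non-finite openness variance for segment ", block@segmentId)
  sqrt(max(v, 0))
}

#' Harmonize GWAS z-scores to the dosage allele coding
#'
#' Aligns summary-statistic z-scores to the effect allele that dosages (and
#' harmonized weights) count: a z whose effect allele is the dosage other
#' allele has its sign flipped; unresolvable allele pairs are dropped, and
#' strand-ambiguous SNPs are dropped by default. Every flip and drop is
#' counted in the `"drops"` attribute.
#'
#' @param gwas data.frame with `snp_id`, `effect_allele`, `other_allele`,
#'   `z`, and optionally `n`.
#' @param variants data.frame with the dosage coding (`snp_id`,
#'   `allele_effect`, `allele_other`).
#' @param allowAmbiguous keep strand-ambiguous SNPs.
#' @return data.frame (`snp_id`, `z`, `n`, `flipped`) with attribute
#'   `"drops"`.
#' @export
harmonizeGwas <- function(gwas, variants, allowAmbiguous = FALSE) {
  gwas <- as.data.frame(gwas)
  need <- c("snp_id", "effect_allele", "other_allele", "z")
  miss <- setdiff(need, names(gwas))
  if (length(miss) > 0L)
    stop("GWAS table lacks column(s): ", paste(miss, collapse = ", "))
  variants <- as.data.frame(variants)
  idx <- match(gwas$snp_id, variants$snp_id)
  drops <- c(not_in_variants = sum(is.na(idx)))
  keep <- !is.na(idx)
  g <- gwas[keep, , drop = FALSE]
  v <- variants[idx[keep], , drop = FALSE]
  same <- g$effect_allele == v$allele_effect & g$other_allele == v$allele_other
  swapped <- g$effect_allele == v$allele_other & g$other_allele == v$allele_effect
  ambiguous <- .isAmbiguous(v$allele_effect, v$allele_other)
  usable <- same | swapped
  drops <- c(drops, allele_mismatch = sum(!usable))
  if (!allowAmbiguous) {
    drops <- c(drops, strand_ambiguous = sum(ambiguous & usable))
    usable <- usable & !ambiguous
  } else {
    drops <- c(drops, strand_ambiguous = 0L)
  }
  out <- data.frame(
    snp_id = g$snp_id[usable],
    z = ifelse(same[usable], g$z[usable], -g$z[usable]),
    n = if ("n" %in% names(g)) g$n[usable] else NA_real_,
    flipped = swapped[usable],
    stringsAsFactors = FALSE
  )
  attr(out, "drops") <- drops
  out
}

#' Segment association from GWAS summary statistics
#'
#' The summary-statistic approximation of the segment test:
#' \eqn{Z_s = \sum_{j \in \Omega_s} (w_j \hat\sigma_j / \hat\sigma_s) z_j},
#' where \eqn{z_j} are per-SNP GWAS z-scores, \eqn{\hat\sigma_j} per-SNP
#' dosage sds from the LD reference and \eqn{\hat\sigma_s} the segment
#' openness sd from [segmentSd()]. Requires no individual-level data and no
#' LD-matrix inversion. GWAS z-scores must already be harmonized to the
#' dosage coding (see [harmonizeGwas()]); weights must be harmonized signed
#' weights (see [harmonizeAlleles()]).
#'
#' Segment SNPs missing from the GWAS, the LD block, or the weight set are
#' dropped and counted; segments with \eqn{\hat\sigma_s = 0} (or no usable
#' SNP) are skipped with note `"degenerate"`.
#'
#' @param gwas harmonized GWAS table (`snp_id`, `z`).
#' @param w harmonized signed weights (data.frame `snp_id`/`weight` or a
#'   named numeric vector).
#' @param blocks named list of [LDBlock] (names are segment ids), e.g. from
#'   [ldFromGenotypes()].
#' @param segments a [SegmentSet] with SNPs assigned.
#' @return data.frame as in [owasIndividual()]; attribute `"drops"` counts
#'   SNPs dropped by reason.
#' @export
owasSummary <- function(gwas, w, blocks, segments) {
  stopifnot(is(segments, "SegmentSet"))
  gwas <- as.data.frame(gwas)
  if (!all(c("snp_id", "z") %in% names(gwas)))
    stop("harmonized GWAS table needs columns snp_id, z")
  if (any(!is.finite(gwas$z))) stop("GWAS z-scores must be finite")
  if (is.data.frame(w)) w <- stats::setNames(w$weight, w$snp_id)
  z <- stats::setNames(gwas$z, gwas$snp_id)
  segSnps <- segmentSnps(segments)
  ids <- segmentIds(segments)
  rows <- vector("list", length(ids))
  drops <- c(no_gwas = 0L, no_ld = 0L, no_weight = 0L)
  for (s in seq_along(ids)) {
    snps <- segSnps[[s]]
    block <- blocks[[ids[s]]]
    if (is.null(block)) {
      drops["no_ld"] <- drops["no_ld"] + length(snps)
      rows[[s]] <- .assocFrame(ids[s], NA_real_, NA_real_, 0L, NA_real_,
                               "degenerate")
      next
    }
    inLd <- snps %in% block@snpIds
    drops["no_ld"] <- drops["no_ld"] + sum(!inLd)
    snps <- snps[inLd]
    inG <- snps %in% names(z)
    drops["no_gwas"] <- drops["no_gwas"] + sum(!inG)
    snps <- snps[inG]
    inW <- snps %in% names(w)
    drops["no_weight"] <- drops["no_weight"] + sum(!inW)
    snps <- snps[inW]
    if (length(snps) == 0L) {
      rows[[s]] <- .assocFrame(ids[s], NA_real_, NA_real_, 0L, NA_real_,
                               "degenerate")
      next
    }
    bi <- match(snps, block@snpIds)
    sub <- new("LDBlock", segmentId = ids[s], snpIds = snps,
               R = block@R[bi, bi, drop = FALSE], sd = block@sd[bi])
    sigmaS <- segmentSd(w[snps], sub)
    if (sigmaS <= 0) {
      rows[[s]] <- .assocFrame(ids[s], NA_real_, NA_real_,
                               length(snps), sigmaS, "degenerate")
      next
    }
    Z <- sum(w[snps] * sub@sd * z[snps]) / sigmaS
    p <- max(2 * stats::pnorm(-abs(Z)), .Machine$double.xmin)
    rows[[s]] <- .assocFrame(ids[s], Z, p, length(snps), sigmaS, "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "drops") <- drops
  .attachGenes(out, segments)
}

#' Unweighted segment association baseline
#'
#' Identical to [owasSummary()] with every SNP weight set to 1 — the
#' comparison baseline that treats all SNPs in a segment equally.
#'
#' @inheritParams owasSummary
#' @return data.frame as in [owasSummary()].
#' @export
unweightedAssociation <- function(gwas, blocks, segments) {
  allSnps <- unique(unlist(segmentSnps(segments), use.names = FALSE))
  w <- stats::setNames(rep(1, length(allSnps)), allSnps)
  owasSummary(gwas, w, blocks, segments)
}

#' Multiple-testing adjustment of segment p-values
#'
#' Bonferroni (default, `p_adj = min(1, p * S)` over the S tested segments)
#' or Benjamini–Hochberg step-up, with a significance flag at `alpha`.
#' Segments with NA p (skipped) are excluded from the correction count.
#'
#' @param assoc association data.frame from [owasIndividual()] /
#'   [owasSummary()].
#' @param method `"bonferroni"` or `"bh"`.
#' @param alpha significance level, default 0.05.
#' @return the data.frame with `p_adj` and `significant` filled.
#' @export
adjustPvalues <- function(assoc, method = c("bonferroni", "bh"),
                          alpha = 0.05) {
  method <- match.arg(method)
  if (nrow(assoc) == 0L) stop("no associations to adjust")
  ok <- !is.na(assoc$p)
  assoc$p_adj <- NA_real_
  assoc$p_adj[ok] <- stats::p.adjust(
    assoc$p[ok], method = if (method == "bonferroni") "bonferroni" else "BH")
  assoc$significant <- assoc$p_adj < alpha
  assoc
}
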