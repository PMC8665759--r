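## Synthetic LD, genotypes, openness-stratified effect sizes, GWAS
## z-scores, and the type-I-error harness.
##
## The generative world mirrors the published simulation design: among m
## SNPs, 90% are null (C0); the rest split into three groups by rank of
## |openness weight| — top 0.5% (C1), next 1.5% (C2), next 8% (C3) — with
## per-group heritabilities 0.5 / 0.2 / 0.1 spread equally within group
## (tau_k = h2(C_k) / M(C_k)); z-scores are then drawn from
## z | R, beta ~ N(sqrt(n) R beta, R) with n = 10000 by default.

#' Describe a synthetic LD model
#'
#' @param kind `"independent"` (identity), `"ar1_blocks"` (within-block
#'   AR(1) correlation `rho^|j-k|`, zero across blocks) or
#'   `"from_genotypes"` (estimate from a genotype panel via
#'   [ldFromGenotypes()] instead of simulating).
#' @param blockSizes block sizes, recycled to cover all SNPs (desk-scale
#'   stand-in for reference-panel LD; default blocks of 50).
#' @param rho AR(1) correlation in (-1, 1), default 0.5.
#' @param mafRange range minor-allele frequencies are drawn from.
#' @return an object of class `ldModel`.
#' @export
ldModel <- function(kind = c("ar1_blocks", "independent", "from_genotypes"),
                    blockSizes = 50L, rho = 0.5,
                    mafRange = c(0.05, 0.5)) {
  kind <- match.arg(kind)
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  if (any(blockSizes < 1)) stop("block sizes must be >= 1")
  structure(list(kind = kind, blockSizes = as.integer(blockSizes),
                 rho = rho, mafRange = mafRange), class = "ldModel")
}

.blockSizesFor <- function(model, m) {
  if (model$kind == "independent") return(rep(1L, m))
  sizes <- rep(model$blockSizes,
               length.out = ceiling(m / min(model$blockSizes)))
  keep <- cumsum(sizes) < m
  out <- c(sizes[keep], m - sum(sizes[keep]))
  out[out > 0L]
}

#' Simulate a block-diagonal LD correlation structure
#'
#' Builds the SNP correlation matrix for `m` SNPs under an [ldModel], kept
#' as a list of diagonal blocks so memory stays linear in block size.
#' Every block is checked positive semi-definite (smallest eigenvalue
#' >= -1e-8).
#'
#' @param model an [ldModel] (`"from_genotypes"` is not simulable here).
#' @param m number of SNPs.
#' @return object of class `ldStructure`: list with `blocks` (correlation
#'   matrices), `sizes`, `blockIndex` (block id per SNP) and `m`.
#' @export
simulateLD <- function(model, m) {
  stopifnot(inherits(model, "ldModel"))
  if (model$kind == "from_genotypes")
    stop("use ldFromGenotypes() for genotype-estimated LD")
  sizes <- .blockSizesFor(model, m)
  blocks <- lapply(sizes, function(k) {
    if (model$kind == "independent" || k == 1L) return(diag(1, k))
    R <- model$rho^abs(outer(seq_len(k), seq_len(k), "-"))
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("simulated LD block is not positive semi-definite")
    R
  })
  structure(list(blocks = blocks, sizes = sizes,
                 blockIndex = rep(seq_along(sizes), sizes), m = as.integer(m)),
            class = "ldStructure")
}

#' Dense LD matrix from an ldStructure
#'
#' @param ld an `ldStructure`.
#' @return the full m x m correlation matrix (use only at small m).
#' @export
ldMatrix <- function(ld) {
  R <- matrix(0, ld$m, ld$m)
  off <- 0L
  for (b in seq_along(ld$blocks)) {
    k <- ld$sizes[b]
    R[off + seq_len(k), off + seq_len(k)] <- ld$blocks[[b]]
    off <- off + k
  }
  R
}

#' Per-segment LD blocks from a simulated LD structure
#'
#' Extracts, for each segment, the theoretical correlation submatrix of its
#' SNPs (zero across simulation blocks) and pairs it with per-SNP sds
#' (default 1, the scale on which the z-score model operates).
#'
#' @param ld an `ldStructure`.
#' @param segments a [SegmentSet] whose SNP ids appear in `snpIds`.
#' @param snpIds character vector giving the global SNP order of `ld`.
#' @param sd per-SNP sds in the same order, default all 1.
#' @return named list of [LDBlock].
#' @export
ldBlocksFromStructure <- function(ld, segments, snpIds, sd = NULL) {
  stopifnot(inherits(ld, "ldStructure"), is(segments, "SegmentSet"))
  if (length(snpIds) != ld$m) stop("snpIds must cover all simulated SNPs")
  if (is.null(sd)) sd <- rep(1, ld$m)
  offsets <- c(0L, cumsum(ld$sizes))
  segSnps <- segmentSnps(segments)
  ids <- segmentIds(segments)
  blocks <- list()
  for (s in seq_along(ids)) {
    snps <- segSnps[[s]]
    g <- match(snps, snpIds)
    if (anyNA(g)) stop("segment ", ids[s], " holds SNPs unknown to the LD structure")
    k <- length(g)
    if (k == 0L) next
    R <- diag(1, k)
    bIdx <- ld$blockIndex[g]
    for (b in unique(bIdx)) {
      sel <- which(bIdx == b)
      loc <- g[sel] - offsets[b]
      R[sel, sel] <- ld$blocks[[b]][loc, loc, drop = FALSE]
    }
    blocks[[ids[s]]] <- new("LDBlock", segmentId = ids[s], snpIds = snps,
                            R = R, sd = sd[g])
  }
  blocks
}

#' Stratify SNPs into heritability groups by openness-weight rank
#'
#' Ranks SNPs by `|w|` descending (ties broken by SNP index) and labels the
#' top `groupProps[1]` fraction as group 1 (high heritability), the next
#' `groupProps[2]` as group 2, the next `groupProps[3]` as group 3; the
#' remainder (default 90%) is the null group 0. Defaults are 0.5%, 1.5%
#' and 8%. Group sizes are rounded proportionally with at least one SNP
#' per group with positive proportion.
#'
#' @param w numeric openness weights.
#' @param groupProps proportions of SNPs in groups 1..3.
#' @return integer vector of labels in `{0, 1, 2, 3}`, same length as `w`.
#' @export
assignGroups <- function(w, groupProps = c(0.005, 0.015, 0.08)) {
  m <- length(w)
  if (sum(groupProps) >= 1) stop("group proportions must sum to < 1")
  sizes <- round(m * groupProps)
  sizes[groupProps > 0 & sizes == 0L] <- 1L
  if (sum(sizes) > m) stop("fewer SNPs than needed to fill the groups")
  ord <- order(-abs(w), seq_len(m))
  labels <- integer(m)
  off <- 0L
  for (k in seq_along(sizes)) {
    labels[ord[off + seq_len(sizes[k])]] <- k
    off <- off + sizes[k]
  }
  labels
}

#' Draw group-stratified SNP effect sizes
#'
#' For each associated group k, effects are drawn i.i.d. from
#' \eqn{N(0, \tau_k)} with \eqn{\tau_k = h^2(C_k) / M(C_k)}, so the
#' expected summed squared effect of group k is exactly its heritability
#' budget. Null-group SNPs get effect 0. Default group heritabilities are
#' 0.5, 0.2 and 0.1.
#'
#' @param labels group labels from [assignGroups()].
#' @param groupH2 per-group heritabilities, one per positive group.
#' @param seed integer seed.
#' @return list with `beta` (per-SNP effects), `labels`, `tau` (per-group
#'   variances) and `groupH2`.
#' @export
drawEffects <- function(labels, groupH2 = c(0.5, 0.2, 0.1), seed = 1L) {
  K <- length(groupH2)
  if (any(groupH2 < 0)) stop("group heritabilities must be >= 0")
  if (sum(groupH2) > 1) stop("group heritabilities must sum to <= 1")
  set.seed(as.integer(seed))
  beta <- numeric(length(labels))
  tau <- numeric(K)
  for (k in seq_len(K)) {
    Mk <- sum(labels == k)
    if (Mk == 0L) {
      if (groupH2[k] > 0) stop("group ", k, " is empty but has positive h2")
      next
    }
    tau[k] <- groupH2[k] / Mk
    beta[labels == k] <- stats::rnorm(Mk, 0, sqrt(tau[k]))
  }
  list(beta = beta, labels = labels, tau = tau, groupH2 = groupH2)
}

#' Simulate GWAS z-scores under LD
#'
#' One draw from the standard summary-statistic model
#' \eqn{z \mid R, \beta \sim N(\sqrt{n}\, R \beta,\; R)}, sampled block by
#' block via the Cholesky factor of each LD block. With \eqn{\beta = 0}
#' this yields exactly the null z ~ N(0, R).
#'
#' @param ld an `ldStructure`.
#' @param beta per-SNP effect sizes.
#' @param n GWAS sample size, default 10000.
#' @param seed integer seed.
#' @return numeric z-score vector of length m.
#' @export
simulateZscores <- function(ld, beta, n = 10000L, seed = 1L) {
  stopifnot(inherits(ld, "ldStructure"))
  if (length(beta) != ld$m) stop("beta must have one entry per SNP")
  set.seed(as.integer(seed))
  z <- numeric(ld$m)
  off <- 0L
  for (b in seq_along(ld$blocks)) {
    k <- ld$sizes[b]
    R <- ld$blocks[[b]]
    U <- tryCatch(chol(R), error = function(e)
      stop("LD block ", b, " is not positive definite"))
    mu <- sqrt(n) * as.vector(R %*% beta[off + seq_len(k)])
    z[off + seq_len(k)] <- mu + as.vector(crossprod(U, stats::rnorm(k)))
    off <- off + k
  }
  z
}

#' Simulate genotype dosages with target LD and MAFs
#'
#' Draws two latent Gaussian haplotypes per individual with the model's
#' block correlation, thresholds each at the allele-frequency quantile and
#' sums the allele indicators into dosages in `{0, 1, 2}`. Realized dosage
#' correlations track the latent target up to the usual thresholding
#' attenuation.
#'
#' @param model an [ldModel].
#' @param n number of individuals.
#' @param mafs per-SNP effect-allele frequencies in (0, 0.5].
#' @param seed integer seed.
#' @param chrom,posStart,posSpacing coordinates given to the synthetic
#'   variants (defaults: chr1 from 1e6, one SNP every 250 bp — about 20
#'   SNPs per 5 kb segment).
#' @return a [GenotypeData] with variants `snp000001`, ... (alleles A/G).
#' @export
simulateGenotypes <- function(model, n, mafs, seed = 1L, chrom = "chr1",
                              posStart = 1000000L, posSpacing = 250L) {
  stopifnot(inherits(model, "ldModel"))
  if (any(mafs <= 0 | mafs > 0.5)) stop("MAFs must lie in (0, 0.5]")
  m <- length(mafs)
  set.seed(as.integer(seed))
  ld <- simulateLD(model, m)
  X <- matrix(0L, n, m)
  thr <- stats::qnorm(mafs)
  off <- 0L
  for (b in seq_along(ld$blocks)) {
    k <- ld$sizes[b]
    U <- chol(ld$blocks[[b]])
    cols <- off + seq_len(k)
    for (h in 1:2) {
      G <- matrix(stats::rnorm(n * k), n, k) %*% U
      X[, cols] <- X[, cols] + (sweep(G, 2L, thr[cols], "<") * 1L)
    }
    off <- off + k
  }
  snpIds <- sprintf("snp%06d", seq_len(m))
  variants <- data.frame(
    snp_id = snpIds, chrom = chrom,
    pos = posStart + (seq_len(m) - 1L) * posSpacing,
    allele_effect = "A", allele_other = "G",
    stringsAsFactors = FALSE
  )
  dimnames(X) <- list(sprintf("ind%05d", seq_len(n)), snpIds)
  new("GenotypeData", dosages = X, variants = variants)
}

#' Simulate a quantitative phenotype with fixed heritability
#'
#' Forms the genetic value \eqn{g = X\beta} and adds Gaussian noise whose
#' variance is chosen so that \eqn{Var(g)/Var(Y)} equals `h2Total` (using
#' the realized genetic variance). The returned phenotype is standardized
#' to mean 0, sd 1 (an affine transform that leaves all Z-scores
#' unchanged).
#'
#' @param genotypes a [GenotypeData] or a plain dosage matrix.
#' @param beta per-SNP effects.
#' @param h2Total target heritability in `[0, 1)`; default 0.8, the sum of
#'   the default group heritabilities.
#' @param seed integer seed.
#' @return standardized numeric phenotype with attribute `"h2_realized"`.
#' @export
simulatePhenotype <- function(genotypes, beta, h2Total = 0.8, seed = 1L) {
  X <- if (is(genotypes, "GenotypeData")) genotypes@dosages else as.matrix(genotypes)
  if (h2Total < 0 || h2Total >= 1) stop("h2Total must lie in [0, 1)")
  set.seed(as.integer(seed))
  n <- nrow(X)
  g <- as.vector(.imputeMissing(X) %*% beta)
  vg <- stats::var(g)
  if (vg == 0 || h2Total == 0) {
    y <- stats::rnorm(n)
    h2r <- 0
  } else {
    e <- stats::rnorm(n, 0, sqrt(vg * (1 - h2Total) / h2Total))
    y <- g + e
    h2r <- vg / stats::var(y)
  }
  out <- as.vector(scale(y))
  attr(out, "h2_realized") <- h2r
  out
}

#' Type-I-error harness for the segment test
#'
#' Calibration study of the individual-level segment test under the null:
#' for each segment size, genotypes for `nSegments` independent segments
#' are simulated once, openness weights are drawn from N(0, 1), and in each
#' of `nReps` replicates a phenotype independent of the genotypes is drawn
#' and every segment is tested. Defaults follow the published design —
#' segment sizes 5, 20 and 50 SNPs, 100 segments, 1000 replicates — with
#' the cohort size exposed (`n`, default 1000) since null calibration does
#' not depend on it at these scales.
#'
#' @param segmentSizes SNPs per segment to study.
#' @param nSegments segments per size.
#' @param nReps null replicates per size.
#' @param n cohort size.
#' @param alpha nominal levels to tabulate.
#' @param rho AR(1) LD within each simulated segment.
#' @param seed integer seed.
#' @return list with `rates` (data.frame: `segment_size`, `alpha`,
#'   `n_tests`, `n_reject`, `rate`) and `zscores` (per size, all
#'   `nSegments * nReps` null segment Z-scores).
#' @export
type1Harness <- function(segmentSizes = c(5L, 20L, 50L), nSegments = 100L,
                         nReps = 1000L, n = 1000L, alpha = c(0.05, 0.01),
                         rho = 0.5, seed = 1L) {
  set.seed(as.integer(seed))
  rates <- list(); zscores <- list()
  for (size in segmentSizes) {
    m <- size * nSegments
    geno <- simulateGenotypes(ldModel("ar1_blocks", blockSizes = size, rho = rho),
                              n = n, mafs = stats::runif(m, 0.05, 0.5),
                              seed = sample.int(2^31 - 1L, 1L))
    w <- stats::rnorm(m)
    X <- geno@dosages
    O <- matrix(0, n, nSegments)
    for (s in seq_len(nSegments)) {
      cols <- (s - 1L) * size + seq_len(size)
      O[, s] <- X[, cols, drop = FALSE] %*% w[cols]
    }
    colnames(O) <- sprintf("size%d_seg%03d", size, seq_len(nSegments))
    Zall <- matrix(NA_real_, nReps, nSegments)
    for (r in seq_len(nReps)) {
      y <- stats::rnorm(n)
      Zall[r, ] <- owasIndividual(O, y)$Z
    }
    z <- as.vector(Zall)
    p <- 2 * stats::pnorm(-abs(z))
    for (a in alpha) {
      rates[[length(rates) + 1L]] <- data.frame(
        segment_size = size, alpha = a, n_tests = length(p),
        n_reject = sum(p < a, na.rm = TRUE),
        rate = mean(p < a, na.rm = TRUE))
    }
    zscores[[as.character(size)]] <- z
  }
  list(rates = do.call(rbind, rates), zscores = zscores)
}
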