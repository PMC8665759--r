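## Evaluation harnesses: heritability-explained ranking curves against
## simulation truth, method comparison, and the two-cohort replication-rate
## binomial analysis.

.quadFormLD <- function(ld, beta, idx, sd) {
  ## beta_S' (D R D) beta_S over selected global indices, blockwise
  if (length(idx) == 0L) return(0)
  offsets <- c(0L, cumsum(ld$sizes))
  bIdx <- ld$blockIndex[idx]
  total <- 0
  for (b in unique(bIdx)) {
    sel <- idx[bIdx == b]
    loc <- sel - offsets[b]
    v <- beta[sel] * sd[sel]
    R <- ld$blocks[[b]][loc, loc, drop = FALSE]
    total <- total + as.numeric(crossprod(v, R %*% v))
  }
  total
}

#' Heritability-explained curve for a segment ranking
#'
#' Ranks segments by ascending p-value (ties by |Z| descending, then
#' segment id; untested segments last) and, for each target proportion of
#' SNPs, computes the true heritability explained by the union S of the
#' selected segments' SNPs: \eqn{\beta_S' \Sigma_S \beta_S / Var(Y)} with
#' \eqn{\Sigma = D R D} built from the simulation LD and per-SNP sds.
#' `Var(Y)` defaults to the total genetic variance divided by `h2Total`,
#' so selecting everything explains exactly `h2Total`. Available only when
#' simulation truth (\eqn{\beta}) is known; estimating heritability on real
#' cohorts is out of scope.
#'
#' @param assoc association data.frame (`segment_id`, `Z`, `p`).
#' @param truth effect-size truth from [drawEffects()] (uses `beta` and,
#'   for the default `Var(Y)`, `groupH2`), or a plain list with `beta`.
#' @param ld the `ldStructure` the z-scores were simulated under.
#' @param segments the [SegmentSet] that was tested.
#' @param snpIds global SNP ids in `ld` order.
#' @param proportions SNP-proportion cutoffs of the curve.
#' @param sd per-SNP sds (default 1, the z-score scale).
#' @param h2Total total trait heritability; default `sum(truth$groupH2)`.
#' @param label method label carried on the curve.
#' @return object of class `rankingCurve`: list with `label` and `points`
#'   (data.frame `proportion`, `explained`, `n_segments`).
#' @export
heritabilityCurve <- function(assoc, truth, ld, segments, snpIds,
                              proportions = seq(0.01, 1, by = 0.01),
                              sd = NULL, h2Total = NULL, label = "owas") {
  stopifnot(inherits(ld, "ldStructure"), is(segments, "SegmentSet"))
  if (is.null(truth$beta)) stop("simulation truth (beta) is required")
  beta <- truth$beta
  if (length(beta) != ld$m) stop("beta must have one entry per SNP")
  if (is.null(sd)) sd <- rep(1, ld$m)
  if (is.null(h2Total)) {
    if (is.null(truth$groupH2)) stop("give h2Total or truth with groupH2")
    h2Total <- sum(truth$groupH2)
  }
  segSnps <- segmentSnps(segments)
  ids <- segmentIds(segments)
  a <- assoc[match(ids, assoc$segment_id), , drop = FALSE]
  ord <- order(is.na(a$p), a$p, -abs(a$Z), ids)
  snpCounts <- lengths(segSnps)[ord]
  totalSnps <- sum(lengths(segSnps))
  cumProp <- cumsum(snpCounts) / totalSnps
  gvarTotal <- .quadFormLD(ld, beta, match(unlist(segSnps, use.names = FALSE),
                                           snpIds), sd)
  varY <- if (h2Total > 0) gvarTotal / h2Total else Inf
  pts <- vapply(proportions, function(pr) {
    k <- sum(cumProp <= pr + 1e-12)
    if (k == 0L) return(c(0, 0))
    snps <- unlist(segSnps[ord[seq_len(k)]], use.names = FALSE)
    idx <- match(snps, snpIds)
    c(.quadFormLD(ld, beta, idx, sd) / varY, k)
  }, numeric(2))
  structure(list(label = label,
                 points = data.frame(proportion = proportions,
                                     explained = pts[1L, ],
                                     n_segments = as.integer(pts[2L, ]))),
            class = "rankingCurve")
}

#' @export
print.rankingCurve <- function(x, ...) {
  cat(sprintf("rankingCurve '%s' with %d cutoffs (explained at max: %.4f)\n",
              x$label, nrow(x$points), x$points$explained[nrow(x$points)]))
  invisible(x)
}

#' Align and compare heritability curves across methods
#'
#' Takes a list of [heritabilityCurve()] results — possibly several
#' replicates per method label — aligns them at their common proportions
#' (curves with differing proportion grids are refused rather than
#' interpolated), and tabulates the per-method mean curve. When exactly two
#' labels with equal replicate counts are present, paired per-replicate
#' differences (first label minus second) with Monte-Carlo standard errors
#' are appended.
#'
#' @param curves list of `rankingCurve` objects.
#' @return data.frame with `proportion`, one `mean_<label>` column per
#'   method, and for two-method comparisons `diff_mean`, `diff_se` and
#'   `n_replicates`.
#' @export
compareMethods <- function(curves) {
  if (inherits(curves, "rankingCurve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "rankingCurve")))
  props <- curves[[1L]]$points$proportion
  for (cv in curves)
    if (!isTRUE(all.equal(cv$points$proportion, props)))
      stop("curves have different proportion grids; interpolation refused")
  labels <- vapply(curves, `[[`, character(1), "label")
  out <- data.frame(proportion = props)
  mats <- list()
  for (lab in unique(labels)) {
    M <- vapply(curves[labels == lab], function(cv) cv$points$explained,
                numeric(length(props)))
    M <- matrix(M, nrow = length(props))
    mats[[lab]] <- M
    out[[paste0("mean_", lab)]] <- rowMeans(M)
  }
  if (length(mats) == 2L && ncol(mats[[1L]]) == ncol(mats[[2L]])) {
    D <- mats[[1L]] - mats[[2L]]
    nrep <- ncol(D)
    out$diff_mean <- rowMeans(D)
    out$diff_se <- if (nrep > 1L) apply(D, 1L, stats::sd) / sqrt(nrep) else NA_real_
    out$n_replicates <- nrep
  }
  out
}

.binomGreater <- function(x, size, p0) {
  ## one-sided P(X >= x) under Binomial(size, p0)
  if (size == 0L) return(NA_real_)
  p0 <- min(max(p0, 0), 1)
  stats::pbinom(x - 1L, size, p0, lower.tail = FALSE)
}

#' Two-cohort replication analysis of prioritized SNPs
#'
#' Bins discovery-cohort SNPs by their GWAS p-values (default five bins:
#' I (0, 1e-6), II [1e-6, 1e-5), III [1e-5, 1e-4), IV [1e-4, 1e-3),
#' V [1e-3, 1e-2)), splits each bin into SNPs harbored by significant
#' segments (segment p < `prioritizeP`, default 5e-8) versus the rest, and
#' compares replication rates — the fraction of SNPs reaching
#' p < `replicateP` (default 0.05) in the replication cohort. A one-sided
#' binomial test asks whether the prioritized group replicates more often
#' than the non-prioritized group's rate.
#'
#' @param discovery,replication data.frames with `snp_id` and `p` (or `z`,
#'   from which two-sided p is derived).
#' @param assoc segment association table with `segment_id` and `p`.
#' @param segments the [SegmentSet] linking SNPs to segments.
#' @param breaks increasing p-value bin edges; bin i is
#'   `(breaks[i], breaks[i+1])` for i = 1 and `[breaks[i], breaks[i+1])`
#'   otherwise.
#' @param prioritizeP segment significance threshold, default 5e-8.
#' @param replicateP relaxed replication threshold, default 0.05.
#' @return data.frame with one row per bin: counts, rates and `binomial_p`
#'   (NA when a group is empty).
#' @export
replicationAnalysis <- function(discovery, replication, assoc, segments,
                                breaks = c(0, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2),
                                prioritizeP = 5e-8, replicateP = 5e-2) {
  stopifnot(is(segments, "SegmentSet"))
  getP <- function(d) {
    d <- as.data.frame(d)
    if (!"p" %in% names(d)) {
      if (!"z" %in% names(d)) stop("cohort table needs a p or z column")
      d$p <- 2 * stats::pnorm(-abs(d$z))
    }
    d$p <- pmax(d$p, .Machine$double.xmin)
    d
  }
  discovery <- getP(discovery); replication <- getP(replication)
  shared <- intersect(discovery$snp_id, replication$snp_id)
  if (length(shared) == 0L) stop("no SNP ids shared between cohorts")
  dP <- discovery$p[match(shared, discovery$snp_id)]
  rP <- replication$p[match(shared, replication$snp_id)]
  sigSegs <- assoc$segment_id[!is.na(assoc$p) & assoc$p < prioritizeP]
  segSnps <- segmentSnps(segments)
  prioritized <- unique(unlist(segSnps[segmentIds(segments) %in% sigSegs],
                               use.names = FALSE))
  isPrior <- shared %in% prioritized
  replicated <- rP < replicateP
  nb <- length(breaks) - 1L
  binLabels <- utils::head(c("I", "II", "III", "IV", "V",
                             paste0("bin", 6:26)), nb)
  bin <- findInterval(dP, breaks, left.open = FALSE, rightmost.closed = FALSE)
  bin[dP >= breaks[nb + 1L]] <- NA  # beyond last edge
  rows <- lapply(seq_len(nb), function(i) {
    inBin <- !is.na(bin) & bin == i
    np <- sum(inBin & isPrior); npr <- sum(inBin & isPrior & replicated)
    no <- sum(inBin & !isPrior); nor <- sum(inBin & !isPrior & replicated)
    rateO <- if (no > 0L) nor / no else NA_real_
    bp <- if (np == 0L || no == 0L) NA_real_ else .binomGreater(npr, np, rateO)
    data.frame(bin = binLabels[i], p_lo = breaks[i], p_hi = breaks[i + 1L],
               n_prioritized = np, n_prioritized_replicated = npr,
               n_other = no, n_other_replicated = nor,
               rate_prioritized = if (np > 0L) npr / np else NA_real_,
               rate_other = rateO, binomial_p = bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
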