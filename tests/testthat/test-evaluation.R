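# shared small simulation world for the evaluation tests
evalWorld <- function(m = 400, k = 20, seedW = 50, seedE = 51, seedZ = 52,
                      nGwas = 400) {
  ld <- simulateLD(ldModel("ar1_blocks", blockSizes = 50, rho = 0.5), m)
  v <- data.frame(snp_id = sprintf("snp%06d", seq_len(m)), chrom = "chr1",
                  pos = 1e6 + seq_len(m) * 250)
  seg <- tileSegmentsBySnpCount(v, k)
  blocks <- ldBlocksFromStructure(ld, seg, v$snp_id)
  set.seed(seedW)
  w <- setNames(rnorm(m), v$snp_id)
  eff <- drawEffects(assignGroups(w), seed = seedE)
  z <- simulateZscores(ld, eff$beta, n = nGwas, seed = seedZ)
  gwas <- data.frame(snp_id = v$snp_id, z = z)
  assoc <- owasSummary(gwas, w, blocks, seg)
  list(ld = ld, v = v, seg = seg, blocks = blocks, w = w, eff = eff,
       gwas = gwas, assoc = assoc)
}

test_that("heritability curve endpoints and monotonicity behave", {
  wd <- evalWorld()
  cv <- heritabilityCurve(wd$assoc, wd$eff, wd$ld, wd$seg, wd$v$snp_id,
                          proportions = c(0.001, 0.05, 0.5, 1))
  # selecting nothing explains nothing; selecting everything explains h2Total
  expect_equal(cv$points$explained[1], 0)
  expect_equal(cv$points$explained[4], sum(wd$eff$groupH2), tolerance = 1e-12)
  expect_true(all(cv$points$explained >= 0))
  expect_error(heritabilityCurve(wd$assoc, list(), wd$ld, wd$seg, wd$v$snp_id),
               "truth")

  # under independent LD the curve is non-decreasing for any ranking
  ldI <- simulateLD(ldModel("independent"), 400)
  blocksI <- ldBlocksFromStructure(ldI, wd$seg, wd$v$snp_id)
  zI <- simulateZscores(ldI, wd$eff$beta, n = 400, seed = 53)
  aI <- owasSummary(data.frame(snp_id = wd$v$snp_id, z = zI), wd$w, blocksI,
                    wd$seg)
  cvI <- heritabilityCurve(aI, wd$eff, ldI, wd$seg, wd$v$snp_id,
                           proportions = seq(0.05, 1, by = 0.05))
  expect_true(all(diff(cvI$points$explained) >= -1e-12))

  # a ranking by true per-segment heritability dominates the p-value ranking
  segSnps <- segmentSnps(wd$seg)
  trueH <- vapply(seq_along(segSnps), function(s) {
    idx <- match(segSnps[[s]], wd$v$snp_id)
    sum(wd$eff$beta[idx]^2)
  }, numeric(1))
  oracleAssoc <- data.frame(segment_id = segmentIds(wd$seg),
                            Z = trueH, p = rank(-trueH) / length(trueH))
  cvO <- heritabilityCurve(oracleAssoc, wd$eff, ldI, wd$seg, wd$v$snp_id,
                           proportions = seq(0.05, 1, by = 0.05))
  expect_true(all(cvO$points$explained >= cvI$points$explained - 0.05))
})

test_that("method comparison aligns curves and matches a hand-computed paired test", {
  mk <- function(label, vals, props = c(0.25, 0.5)) {
    structure(list(label = label,
                   points = data.frame(proportion = props, explained = vals,
                                       n_segments = c(1L, 2L))),
              class = "rankingCurve")
  }
  # identical curves -> zero difference
  cmp0 <- compareMethods(list(mk("a", c(0.1, 0.2)), mk("b", c(0.1, 0.2))))
  expect_equal(cmp0$diff_mean, c(0, 0))
  # single curve -> passthrough of its values
  one <- compareMethods(list(mk("a", c(0.3, 0.4))))
  expect_equal(one$mean_a, c(0.3, 0.4))
  expect_null(one$diff_mean)
  # 5 replicate pairs at one proportion: hand-computed paired mean/SE
  aVals <- c(0.50, 0.60, 0.55, 0.52, 0.58)
  bVals <- c(0.45, 0.50, 0.56, 0.50, 0.49)
  curves <- c(lapply(aVals, function(x) mk("a", c(x, x))),
              lapply(bVals, function(x) mk("b", c(x, x))))
  cmp <- compareMethods(curves)
  d <- aVals - bVals
  md <- sum(d) / 5
  se <- sqrt(sum((d - md)^2) / 4) / sqrt(5)
  expect_equal(cmp$diff_mean, c(md, md))
  expect_equal(cmp$diff_se, c(se, se))
  expect_equal(cmp$n_replicates, c(5L, 5L))
  # differing proportion grids are refused
  expect_error(compareMethods(list(mk("a", c(0.1, 0.2)),
                                   mk("b", c(0.1, 0.2), props = c(0.3, 0.6)))),
               "interpolation refused")
})

test_that("replication analysis handles the degenerate identical-cohort case", {
  wd <- evalWorld(nGwas = 10000)
  disc <- data.frame(snp_id = wd$v$snp_id, z = wd$gwas$z)
  tab <- replicationAnalysis(disc, disc, wd$assoc, wd$seg,
                             prioritizeP = 5e-8, replicateP = 5e-2)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$bin, c("I", "II", "III", "IV", "V"))
  # every SNP in bins I-V has discovery p < 1e-2 < 5e-2, so all replicate
  filled <- tab[tab$n_prioritized + tab$n_other > 0, ]
  rates <- c(filled$rate_prioritized, filled$rate_other)
  expect_true(all(rates[!is.na(rates)] == 1))
  expect_true(all(tab$n_prioritized_replicated <= tab$n_prioritized))
  expect_true(all(tab$n_other_replicated <= tab$n_other))

  # no prioritized segments -> binomial p all NA
  nullAssoc <- wd$assoc; nullAssoc$p <- 0.5
  tab2 <- replicationAnalysis(disc, disc, nullAssoc, wd$seg)
  expect_true(all(is.na(tab2$binomial_p)))
})

test_that("binomial replication test matches an exact enumeration oracle", {
  # oracle: P(X >= x) as an explicit dbinom sum
  for (case in list(c(7, 10, 0.3), c(0, 5, 0.5), c(12, 12, 0.9))) {
    x <- case[1]; n <- case[2]; p0 <- case[3]
    expect_equal(openwas:::.binomGreater(x, n, p0),
                 sum(dbinom(x:n, n, p0)), tolerance = 1e-12)
  }
})

test_that("shared-signal cohorts replicate prioritized SNPs more often", {
  set.seed(54)
  wins <- 0L; total <- 0L
  for (rep in 1:12) {
    m <- 1000
    ld <- simulateLD(ldModel("ar1_blocks", blockSizes = 50, rho = 0.5), m)
    v <- data.frame(snp_id = sprintf("snp%06d", 1:m), chrom = "chr1",
                    pos = 1e6 + (1:m) * 250)
    seg <- tileSegmentsBySnpCount(v, 20)
    blocks <- ldBlocksFromStructure(ld, seg, v$snp_id)
    w <- setNames(rnorm(m), v$snp_id)
    eff <- drawEffects(assignGroups(w), seed = sample.int(2^31 - 1, 1))
    zD <- simulateZscores(ld, eff$beta, n = 2000, seed = sample.int(2^31 - 1, 1))
    zR <- simulateZscores(ld, eff$beta, n = 2000, seed = sample.int(2^31 - 1, 1))
    assoc <- owasSummary(data.frame(snp_id = v$snp_id, z = zD), w, blocks, seg)
    tab <- replicationAnalysis(data.frame(snp_id = v$snp_id, z = zD),
                               data.frame(snp_id = v$snp_id, z = zR),
                               assoc, seg, prioritizeP = 5e-8)
    ok <- !is.na(tab$rate_prioritized) & !is.na(tab$rate_other)
    wins <- wins + sum(tab$rate_prioritized[ok] >= tab$rate_other[ok])
    total <- total + sum(ok)
  }
  # prioritized replication rate at least matches the baseline in a majority
  expect_gt(wins / total, 0.5)
})

test_that("openness weighting explains more heritability when per-SNP power matches the full-scale design", {
  # m scaled down 70x from the published chromosome-wide design; the GWAS
  # sample size is scaled by the same factor (n = 142) so that per-SNP
  # non-centrality sqrt(n * tau_k) matches the full-scale study. Without
  # that rescaling every associated segment saturates and the ranking
  # comparison is uninformative (see the methods vignette).
  set.seed(60)
  m <- 2000
  ld <- simulateLD(ldModel("ar1_blocks", blockSizes = 50, rho = 0.5), m)
  v <- data.frame(snp_id = sprintf("snp%06d", 1:m), chrom = "chr1",
                  pos = 1e6 + (1:m) * 250)
  seg <- tileSegmentsBySnpCount(v, 20)
  blocks <- ldBlocksFromStructure(ld, seg, v$snp_id)
  curves <- list()
  for (rep in 1:20) {
    w <- setNames(rnorm(m), v$snp_id)
    eff <- drawEffects(assignGroups(w), seed = sample.int(2^31 - 1, 1))
    z <- simulateZscores(ld, eff$beta, n = 142, seed = sample.int(2^31 - 1, 1))
    gwas <- data.frame(snp_id = v$snp_id, z = z)
    ow <- owasSummary(gwas, w, blocks, seg)
    un <- unweightedAssociation(gwas, blocks, seg)
    curves[[2 * rep - 1]] <- heritabilityCurve(ow, eff, ld, seg, v$snp_id,
                                               proportions = 0.05,
                                               label = "owas")
    curves[[2 * rep]] <- heritabilityCurve(un, eff, ld, seg, v$snp_id,
                                           proportions = 0.05,
                                           label = "unweighted")
  }
  cmp <- compareMethods(curves)
  # paired mean advantage clearly positive (beyond 2 Monte-Carlo SEs)
  expect_gt(cmp$diff_mean, 2 * cmp$diff_se)
})
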