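test_that("individual-mode Z matches the full least-squares fit", {
  geno <- randomGenotypes(80, 10, seed = 21)
  v <- variantInfo(geno)
  seg <- tileSegmentsBySnpCount(v, k = 5)
  set.seed(22)
  w <- data.frame(snp_id = v$snp_id, weight = rnorm(10))
  O <- computeOpenness(geno, w, seg)
  y <- rnorm(80) + 0.2 * scores(O)[, 1]
  covar <- cbind(age = rnorm(80), pc1 = rnorm(80))

  a <- owasIndividual(O, y)
  aC <- owasIndividual(O, y, covariates = covar)
  for (s in 1:2) {
    f <- summary(lm(y ~ scores(O)[, s]))$coefficients
    expect_equal(a$Z[s], f[2, "t value"], tolerance = 1e-10)
    fc <- summary(lm(y ~ scores(O)[, s] + covar))$coefficients
    expect_equal(aC$Z[s], fc[2, "t value"], tolerance = 1e-10)
  }
  expect_equal(a$p, 2 * pnorm(-abs(a$Z)), tolerance = 1e-12)
  expect_equal(a$sigma_s, apply(scores(O), 2, sd), ignore_attr = TRUE)
})

test_that("degenerate and saturated openness columns are handled", {
  set.seed(23)
  O <- cbind(const = rep(2, 50), ok = rnorm(50))
  y <- rnorm(50)
  a <- owasIndividual(O, y)
  expect_true(is.na(a$Z[1]))
  expect_equal(a$note[1], "degenerate openness")
  # perfect fit: affine transform of y
  a2 <- owasIndividual(cbind(sat = 2 * y + 1), y)
  expect_equal(a2$note, "saturated")
  expect_equal(a2$p, .Machine$double.xmin)
})

test_that("quadratic-form segment sd matches closed forms and the sample sd", {
  b1 <- new("LDBlock", segmentId = "s", snpIds = "a",
            R = matrix(1, 1, 1), sd = 0.6)
  expect_equal(segmentSd(1, b1), 0.6)
  b2 <- new("LDBlock", segmentId = "s", snpIds = c("a", "b"),
            R = diag(2), sd = c(1, 1))
  expect_equal(segmentSd(c(1, 1), b2), sqrt(2))
  expect_equal(segmentSd(c(0, 0), b2), 0)

  # oracle: sample sd of O computed directly from the genotypes behind R
  geno <- randomGenotypes(200, 10, seed = 24)
  v <- variantInfo(geno)
  seg <- tileSegmentsBySnpCount(v, k = 10)
  set.seed(25); w <- setNames(rnorm(10), v$snp_id)
  blocks <- ldFromGenotypes(geno, seg)
  O <- dosages(geno) %*% w
  expect_equal(segmentSd(w, blocks[[1]]), sd(O), tolerance = 1e-10)
})

test_that("summary-mode Z reduces exactly for single-SNP segments", {
  v <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 5000,
                  allele_effect = "A", allele_other = "G")
  seg <- tileSegmentsBySnpCount(v, k = 1)
  block <- list(new("LDBlock", segmentId = segmentIds(seg), snpIds = "rs1",
                    R = matrix(1, 1, 1), sd = 0.7))
  names(block) <- segmentIds(seg)
  gwas <- data.frame(snp_id = "rs1", z = 2.34)
  aPlus <- owasSummary(gwas, c(rs1 = 1), block, seg)
  expect_equal(aPlus$Z, 2.34)
  aMinus <- owasSummary(gwas, c(rs1 = -1), block, seg)
  expect_equal(aMinus$Z, -2.34)
  expect_equal(aPlus$p, 2 * pnorm(-2.34), tolerance = 1e-12)
})

test_that("summary-mode Z has closed form for independent equal-sd SNPs", {
  v <- data.frame(snp_id = c("rs1", "rs2"), chrom = "chr1",
                  pos = c(5000, 6000), allele_effect = "A", allele_other = "G")
  seg <- tileSegmentsBySnpCount(v, k = 2)
  block <- list(new("LDBlock", segmentId = segmentIds(seg),
                    snpIds = c("rs1", "rs2"), R = diag(2), sd = c(1, 1)))
  names(block) <- segmentIds(seg)
  gwas <- data.frame(snp_id = c("rs1", "rs2"), z = c(1.1, -0.4))
  un <- unweightedAssociation(gwas, block, seg)
  expect_equal(un$Z, (1.1 - 0.4) / sqrt(2))
  # and equals owasSummary with all weights 1
  ow <- owasSummary(gwas, c(rs1 = 1, rs2 = 1), block, seg)
  expect_equal(un$Z, ow$Z)
})

test_that("weight rescaling leaves |Z| invariant; negative scale flips sign", {
  geno <- randomGenotypes(300, 40, seed = 26)
  v <- variantInfo(geno)
  seg <- tileSegmentsBySnpCount(v, k = 20)
  blocks <- ldFromGenotypes(geno, seg)
  set.seed(27)
  w <- setNames(rnorm(40), v$snp_id)
  gwas <- data.frame(snp_id = v$snp_id, z = rnorm(40))
  z1 <- owasSummary(gwas, w, blocks, seg)$Z
  z5 <- owasSummary(gwas, 5 * w, blocks, seg)$Z
  zn <- owasSummary(gwas, -2 * w, blocks, seg)$Z
  expect_equal(z5, z1, tolerance = 1e-12)
  expect_equal(zn, -z1, tolerance = 1e-12)
})

test_that("allele-flip involution leaves segment Z-scores unchanged", {
  geno <- randomGenotypes(200, 20, seed = 28)
  v <- variantInfo(geno)
  seg <- tileSegmentsBySnpCount(v, k = 10)
  set.seed(29)
  gwasRaw <- data.frame(snp_id = v$snp_id, effect_allele = "A",
                        other_allele = "G", z = rnorm(20))
  wRaw <- opennessWeights(v$snp_id, rep("A", 20), rnorm(20))
  run <- function(geno, gwasRaw, wRaw) {
    vv <- variantInfo(geno)
    g <- harmonizeGwas(gwasRaw, vv)
    h <- harmonizeAlleles(wRaw, vv)
    owasSummary(g, h, ldFromGenotypes(geno, seg), seg)$Z
  }
  z1 <- run(geno, gwasRaw, wRaw)
  # flip effect/other everywhere for SNP 4: dosage recoded 2-X, gwas z sign
  # flips, weight allele now matches the other allele
  j <- 4
  X2 <- dosages(geno); X2[, j] <- 2 - X2[, j]
  v2 <- v; v2$allele_effect[j] <- "G"; v2$allele_other[j] <- "A"
  geno2 <- genotypeData(X2, v2)
  z2 <- run(geno2, gwasRaw, wRaw)
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("GWAS harmonization flips swapped alleles and logs drops", {
  v <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                  allele_effect = c("A", "G", "A"),
                  allele_other = c("G", "A", "C"))
  gwas <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs9"),
                     effect_allele = c("A", "A", "T", "A"),
                     other_allele = c("G", "G", "C", "G"),
                     z = c(1, 2, 3, 4))
  h <- harmonizeGwas(gwas, v)
  expect_equal(h$z[h$snp_id == "rs1"], 1)
  expect_equal(h$z[h$snp_id == "rs2"], -2)   # swapped coding
  expect_false("rs3" %in% h$snp_id)          # unresolvable alleles
  drops <- attr(h, "drops")
  expect_equal(unname(drops["not_in_variants"]), 1L)
  expect_equal(unname(drops["allele_mismatch"]), 1L)
})

test_that("multiple-testing adjustment matches hand-computed references", {
  a <- data.frame(segment_id = sprintf("s%d", 1:10), Z = 1, p = 0.01,
                  p_adj = NA_real_, significant = NA)
  bf <- adjustPvalues(a, "bonferroni")
  expect_equal(bf$p_adj, rep(0.1, 10))
  expect_false(any(bf$significant))

  ones <- data.frame(segment_id = c("a", "b"), Z = 0, p = c(1, 1),
                     p_adj = NA_real_, significant = NA)
  expect_equal(adjustPvalues(ones, "bonferroni")$p_adj, c(1, 1))

  # BH step-up by hand: p (0.001, 0.02, 0.9) -> adj (0.003, 0.03, 0.9)
  b <- data.frame(segment_id = c("a", "b", "c"), Z = 1,
                  p = c(0.001, 0.02, 0.9), p_adj = NA_real_, significant = NA)
  bh <- adjustPvalues(b, "bh")
  expect_equal(bh$p_adj, c(0.003, 0.03, 0.9))
  expect_equal(bh$significant, c(TRUE, TRUE, FALSE))
})

test_that("null rejection rate of the individual test is calibrated", {
  set.seed(30)
  n <- 400; nSim <- 400
  O <- matrix(rnorm(n * 5), n, 5)
  hits <- 0L; total <- 0L
  for (i in seq_len(nSim)) {
    a <- owasIndividual(O, rnorm(n))
    hits <- hits + sum(a$p < 0.05)
    total <- total + 5L
  }
  rate <- hits / total
  band <- 2 * sqrt(0.05 * 0.95 / total)
  expect_lt(abs(rate - 0.05), band + 1e-12)
})
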