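test_that("map and gene simulation is deterministic and well-spaced", {
  a <- simulateMapAndGenes(1000, 2, 10, seed = 5)
  b <- simulateMapAndGenes(1000, 2, 10, seed = 5)
  expect_identical(start(a$map), start(b$map))
  expect_identical(start(a$genes), start(b$genes))
  # mean inter-SNP gap near the requested spacing
  gaps <- unlist(lapply(split(start(a$map),
                              as.character(seqnames(a$map))), diff))
  expect_lt(abs(mean(gaps) - 3000) / 3000, 0.10)
  # genes never overlap
  ov <- findOverlaps(a$genes, a$genes)
  expect_true(all(queryHits(ov) == subjectHits(ov)))
  expect_error(simulateMapAndGenes(100, 1, 50, meanGap = 100,
                                   geneLengthRange = c(5000, 9000),
                                   seed = 1),
               "infeasible")
})

test_that("planted blocks satisfy the clustering criteria by construction", {
  sim <- simulateMapAndGenes(5000, 2, 50, seed = 9)
  tr <- plantEffects(sim$map, sim$genes, nLoci = 5, blockSpan = 25000,
                     snpsPerBlock = 6, seed = 10)
  expect_equal(nrow(tr@loci), 5L)
  expect_length(effectSnps(tr), 30)
  blocks <- findClusters(sim$map[effectSnps(tr)],
                         convergenceCriteria(3, 25000))
  expect_true(all(effectSnps(tr) %in% unlist(blocks$snp_id)))
  # every block sits inside its host gene
  for (i in seq_len(nrow(tr@loci))) {
    g <- sim$genes[tr@loci$gene_id[i]]
    expect_gte(tr@loci$start[i], start(g))
    expect_lte(tr@loci$end[i], end(g))
    expect_lte(tr@loci$end[i] - tr@loci$start[i], 25000)
  }
  empty <- plantEffects(sim$map, sim$genes, nLoci = 0)
  expect_length(effectSnps(empty), 0)
})

test_that("disjoint tagging splits block SNPs between populations", {
  sim <- simulateMapAndGenes(5000, 1, 40, seed = 11)
  tr <- plantEffects(sim$map, sim$genes, nLoci = 3, snpsPerBlock = 6,
                     tagging = "disjoint", seed = 12)
  expect_length(intersect(tr@tagged$A, tr@tagged$B), 0)
  expect_setequal(c(tr@tagged$A, tr@tagged$B), effectSnps(tr))
  expect_length(tr@tagged$A, 9)
})

test_that("pool simulation is deterministic and respects the scale", {
  sim <- simulateMapAndGenes(200, 1, 2, seed = 21)
  d <- poolDesignTable(3, 3, "A")
  f <- simulateAlleleFreqs(sim$map, "A", seed = 22)[, 1]
  p1 <- simulatePools(sim$map, d, f, seed = 23)
  p2 <- simulatePools(sim$map, d, f, seed = 23)
  expect_identical(assay(p1, "arctan"), assay(p2, "arctan"))
  expect_true(all(assay(p1) >= 0 & assay(p1) <= pi / 2))
  expect_error(simulatePools(sim$map, d, f * 10, seed = 1), "\\[0, 1\\]")
})

test_that("zero noise and fixed frequency give the exact arctan value", {
  map <- testMap(1:20 * 1000)
  d <- poolDesignTable(2, 2, "A", nIndividuals = 20)
  # enormous pools make the binomial draw exact at f = 0.5
  d$n_individuals <- 5e5
  p <- simulatePools(map, d, rep(0.5, 20), noise = noiseModel(0),
                     seed = 2)
  expect_equal(unname(as.vector(assay(p))), rep(pi / 4, 20 * 12),
               tolerance = 2e-3)
})

test_that("generator noise reproduces the stated SEM calibration", {
  sim <- simulateMapAndGenes(10000, 2, 10, seed = 31)
  d <- poolDesignTable(20, 20, "A")
  f <- simulateAlleleFreqs(sim$map, "A", seed = 32)[, 1]
  panel <- simulatePools(sim$map, d, f, seed = 33)
  qc <- qcReport(panel)
  expect_lt(abs(mean(replicateSEM(qc)) - 0.03) / 0.03, 0.05)
  expect_lt(abs(mean(groupSEM(qc)) - 0.02) / 0.02, 0.05)
})

test_that("per-SNP detection rates agree with the power calculation", {
  nSnps <- 4000
  map <- simulateMapAndGenes(nSnps, 1, 4, seed = 41)$map
  d <- poolDesignTable(20, 14, "A")
  f <- rep(0.3, nSnps)
  tr <- new("SyntheticTruth",
            loci = data.frame(locus = 1, gene_id = "g", chrom = "chr1",
                              start = 1, end = 2, n_snps = nSnps),
            effectSnps = names(map), tagged = list(A = names(map)),
            effectSize = 0.10, seed = 1L)
  panel <- simulatePools(map, d, f, truth = tr, population = "A",
                         seed = 42)
  assoc <- snpTTest(panel)
  rate <- length(nominalPositives(assoc)) / nSnps
  # predicted power at the arctan-scale effect and empirical pool SD
  pm <- poolMeans(panel)
  sdPool <- sqrt(mean(poolConverge:::rowVarsFast(
    pm[, poolDesign(panel)$phenotype == "control"])))
  deltaArctan <- atan2(0.4, 0.6) - atan2(0.3, 0.7)
  predicted <- tTestPower(deltaArctan, sdPool, 20, 14)
  expect_lt(abs(rate - predicted), 0.10)
})

test_that("validation design recovers expected frequencies", {
  vd0 <- simulateValidationDesign(nSnps = 300, noise = noiseModel(0),
                                  seed = 51)
  expect_equal(validationCorrelation(vd0), 1)
  vd <- simulateValidationDesign(nSnps = 800, seed = 52)
  expect_gte(validationCorrelation(vd), 0.95)
  vd2 <- simulateValidationDesign(nSnps = 800, seed = 52)
  expect_identical(vd$observedArctan, vd2$observedArctan)
  expect_equal(sum(vd$poolSizes), 81)
})

test_that("a full study is reproducible from its master seed", {
  s1 <- simulateStudy(nSnps = 400, nGenes = 4, nLoci = 1, seed = 61)
  s2 <- simulateStudy(nSnps = 400, nGenes = 4, nLoci = 1, seed = 61)
  expect_identical(assay(s1$panels$A), assay(s2$panels$A))
  expect_identical(assay(s1$panels$B), assay(s2$panels$B))
  expect_identical(effectSnps(s1$truth), effectSnps(s2$truth))
  expect_identical(s1$freqs, s2$freqs)
})
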