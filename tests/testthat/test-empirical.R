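test_that("empirical p follows the add-one convention and its bounds", {
  e <- poolConverge:::empiricalPFromTrials(5, c(1, 2, 5, 7), seed = 1)
  expect_equal(pValue(e), (2 + 1) / (4 + 1))
  expect_equal(nullExceed(e), 2)
  # monotone decreasing in the observed statistic, bounded
  trials <- 0:99
  ps <- sapply(c(0, 10, 50, 99, 100), function(obs)
    pValue(poolConverge:::empiricalPFromTrials(obs, trials)))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 1 / 101 & ps <= 1))
  expect_equal(ps[1], 1)            # observed 0: every trial ties
  expect_equal(ps[5], 1 / 101)      # observed above all trials
})

test_that("overlap Monte Carlo agrees with the hypergeometric tail", {
  exact <- phyper(6 - 1, 10, 10, 10, lower.tail = FALSE)
  for (method in c("hypergeometric", "sets")) {
    e <- mcOverlapP(20, 10, 10, 6, nTrials = 20000, seed = 7,
                    method = method)
    se <- sqrt(exact * (1 - exact) / 20000)
    expect_lt(abs(pValue(e) - exact), 3 * se + 2 / 20001)
  }
  expect_equal(pValue(mcOverlapP(50, 10, 10, 0, 500, seed = 1)), 1)
  expect_error(mcOverlapP(20, 5, 5, 6, 10), "exceeds")
})

test_that("cluster Monte Carlo matches exhaustive draw enumeration", {
  pos <- c(1, 2, 3, 4, 1000, 2000, 5000, 9000, 20000, 40000, 70000,
           110000)
  map <- testMap(pos)
  cr <- convergenceCriteria(3, 100)
  # exact null: every C(12,3) draw of pseudopositives
  combos <- combn(12, 3)
  stat <- apply(combos, 2, function(ix) {
    cc <- bruteChains(pos[sort(ix)], 100, 3)
    if (is.null(cc)) 0 else sum(cc$size)
  })
  exactP <- mean(stat >= 3)
  e <- mcClusterP(map, 3, cr, observed = 3, nTrials = 4000, seed = 21)
  se <- sqrt(exactP * (1 - exactP) / 4000)
  expect_lt(abs(pValue(e) - exactP), 3 * se + 2 / 4001)
  expect_equal(pValue(mcClusterP(map, 3, cr, observed = 0, 100,
                                 seed = 1)), 1)
})

test_that("fully clustered real positives give the floor p", {
  # all real positives consecutive and tight: no random draw beats them
  pos <- c(seq(100, 1000, by = 100), seq(1e6, 2e6, by = 1e5))
  map <- testMap(pos)
  cr <- convergenceCriteria(3, 500)
  obs <- poolConverge:::clusteredSnpCount(pos[1:10], 500, 3)
  expect_equal(obs, 10L)
  e <- mcClusterP(map, 10, cr, observed = 10, nTrials = 400, seed = 3)
  expect_equal(pValue(e), 1 / 401)
})

test_that("the fast convergence trial statistic equals the full analysis", {
  set.seed(47)
  sim <- simulateMapAndGenes(800, 2, 12, meanGap = 2500, seed = 48)
  for (rep in 1:10) {
    idsA <- sample(names(sim$map), 120)
    idsB <- sample(names(sim$map), 150)
    for (rule in c("minSize", "anyOverlap")) {
      cr <- convergenceCriteria(3, 10000)
      slow <- poolConverge:::.convergentGenes(idsA, idsB, sim$map,
                                              sim$genes, cr, 10000, rule)
      mach <- poolConverge:::.mc2Machine(sim$map, sim$genes, cr, 10000,
                                         rule)
      g <- mach$coords
      fast <- mach$count(sort(g[names(sim$map) %in% idsA]),
                         sort(g[names(sim$map) %in% idsB]))
      expect_equal(fast, length(slow))
    }
  }
})

test_that("gene-convergence Monte Carlo is self-consistent across seeds", {
  sim <- simulateMapAndGenes(500, 1, 10, meanGap = 2000, seed = 41)
  cr <- convergenceCriteria(3, 10000)
  e1 <- mcGeneConvergenceP(sim$map, sim$genes, 80, 80, cr, observed = 2,
                           nTrials = 150, seed = 1)
  e2 <- mcGeneConvergenceP(sim$map, sim$genes, 80, 80, cr, observed = 2,
                           nTrials = 1500, seed = 99)
  p1 <- pValue(e1); p2 <- pValue(e2)
  se <- sqrt(p2 * (1 - p2) / 150)
  expect_lt(abs(p1 - p2), 3 * se + 2 / 151)
  expect_equal(pValue(mcGeneConvergenceP(sim$map, sim$genes, 20, 20, cr,
                                         observed = 0, nTrials = 30,
                                         seed = 2)), 1)
})

test_that("saturated pseudopositive sets converge every eligible gene", {
  sim <- simulateMapAndGenes(400, 1, 8, meanGap = 2500, seed = 43)
  cr <- convergenceCriteria(3, 25000)
  n <- length(sim$map)
  allIds <- names(sim$map)
  full <- poolConverge:::.convergentGenes(allIds, allIds, sim$map,
                                          sim$genes, cr, 10000,
                                          "minSize")
  e <- mcGeneConvergenceP(sim$map, sim$genes, n, n, cr,
                          observed = length(full), nTrials = 20,
                          seed = 3)
  expect_equal(pValue(e), 1)
})

test_that("per-gene Monte Carlo matches exhaustive segment placement", {
  # 5 short genes; positives concentrated in gene g3
  genes <- GRanges("chr1", IRanges(c(1000, 6000, 11000, 16000, 21000),
                                   width = 800))
  names(genes) <- paste0("g", 1:5)
  pos <- c(11100, 11200, 11300, 6100, 21500, 16050)
  map <- testMap(pos)
  posIds <- names(map)
  cr <- convergenceCriteria(3, 400)
  flank <- 100
  e <- mcGeneLevelP("g3", genes, map, posIds, posIds, cr, approach = 1,
                    nTrials = 30000, seed = 5, flank = flank)
  expect_equal(observedStat(e), 3)
  # exhaustive oracle over every placement of an L-bp segment inside
  # the flanked genes
  L <- 800 + 2 * flank
  placements <- unlist(lapply(seq_along(genes), function(g) {
    lo <- start(genes)[g] - flank; hi <- end(genes)[g] + flank
    if (hi - lo + 1 < L) return(NULL)
    lapply(lo:(hi - L + 1), function(s) c(s, s + L - 1))
  }), recursive = FALSE)
  feat <- vapply(placements, function(seg) {
    inPos <- sort(pos[pos >= seg[1] & pos <= seg[2]])
    cc <- bruteChains(inPos, 400, 3)
    if (is.null(cc)) 0 else sum(cc$size)
  }, numeric(1))
  exactP <- mean(feat >= 3)
  se <- sqrt(exactP * (1 - exactP) / 30000)
  expect_lt(abs(pValue(e) - exactP), 3 * se + 2 / 30001)
})

test_that("per-gene Monte Carlo handles extremes", {
  genes <- GRanges("chr1", IRanges(c(1000, 50000), width = 2000))
  names(genes) <- c("hot", "cold")
  pos <- seq(1100, 2500, by = 200)
  map <- testMap(pos)
  ids <- names(map)
  cr <- convergenceCriteria(3, 1000)
  hot <- mcGeneLevelP("hot", genes, map, ids, ids, cr, nTrials = 300,
                      seed = 4)
  expect_lt(pValue(hot), 0.35)  # segments in "cold" show nothing
  none <- mcGeneLevelP("cold", genes, map, character(), character(),
                       cr, nTrials = 50, seed = 4)
  expect_equal(observedStat(none), 0)
  expect_equal(pValue(none), 1)
})

test_that("approach-2 per-gene features require clusters in both samples", {
  genes <- GRanges("chr1", IRanges(c(1000, 50000), width = 3000))
  names(genes) <- c("g1", "g2")
  pos <- seq(1100, 3800, by = 300)
  map <- testMap(pos)
  a <- names(map)[1:5]; b <- names(map)[6:10]
  e <- mcGeneLevelP("g1", genes, map, a, b, convergenceCriteria(3, 1000),
                    approach = 2, nTrials = 100, seed = 6)
  expect_true(observedStat(e) %in% c(0, 1))
})

test_that("true-gene fraction follows its defining formula", {
  expect_equal(truePositiveFraction(100, 0), 1)
  expect_equal(truePositiveFraction(100, 100), 0)
  expect_equal(truePositiveFraction(341, 194.4), (341 - 194.4) / 341)
  expect_equal(truePositiveFraction(10, 15), 0)   # clamped
  expect_warning(tf <- truePositiveFraction(0, 5), "zero")
  expect_true(is.na(tf))
})
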