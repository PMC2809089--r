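test_that("power equals alpha at zero effect and is monotone", {
  expect_equal(tTestPower(0, 0.052, 20, 14), 0.05)
  expect_equal(tTestPower(0, 0.052, 20, 14, alpha = 0.10), 0.10)
  expect_gt(tTestPower(0.10, 0.052, 20, 14),
            tTestPower(0.05, 0.052, 20, 14))
  expect_gt(tTestPower(0.05, 0.052, 35, 12),
            tTestPower(0.05, 0.052, 20, 12))
  expect_gt(tTestPower(0.05, 0.04, 20, 14),
            tTestPower(0.05, 0.08, 20, 14))
})

test_that("power matches a large simulation of the t test", {
  delta <- 0.05; sd <- 0.052; n1 <- 20; n2 <- 14
  nSim <- 2e5
  set.seed(71)
  x <- matrix(rnorm(nSim * n1, delta, sd), nSim)
  y <- matrix(rnorm(nSim * n2, 0, sd), nSim)
  p <- poolConverge:::rowWelch(x, y)$p
  simPower <- mean(p < 0.05)
  power <- tTestPower(delta, sd, n1, n2)
  se <- sqrt(simPower * (1 - simPower) / nSim)
  expect_lt(abs(power - simPower), 3 * se + 0.003)
})

test_that("power table crosses deltas and sample sizes", {
  tab <- powerTable(c(0.05, 0.10), 0.052, c(20, 35), c(14, 12))
  expect_equal(nrow(tab), 8L)
  expect_true(all(tab$power > 0 & tab$power < 1))
})

test_that("overlap control reports observed, expectation and p", {
  u <- paste0("s", 1:100)
  r <- overlapControl(u[1:10], u[11:20], u)
  expect_equal(r$observed, 0)
  expect_equal(r$expected, 1.0)
  r2 <- overlapControl(u, u, u)
  expect_equal(r2$observed, 100)
  expect_equal(r2$expected, 100)
  expect_equal(r2$p, 1)
  r3 <- overlapControl(u[1:10], u[10:19], u)
  expect_equal(r3$observed, 1)
  expect_equal(r3$expected, 1.0)
  oracle <- fisher.test(matrix(c(1, 9, 9, 81), 2))$p.value
  expect_equal(r3$p, oracle)
  expect_error(overlapControl("a", "b", character()), "empty")
})

test_that("suspect selection takes the top score quantile", {
  score <- setNames(1:100, paste0("s", 1:100))
  top <- suspectSnps(score, 0.10)
  expect_length(top, 10)
  expect_setequal(top, paste0("s", 91:100))
})

test_that("population structure dominates the first component", {
  set.seed(61)
  nSnps <- 300
  fA <- runif(nSnps, 0.2, 0.8)
  fB <- pmin(pmax(fA + rnorm(nSnps, 0, 0.15), 0.05), 0.95)
  mkPools <- function(f, n) t(vapply(seq_len(n), function(i)
    atan2(f, 1 - f) + rnorm(nSnps, 0, 0.02), numeric(nSnps)))
  mat <- rbind(mkPools(fA, 8), mkPools(fB, 8))
  pop <- rep(c("A", "B"), each = 8)
  r <- pcaSeparation(mat, pop, nTrials = 400, seed = 3)
  expect_equal(sum(r$varianceFraction), 1, tolerance = 1e-9)
  expect_gt(r$varianceFraction[1], 0.5)
  # first component separates the populations perfectly
  s1 <- r$scores[, 1]
  expect_true(max(s1[pop == "A"]) < min(s1[pop == "B"]) ||
                max(s1[pop == "B"]) < min(s1[pop == "A"]))
  expect_lt(r$separationP[1], 0.01)
})

test_that("separation p is invariant to pool row order", {
  set.seed(62)
  mat <- matrix(rnorm(12 * 50), 12)
  lab <- rep(c("case", "control"), 6)
  r1 <- pcaSeparation(mat, lab, nTrials = 800, seed = 5)
  o <- sample(12)
  r2 <- pcaSeparation(mat[o, ], lab[o], nTrials = 800, seed = 5)
  expect_equal(r1$varianceFraction, r2$varianceFraction)
  # permutation p is invariant up to Monte Carlo error
  expect_true(all(abs(r1$separationP - r2$separationP) <
                    3 * sqrt(0.25 / 800) + 2 / 801))
})

test_that("random labels give uncalibrated separation no alarm", {
  set.seed(63)
  ps <- vapply(1:40, function(i) {
    mat <- matrix(rnorm(10 * 40), 10)
    pcaSeparation(mat, rep(c("a", "b"), 5), nComponents = 1,
                  nTrials = 99, seed = i)$separationP[1]
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0)   # some small ps occur by chance...
  expect_lt(mean(ps < 0.05), 0.3) # ...but not an excess
  expect_error(pcaSeparation(matrix(1, 5, 4), rep(c("a", "b"), c(2, 3))),
               "constant")
})
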