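# Both convergence strategies on constructed association tables: the
# tests drive clustering and gene assignment directly from positive
# sets, independent of the t-test stage.

.toyWorld <- function() {
  pos <- c(10000, 15000, 20000, 200000, 205000, 210000, 215000,
           500000)
  map <- testMap(pos)
  genes <- GRanges("chr1", IRanges(c(5000, 195000), c(25000, 220000)))
  names(genes) <- c("gA", "gB")
  list(map = map, genes = genes, ids = names(map))
}

test_that("shared positives in one gene are found by approach 1", {
  w <- .toyWorld()
  p <- rep(0.5, 8); p[1:3] <- 0.01
  aA <- testAssoc(w$ids, p); aB <- testAssoc(w$ids, p)
  r <- convergeThenCluster(aA, aB, w$map, w$genes,
                           convergenceCriteria(3, 25000))
  expect_setequal(r$reproducibleSnps, w$ids[1:3])
  expect_identical(r$geneHits$gene_id, "gA")
  expect_equal(r$geneHits$n_snps, 3L)
})

test_that("disjoint positive sets yield nothing under approach 1", {
  w <- .toyWorld()
  pA <- rep(0.5, 8); pA[1:3] <- 0.01
  pB <- rep(0.5, 8); pB[4:7] <- 0.01
  r <- convergeThenCluster(testAssoc(w$ids, pA), testAssoc(w$ids, pB),
                           w$map, w$genes, convergenceCriteria(3, 25000))
  expect_length(r$reproducibleSnps, 0)
  expect_equal(nrow(r$geneHits), 0L)
})

test_that("approach 2 requires a qualifying cluster from each sample", {
  w <- .toyWorld()
  pA <- rep(0.5, 8); pA[4:7] <- 0.01   # 4 SNPs within 15 kb in gB
  pNull <- rep(0.5, 8)
  cr <- convergenceCriteria(4, 10000)
  one <- clusterThenConverge(testAssoc(w$ids, pA),
                             testAssoc(w$ids, pNull), w$map, w$genes, cr)
  expect_equal(nrow(one$geneHits), 0L)
  both <- clusterThenConverge(testAssoc(w$ids, pA),
                              testAssoc(w$ids, pA), w$map, w$genes, cr)
  expect_identical(both$geneHits$gene_id, "gB")
  expect_equal(both$geneHits$n_snps_a, 4L)
  expect_equal(both$geneHits$n_snps_b, 4L)
})

test_that("non-overlapping tagging SNPs converge under approach 2 only", {
  # six effect SNPs in one gene; sample A's signal is on the odd
  # members, sample B's on the even ones: no shared positive SNP
  pos <- c(seq(100000, 125000, by = 5000), 400000)
  map <- testMap(pos)
  genes <- GRanges("chr1", IRanges(95000, 130000)); names(genes) <- "g"
  pA <- rep(0.5, 7); pA[c(1, 3, 5)] <- 0.01
  pB <- rep(0.5, 7); pB[c(2, 4, 6)] <- 0.01
  cr <- convergenceCriteria(3, 25000)
  a1 <- convergeThenCluster(testAssoc(names(map), pA),
                            testAssoc(names(map), pB), map, genes, cr)
  a2 <- clusterThenConverge(testAssoc(names(map), pA),
                            testAssoc(names(map), pB), map, genes, cr)
  expect_equal(nrow(a1$geneHits), 0L)
  expect_identical(a2$geneHits$gene_id, "g")
})

test_that("disjoint SNP universes are an error", {
  aA <- testAssoc(c("a", "b"), c(0.5, 0.5))
  aB <- testAssoc(c("c", "d"), c(0.5, 0.5))
  w <- .toyWorld()
  expect_error(convergeThenCluster(aA, aB, w$map, w$genes),
               "disjoint")
  expect_error(clusterThenConverge(aA, aB, w$map, w$genes),
               "disjoint")
})

test_that("results are invariant to association-table row order", {
  w <- .toyWorld()
  set.seed(5)
  p <- runif(8, 0, 0.2)
  aA <- testAssoc(w$ids, p)
  aB <- testAssoc(w$ids, pmin(p + 0.01, 1))
  perm <- sample(8)
  r1 <- convergeThenCluster(aA, aB, w$map, w$genes)
  r2 <- convergeThenCluster(aA[perm, ], aB[perm, ], w$map[perm],
                            w$genes)
  expect_setequal(r1$reproducibleSnps, r2$reproducibleSnps)
  expect_identical(r1$geneHits$gene_id, r2$geneHits$gene_id)
})

test_that("criteria nesting and approach containment hold on random data", {
  set.seed(610)
  grid <- defaultCriteriaGrid()
  for (rep in 1:20) {
    map <- testMap(sort(sample.int(4e5, 300)))
    starts <- seq(10000, 350000, by = 70000)
    genes <- GRanges("chr1", IRanges(starts, width = 30000))
    names(genes) <- paste0("g", seq_along(genes))
    mkAssoc <- function() {
      p <- runif(300)
      p[sample(300, 60)] <- runif(60, 0, 0.049)
      testAssoc(names(map), p)
    }
    aA <- mkAssoc(); aB <- mkAssoc()
    gene1 <- lapply(grid, function(cr)
      convergeThenCluster(aA, aB, map, genes, cr)$geneHits$gene_id)
    gene2 <- lapply(grid, function(cr)
      clusterThenConverge(aA, aB, map, genes, cr)$geneHits$gene_id)
    names(gene1) <- names(gene2) <-
      sapply(grid, function(cr) paste0(cr@minSize, "/", cr@maxGap))
    for (gs in list(gene1, gene2)) {
      expect_true(all(gs[["3/10000"]] %in% gs[["3/25000"]]))
      expect_true(all(gs[["4/25000"]] %in% gs[["3/25000"]]))
      expect_true(all(gs[["4/10000"]] %in% gs[["4/25000"]]))
      expect_true(all(gs[["4/10000"]] %in% gs[["3/10000"]]))
    }
    # every approach-1 gene is an approach-2 gene at equal criteria
    for (k in seq_along(grid))
      expect_true(all(gene1[[k]] %in% gene2[[k]]))
  }
})

test_that("the grid summary reflects the nesting structure", {
  w <- .toyWorld()
  set.seed(11)
  p <- c(0.01, 0.01, 0.01, 0.02, 0.02, 0.02, 0.02, 0.5)
  aA <- testAssoc(w$ids, p); aB <- testAssoc(w$ids, p)
  s <- criteriaGridSummary(aA, aB, w$map, w$genes)
  expect_equal(nrow(s), 8L)
  a1 <- s[s$approach == 1, ]
  expect_true(all(a1$overlap_primary == a1$n_genes))
  expect_true(all(a1$n_genes <= a1$n_genes[1]))
  expect_true(all(s$n_genes[s$approach == 1] <=
                    max(s$n_genes[s$approach == 2])))
})
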