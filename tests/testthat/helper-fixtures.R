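# Shared fixture builders. Everything is generated in code; no files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(S4Vectors)
})

testMap <- function(pos, chrom = "chr1", ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(pos))
  makeSnpMap(data.frame(snp_id = ids, chrom = chrom, pos = pos))
}

# Panel whose pool means are exactly `values` (SNPs x pools): each pool
# gets nRep identical replicate arrays, optionally jittered.
testPanel <- function(values, phenotype, sampleLabel = "S",
                      map = NULL, nRep = 3, noiseSd = 0, seed = 1) {
  values <- as.matrix(values)
  nSnps <- nrow(values); nPools <- ncol(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nSnps))
  if (is.null(map)) map <- testMap(seq_len(nSnps) * 1000,
                                   ids = rownames(values))
  arr <- values[, rep(seq_len(nPools), each = nRep), drop = FALSE]
  if (noiseSd > 0) {
    set.seed(seed)
    arr <- arr + matrix(rnorm(length(arr), 0, noiseSd), nrow(arr))
  }
  arr <- pmin(pmax(arr, 0), pi / 2)
  PoolPanel(arr, map,
            poolId = rep(sprintf("p%02d", seq_len(nPools)), each = nRep),
            replicate = rep(seq_len(nRep), nPools),
            phenotype = rep(phenotype, each = nRep),
            sampleLabel = sampleLabel)
}

# Association table built directly from p-values (direction +1), for
# tests that exercise clustering/convergence downstream of the t test.
testAssoc <- function(ids, p) {
  DataFrame(snp_id = ids, t = qt(1 - p / 2, df = 10), df = 10, p = p,
            direction = 1, ratio = 1, n_case_pools = 3L,
            n_control_pools = 3L, degenerate = FALSE)
}

# Independent chain-enumeration oracle: walk positions left to right,
# extend a chain while the next gap is within maxGap, report maximal
# chains of at least minSize members.
bruteChains <- function(pos, maxGap, minSize) {
  stopifnot(!is.unsorted(pos, strictly = TRUE))
  out <- NULL
  i <- 1; n <- length(pos)
  while (i <= n) {
    j <- i
    while (j < n && pos[j + 1] - pos[j] <= maxGap) j <- j + 1
    if (j - i + 1 >= minSize)
      out <- rbind(out, data.frame(start = pos[i], end = pos[j],
                                   size = j - i + 1))
    i <- j + 1
  }
  out
}

# Independent interval-scan oracle for gene support: count each
# cluster's member SNPs inside every flanked gene by explicit
# comparison.
bruteGeneSupport <- function(clusters, genes, minSize, flank = 10000) {
  hits <- list()
  for (g in seq_along(genes)) {
    lo <- max(start(genes)[g] - flank, 1)
    hi <- end(genes)[g] + flank
    total <- character()
    nc <- 0L
    for (k in seq_along(clusters)) {
      if (as.character(seqnames(clusters))[k] !=
          as.character(seqnames(genes))[g]) next
      pos <- clusters$snp_pos[[k]]
      inside <- pos >= lo & pos <= hi
      if (sum(inside) >= minSize) {
        nc <- nc + 1L
        total <- union(total, clusters$snp_id[[k]][inside])
      }
    }
    if (nc > 0)
      hits[[names(genes)[g]]] <- list(n_clusters = nc,
                                      n_snps = length(total))
  }
  hits
}
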