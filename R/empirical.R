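# Empirical null machinery: Monte Carlo resampling of pseudopositive
# SNPs from the real map, and phenotype-label permutation. All
# empirical p-values use the add-one convention
# p = (exceedances + 1) / (trials + 1), where a trial counts as an
# exceedance when its null statistic matched or exceeded the observed
# one; exhaustive enumeration reports the exact fraction instead.

#' Monte Carlo p-value for the overlap of two SNP sets
#'
#' Null model for the "reproducibly positive" SNP count of the
#' converge-then-cluster approach: per trial, two random subsets of the
#' stated sizes are drawn without replacement from the SNP universe and
#' their intersection size is recorded. Because the intersection of two
#' independent uniform subsets is exactly hypergeometric, the default
#' method draws trial statistics directly from that distribution;
#' \code{method = "sets"} samples the subsets explicitly (useful as a
#' cross-check on small universes).
#'
#' @param nUniverse number of SNPs in the universe.
#' @param nA,nB sizes of the two positive sets.
#' @param observedOverlap observed intersection size.
#' @param nTrials Monte Carlo trials (default 100000).
#' @param seed RNG seed.
#' @param method "hypergeometric" (default) or "sets".
#' @return An \code{\link{EmpiricalP}}.
#' @examples
#' mcOverlapP(20, 10, 10, 6, nTrials = 1000, seed = 1)
#' @export
mcOverlapP <- function(nUniverse, nA, nB, observedOverlap,
                       nTrials = 100000, seed = NULL,
                       method = c("hypergeometric", "sets")) {
  method <- match.arg(method)
  stopifnot(nA <= nUniverse, nB <= nUniverse)
  if (observedOverlap > min(nA, nB))
    stop("observed overlap exceeds the smaller set")
  trials <- withSeed(seed, {
    if (method == "hypergeometric") {
      rhyper(nTrials, nA, nUniverse - nA, nB)
    } else {
      vapply(seq_len(nTrials), function(i) {
        a <- sample.int(nUniverse, nA)
        b <- sample.int(nUniverse, nB)
        sum(!is.na(match(a, b)))
      }, numeric(1))
    }
  })
  empiricalPFromTrials(observedOverlap, trials, seed)
}

#' Monte Carlo p-value for SNP clustering extent (Monte Carlo I)
#'
#' Per trial, \code{nPositive} pseudopositive SNPs are sampled without
#' replacement from the real SNP map (preserving its spacing
#' structure), clusters are found under \code{criteria}, and the trial
#' statistic is the number of pseudopositive SNPs lying in qualifying
#' clusters. The empirical p is the add-one exceedance fraction for the
#' observed clustered-SNP count.
#'
#' @param map SNP map \code{GRanges}.
#' @param nPositive number of pseudopositive SNPs per trial.
#' @param criteria \code{\link{ConvergenceCriteria}}.
#' @param observed observed clustered-SNP count.
#' @param nTrials Monte Carlo trials (default 1000).
#' @param seed RNG seed.
#' @return An \code{\link{EmpiricalP}}.
#' @export
mcClusterP <- function(map, nPositive, criteria = convergenceCriteria(),
                       observed, nTrials = 1000, seed = NULL) {
  stopifnot(nPositive <= length(map))
  g <- globalCoords(map)
  trials <- withSeed(seed, {
    vapply(seq_len(nTrials), function(i) {
      clusteredSnpCount(g[sample.int(length(g), nPositive)],
                        criteria@maxGap, criteria@minSize)
    }, numeric(1))
  })
  empiricalPFromTrials(observed, trials, seed)
}

# Convergent gene count from two positive SNP id sets.
.convergentGenes <- function(posA, posB, map, genes, criteria, flank,
                             rule) {
  hitIds <- function(pos) {
    cl <- findClusters(map[names(map) %in% pos], criteria)
    assignClustersToGenes(cl, genes, criteria, flank, rule)$gene_id
  }
  intersect(hitIds(posA), hitIds(posB))
}

#' Monte Carlo p-value for cross-sample gene convergence (Monte Carlo
#' II)
#'
#' Null model for the cluster-then-converge gene count: per trial,
#' independent pseudopositive SNP sets of sizes \code{nPosA} and
#' \code{nPosB} are sampled without replacement from the real map, the
#' cluster-then-converge analysis is run on them, and the trial
#' statistic is the number of genes tagged by qualifying clusters from
#' both sets. Trial set sizes default to the raw per-sample
#' nominal-positive counts; pass the per-sample clustered-SNP counts
#' instead to match on clustered positives.
#'
#' @inheritParams mcClusterP
#' @param genes gene annotation \code{GRanges}.
#' @param nPosA,nPosB pseudopositive set size per sample.
#' @param observed observed convergent gene count.
#' @param flank gene flanking distance in bp.
#' @param rule gene-support rule, see
#'   \code{\link{assignClustersToGenes}}.
#' @return An \code{\link{EmpiricalP}}; its null mean also feeds
#'   \code{\link{truePositiveFraction}}.
#' @export
mcGeneConvergenceP <- function(map, genes, nPosA, nPosB,
                               criteria = convergenceCriteria(),
                               observed, nTrials = 200, seed = NULL,
                               flank = 10000,
                               rule = c("minSize", "anyOverlap")) {
  rule <- match.arg(rule)
  stopifnot(nPosA <= length(map), nPosB <= length(map))
  mach <- .mc2Machine(map, genes, criteria, flank, rule)
  g <- mach$coords
  n <- length(g)
  trials <- withSeed(seed, {
    vapply(seq_len(nTrials), function(i) {
      mach$count(sort(g[sample.int(n, nPosA)]),
                 sort(g[sample.int(n, nPosB)]))
    }, numeric(1))
  })
  empiricalPFromTrials(observed, trials, seed)
}

#' Per-gene Monte Carlo p-value (Monte Carlo III)
#'
#' Assigns an empirical p to one identified gene by asking how often a
#' randomly placed gene-resident genomic segment of the same length as
#' the gene's flanked interval displays features at least as strong as
#' the gene's. Segments are placed uniformly over all positions at
#' which they lie wholly within some annotated gene's flanked interval.
#' For approach 1 the feature is the count of clustered reproducible
#' SNPs inside the segment; for approach 2 it is the presence of a
#' qualifying cluster of each sample's positives inside the segment.
#'
#' @inheritParams mcGeneConvergenceP
#' @param geneId the identified gene to assess (must be in
#'   \code{genes}).
#' @param positivesA,positivesB nominally positive SNP ids per sample.
#' @param approach 1 (clustered reproducible SNP count) or 2
#'   (qualifying cluster from each sample).
#' @return An \code{\link{EmpiricalP}} whose observed statistic is the
#'   gene's own feature value.
#' @export
mcGeneLevelP <- function(geneId, genes, map, positivesA, positivesB,
                         criteria = convergenceCriteria(), approach = 1,
                         nTrials = 10000, seed = NULL, flank = 10000) {
  stopifnot(geneId %in% names(genes), approach %in% 1:2)
  fl <- flankGenes(genes, flank)
  target <- fl[geneId]
  L <- width(target)
  widths <- width(fl)
  eligible <- which(widths >= L)
  if (!length(eligible))
    stop("gene is longer than every annotated interval")
  w <- widths[eligible] - L + 1
  # per-chromosome sorted, deduplicated positive positions
  posByChrom <- function(ids) {
    sub <- map[names(map) %in% ids]
    lapply(split(start(sub), as.character(seqnames(sub))),
           function(p) sort(unique(p)))
  }
  bcA <- posByChrom(positivesA)
  bcB <- posByChrom(positivesB)
  bcR <- posByChrom(intersect(positivesA, positivesB))
  minSize <- criteria@minSize
  maxGap <- criteria@maxGap
  segmentFeature <- function(chrom, lo, hi) {
    clusteredIn <- function(bc) {
      pos <- bc[[chrom]]
      if (is.null(pos)) return(0L)
      i <- findInterval(c(lo - 1, hi), pos)
      if (i[2] - i[1] < minSize) return(0L)
      sel <- pos[(i[1] + 1):i[2]]
      first <- which(c(TRUE, diff(sel) > maxGap))
      size <- diff(c(first, length(sel) + 1L))
      sum(size[size >= minSize])
    }
    if (approach == 1) clusteredIn(bcR)
    else as.integer(clusteredIn(bcA) >= minSize &&
                    clusteredIn(bcB) >= minSize)
  }
  observed <- segmentFeature(as.character(seqnames(target)),
                             start(target), end(target))
  trials <- withSeed(seed, {
    gi <- sample(seq_along(eligible), nTrials, replace = TRUE,
                 prob = w / sum(w))
    off <- floor(runif(nTrials) * w[gi])
    segStart <- start(fl)[eligible[gi]] + off
    chroms <- as.character(seqnames(fl))[eligible[gi]]
    vapply(seq_len(nTrials), function(i) {
      segmentFeature(chroms[i], segStart[i], segStart[i] + L - 1)
    }, numeric(1))
  })
  empiricalPFromTrials(observed, trials, seed)
}

# Positive-call matrix for permutation chunks: given the pool-means
# matrix M (SNPs x pools), its elementwise square M2, and a 0/1 pool x
# trial case-membership matrix Ind (k cases per column), return the
# logical SNPs x trials matrix of nominal positives under a Welch test.
.posMatrix <- function(M, M2, Ind, k, alpha) {
  n <- ncol(M); n2 <- n - k
  S1 <- M %*% Ind; Q1 <- M2 %*% Ind
  S2 <- rowSums(M) - S1; Q2 <- rowSums(M2) - Q1
  m1 <- S1 / k; m2 <- S2 / n2
  v1 <- pmax((Q1 - k * m1 * m1) / (k - 1), 0)
  v2 <- pmax((Q2 - n2 * m2 * m2) / (n2 - 1), 0)
  a1 <- v1 / k; a2 <- v2 / n2
  se2 <- a1 + a2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2 * se2 / (a1 * a1 / (k - 1) + a2 * a2 / (n2 - 1))
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  p[se2 == 0] <- 1
  p < alpha
}

#' Phenotype-label permutation p-value
#'
#' Builds the permutation null of a full pipeline statistic by
#' reassigning case/control labels across pools --- the pool is the
#' permutation unit, and labels are shuffled within each sample
#' independently, preserving each sample's case/control pool counts.
#' The default statistic is the approach-1 reproducible-SNP count (the
#' number of SNPs nominally positive in both samples); any function of
#' the two per-sample association tables may be supplied instead. When
#' the number of distinct label assignments is at most \code{nTrials},
#' the null is enumerated exhaustively and the exact p is reported.
#'
#' @param panelA,panelB \code{\link{PoolPanel}}s for the two samples
#'   (same SNP universe).
#' @param alpha nominal per-SNP significance level for the default
#'   statistic.
#' @param nTrials permutation trials (default 10000).
#' @param seed RNG seed.
#' @param statistic NULL for the fast vectorized reproducible-SNP
#'   count, or \code{function(assocA, assocB)} returning one number.
#' @param chunkSize trials computed per matrix block (memory knob).
#' @return An \code{\link{EmpiricalP}}.
#' @export
permutationP <- function(panelA, panelB, alpha = 0.05, nTrials = 10000,
                         seed = NULL, statistic = NULL,
                         chunkSize = 250) {
  common <- intersect(rownames(panelA), rownames(panelB))
  if (length(common) == 0L)
    stop("the two panels share no SNPs: disjoint SNP universes")
  panelA <- panelA[common, ]; panelB <- panelB[common, ]
  dA <- poolDesign(panelA); dB <- poolDesign(panelB)
  kA <- sum(dA$phenotype == "case"); nA <- nrow(dA)
  kB <- sum(dB$phenotype == "case"); nB <- nrow(dB)
  nDistinct <- choose(nA, kA) * choose(nB, kB)
  exact <- nDistinct <= nTrials
  if (!is.null(statistic))
    return(.permuteGeneric(panelA, panelB, statistic, nTrials, seed,
                           exact))
  MA <- poolMeans(panelA); MB <- poolMeans(panelB)
  MA2 <- MA * MA; MB2 <- MB * MB
  obsPos <- function(M, M2, d, k) {
    ind <- matrix(as.numeric(d$phenotype == "case"), ncol = 1)
    .posMatrix(M, M2, ind, k, alpha)[, 1]
  }
  observed <- sum(obsPos(MA, MA2, dA, kA) & obsPos(MB, MB2, dB, kB))
  indMatrix <- function(combs, n) {
    ind <- matrix(0, n, ncol(combs))
    ind[cbind(as.vector(combs),
              rep(seq_len(ncol(combs)), each = nrow(combs)))] <- 1
    ind
  }
  if (exact) {
    PA <- .posMatrix(MA, MA2, indMatrix(combn(nA, kA), nA), kA, alpha)
    PB <- .posMatrix(MB, MB2, indMatrix(combn(nB, kB), nB), kB, alpha)
    counts <- crossprod(PA, PB)  # assignments A x assignments B
    return(empiricalPFromTrials(observed, as.vector(counts), seed,
                                exact = TRUE))
  }
  trials <- withSeed(seed, {
    out <- numeric(nTrials)
    done <- 0L
    while (done < nTrials) {
      m <- min(chunkSize, nTrials - done)
      cA <- vapply(seq_len(m), function(i) sample.int(nA, kA),
                   integer(kA))
      cB <- vapply(seq_len(m), function(i) sample.int(nB, kB),
                   integer(kB))
      PA <- .posMatrix(MA, MA2, indMatrix(cA, nA), kA, alpha)
      PB <- .posMatrix(MB, MB2, indMatrix(cB, nB), kB, alpha)
      out[done + seq_len(m)] <- colSums(PA & PB)
      done <- done + m
    }
    out
  })
  empiricalPFromTrials(observed, trials, seed)
}

# Slow generic path: permute pool phenotypes in colData and recompute
# the user statistic from full association tables.
.permuteGeneric <- function(panelA, panelB, statistic, nTrials, seed,
                            exact) {
  relabel <- function(panel, caseIdx) {
    d <- poolDesign(panel)
    ph <- ifelse(seq_len(nrow(d)) %in% caseIdx, "case", "control")
    panel$phenotype <- ph[match(panel$pool_id, d$pool_id)]
    panel
  }
  observed <- statistic(snpTTest(panelA), snpTTest(panelB))
  dA <- poolDesign(panelA); dB <- poolDesign(panelB)
  kA <- sum(dA$phenotype == "case"); nA <- nrow(dA)
  kB <- sum(dB$phenotype == "case"); nB <- nrow(dB)
  evalOne <- function(ia, ib) {
    statistic(snpTTest(relabel(panelA, ia)),
              snpTTest(relabel(panelB, ib)))
  }
  if (exact) {
    cA <- combn(nA, kA); cB <- combn(nB, kB)
    trials <- as.vector(vapply(seq_len(ncol(cA)), function(i)
      vapply(seq_len(ncol(cB)), function(j)
        evalOne(cA[, i], cB[, j]), numeric(1)), numeric(ncol(cB))))
    return(empiricalPFromTrials(observed, trials, seed, exact = TRUE))
  }
  trials <- withSeed(seed, {
    vapply(seq_len(nTrials), function(i)
      evalOne(sample.int(nA, kA), sample.int(nB, kB)), numeric(1))
  })
  empiricalPFromTrials(observed, trials, seed)
}

#' Fraction of identified genes expected to be true positives
#'
#' (observed - null mean) / observed, clamped to [0, 1]: the average
#' fraction of an identified gene list not attributable to the
#' resampling null, with the null mean taken from the matching Monte
#' Carlo analysis (e.g. \code{\link{mcGeneConvergenceP}}).
#'
#' @param observed observed gene count.
#' @param null an \code{\link{EmpiricalP}} (its null mean is used) or a
#'   numeric null mean.
#' @return Fraction in [0, 1]; NA with a warning when \code{observed}
#'   is zero.
#' @export
truePositiveFraction <- function(observed, null) {
  nm <- if (is(null, "EmpiricalP")) nullMean(null) else as.numeric(null)
  if (observed == 0) {
    warning("observed gene count is zero; fraction undefined")
    return(NA_real_)
  }
  min(max((observed - nm) / observed, 0), 1)
}
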