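# Synthetic pooled-GWA data with the statistical structure the
# analysis assumes: two populations, case/control pools of ~20
# individuals, replicate-array noise, LD-like blocks of planted
# effects, and a pooled-vs-individual validation design.

#' Measurement noise model for pooled arrays
#'
#' Replicate-array noise is additive Gaussian on the arctan scale with
#' standard deviation \code{replicateSd}; the default 0.03 * sqrt(3)
#' makes the standard error of a 3-replicate pool mean 0.03, the
#' replicate-to-replicate variability the pooled design is calibrated
#' to. Pool-to-pool variability needs no separate knob: it arises from
#' binomial sampling of 2 x n_individuals chromosomes per pool, which
#' at the generator's default allele frequencies yields an across-pool
#' SEM near 0.02 for 20-pool groups.
#'
#' @param replicateSd per-array noise SD on the arctan scale.
#' @return list with element \code{replicateSd}.
#' @export
noiseModel <- function(replicateSd = 0.03 * sqrt(3)) {
  stopifnot(replicateSd >= 0)
  list(replicateSd = replicateSd)
}

#' Simulate a SNP map and non-overlapping gene annotation
#'
#' SNP positions are uniform within each chromosome; gene intervals are
#' non-overlapping, with lengths uniform in \code{geneLengthRange} and
#' random inter-gene gaps. Deterministic given \code{seed}.
#'
#' @param nSnps total SNPs.
#' @param nChromosomes autosomes to spread them over.
#' @param nGenes gene intervals to place.
#' @param meanGap mean inter-SNP spacing in bp (sets chromosome
#'   length; default 3000, the density of a ~1M-SNP array genome).
#' @param geneLengthRange min/max gene length in bp.
#' @param seed RNG seed.
#' @return list with \code{map} and \code{genes} (\code{GRanges}).
#' @examples
#' sim <- simulateMapAndGenes(1000, 1, 10, seed = 1)
#' @export
simulateMapAndGenes <- function(nSnps, nChromosomes = 2, nGenes,
                                meanGap = 3000,
                                geneLengthRange = c(20000, 100000),
                                seed = NULL) {
  stopifnot(nSnps >= nGenes)
  chromLen <- ceiling(nSnps * meanGap / nChromosomes)
  withSeed(seed, {
    perChrom <- diff(round(seq(0, nSnps, length.out = nChromosomes + 1)))
    map <- suppressWarnings(do.call(c, lapply(seq_len(nChromosomes),
                                              function(ch) {
      pos <- sort(sample.int(chromLen, perChrom[ch]))
      GRanges(paste0("chr", ch), IRanges(pos, width = 1))
    })))
    names(map) <- paste0("snp", sprintf("%06d", seq_len(nSnps)))
    genesPerChrom <- diff(round(seq(0, nGenes,
                                    length.out = nChromosomes + 1)))
    genes <- suppressWarnings(do.call(c, lapply(seq_len(nChromosomes),
                                                function(ch) {
      ng <- genesPerChrom[ch]
      if (ng == 0L) return(GRanges())
      len <- round(runif(ng, geneLengthRange[1], geneLengthRange[2]))
      slack <- chromLen - sum(len)
      if (slack <= ng)
        stop("infeasible gene density: total gene length exceeds ",
             "chromosome length")
      cuts <- sort(sample.int(slack, ng))
      starts <- cuts + c(0, cumsum(len))[seq_len(ng)]
      GRanges(paste0("chr", ch), IRanges(starts, width = len))
    })))
    names(genes) <- paste0("gene", sprintf("%04d", seq_len(nGenes)))
    list(map = map, genes = genes)
  })
}

#' Simulate population allele frequencies
#'
#' Draws a base minor-allele frequency per SNP uniformly on
#' \code{mafRange} (default 0.05-0.28, the range at which binomial
#' pool-composition variance reproduces the targeted across-pool SEM of
#' 0.02 for 20-individual pools), flips it to the complementary allele
#' with probability 1/2, and adds an independent Gaussian
#' population-divergence shift per additional population, clamped to
#' [0.05, 0.95].
#'
#' @param map SNP map \code{GRanges}.
#' @param populations character vector of population names.
#' @param mafRange base minor-allele-frequency range.
#' @param divergenceSd SD of the between-population frequency shift.
#' @param seed RNG seed.
#' @return Numeric matrix, SNPs x populations, of allele frequencies.
#' @export
simulateAlleleFreqs <- function(map, populations = c("A", "B"),
                                mafRange = c(0.05, 0.28),
                                divergenceSd = 0.05, seed = NULL) {
  n <- length(map)
  withSeed(seed, {
    maf <- runif(n, mafRange[1], mafRange[2])
    flip <- runif(n) < 0.5
    base <- ifelse(flip, 1 - maf, maf)
    out <- vapply(seq_along(populations), function(i) {
      f <- if (i == 1) base else base + rnorm(n, 0, divergenceSd)
      pmin(pmax(f, 0.05), 0.95)
    }, numeric(n))
    dimnames(out) <- list(names(map), populations)
    out
  })
}

#' Plant clustered case-control effects
#'
#' Chooses \code{nLoci} genes that contain a run of
#' \code{snpsPerBlock} consecutive SNPs spanning at most
#' \code{blockSpan} bp, and marks those runs as LD-like effect blocks:
#' every member SNP's case allele frequency is shifted by
#' \code{effectSize} (toward 0.5, so shifted frequencies stay in
#' range). With \code{tagging = "shared"} the same member SNPs carry
#' the effect in both populations; with \code{"disjoint"} alternating
#' members tag it in each population --- a fixture for the designed
#' difference between the two convergence approaches, which does not
#' require the identical SNPs to be significant in both samples.
#'
#' @param map,genes simulated map and annotation.
#' @param nLoci planted blocks (0 gives a pure null).
#' @param effectSize case-minus-control allele-frequency difference
#'   (default 0.10).
#' @param blockSpan maximum bp span of a block (default 25000).
#' @param snpsPerBlock consecutive SNPs per block (default 6).
#' @param populations population names (matched by
#'   \code{\link{simulatePools}}).
#' @param tagging "shared" or "disjoint".
#' @param seed RNG seed.
#' @return A \code{\link{SyntheticTruth}}.
#' @export
plantEffects <- function(map, genes, nLoci, effectSize = 0.10,
                         blockSpan = 25000, snpsPerBlock = 6,
                         populations = c("A", "B"),
                         tagging = c("shared", "disjoint"),
                         seed = NULL) {
  tagging <- match.arg(tagging)
  emptyLoci <- data.frame(locus = integer(), gene_id = character(),
                          chrom = character(), start = integer(),
                          end = integer(), n_snps = integer())
  if (nLoci == 0L)
    return(new("SyntheticTruth", loci = emptyLoci,
               effectSnps = character(),
               tagged = setNames(rep(list(character()), length(populations)),
                                 populations),
               effectSize = effectSize,
               seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
  ov <- findOverlaps(map, genes)
  bySnp <- split(queryHits(ov), subjectHits(ov))
  candidates <- list()
  for (g in names(bySnp)) {
    idx <- bySnp[[g]]
    pos <- start(map)[idx]
    o <- order(pos); idx <- idx[o]; pos <- pos[o]
    m <- length(pos)
    if (m < snpsPerBlock) next
    ok <- which(pos[seq_len(m - snpsPerBlock + 1) + snpsPerBlock - 1] -
                  pos[seq_len(m - snpsPerBlock + 1)] <= blockSpan)
    if (length(ok))
      candidates[[g]] <- idx[ok[1]:(ok[1] + snpsPerBlock - 1)]
  }
  if (length(candidates) < nLoci)
    stop("not enough genic SNP runs to plant ", nLoci, " loci (",
         length(candidates), " available)")
  withSeed(seed, {
    chosen <- sample(names(candidates), nLoci)
    loci <- lapply(seq_along(chosen), function(i) {
      idx <- candidates[[chosen[i]]]
      data.frame(locus = i,
                 gene_id = names(genes)[as.integer(chosen[i])],
                 chrom = as.character(seqnames(map))[idx[1]],
                 start = min(start(map)[idx]),
                 end = max(start(map)[idx]), n_snps = length(idx))
    })
    allIdx <- unlist(lapply(chosen, function(g) candidates[[g]]))
    ids <- names(map)[allIdx]
    tagged <- if (tagging == "shared") {
      setNames(rep(list(ids), length(populations)), populations)
    } else {
      blocks <- split(ids, rep(seq_along(chosen), each = snpsPerBlock))
      setNames(lapply(seq_along(populations), function(pi) {
        unlist(lapply(blocks, function(b)
          b[seq_along(b) %% length(populations) == pi %% length(populations)]),
          use.names = FALSE)
      }), populations)
    }
    new("SyntheticTruth", loci = do.call(rbind, loci), effectSnps = ids,
        tagged = tagged, effectSize = effectSize,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

#' Pool design table
#'
#' One row per pool: case pools first, then control pools, with the
#' stated number of pooled individuals and replicate arrays each.
#'
#' @param nCase,nControl case and control pool counts.
#' @param sampleLabel sample (population) label.
#' @param nIndividuals individuals per pool (default 20).
#' @param nReplicates replicate arrays per pool (default 3).
#' @return data.frame with columns \code{pool_id},
#'   \code{sample_label}, \code{phenotype}, \code{n_individuals},
#'   \code{n_replicates}.
#' @export
poolDesignTable <- function(nCase, nControl, sampleLabel = "S1",
                            nIndividuals = 20, nReplicates = 3) {
  stopifnot(nCase >= 1, nControl >= 1, nReplicates >= 1)
  data.frame(
    pool_id = paste0(sampleLabel, ".",
                     c(sprintf("case%02d", seq_len(nCase)),
                       sprintf("ctrl%02d", seq_len(nControl)))),
    sample_label = sampleLabel,
    phenotype = rep(c("case", "control"), c(nCase, nControl)),
    n_individuals = nIndividuals, n_replicates = nReplicates)
}

#' Simulate replicate pooled-array measurements for one sample
#'
#' Each pool's allele frequency is a binomial draw of
#' 2 x n_individuals chromosomes from the population frequency (plus
#' the planted effect for case pools at tagged SNPs, shifted toward
#' 0.5); each replicate array measures arctan(f / (1 - f)) plus
#' Gaussian replicate noise, clipped to [0, pi/2].
#'
#' @param map SNP map \code{GRanges}.
#' @param design pool design from \code{\link{poolDesignTable}}.
#' @param baseFreq numeric vector of population allele frequencies per
#'   SNP (one column of \code{\link{simulateAlleleFreqs}}).
#' @param truth optional \code{\link{SyntheticTruth}}; effects apply to
#'   the SNPs it tags for \code{population}.
#' @param population population name used to look up tagged SNPs.
#' @param noise \code{\link{noiseModel}}.
#' @param seed RNG seed.
#' @return A \code{\link{PoolPanel}}.
#' @export
simulatePools <- function(map, design, baseFreq, truth = NULL,
                          population = design$sample_label[1],
                          noise = noiseModel(), seed = NULL) {
  nSnps <- length(map)
  stopifnot(length(baseFreq) == nSnps)
  if (any(baseFreq < 0 | baseFreq > 1))
    stop("allele frequencies must lie in [0, 1]")
  nPools <- nrow(design)
  tagged <- if (is.null(truth)) character()
    else truth@tagged[[population]]
  effIdx <- which(names(map) %in% tagged)
  eff <- numeric(nSnps)
  if (length(effIdx)) {
    shift <- ifelse(baseFreq[effIdx] <= 0.5, truth@effectSize,
                    -truth@effectSize)
    eff[effIdx] <- shift
    if (any(baseFreq[effIdx] + shift < 0 | baseFreq[effIdx] + shift > 1))
      stop("planted effect pushes allele frequency outside [0, 1]")
  }
  withSeed(seed, {
    chrom2 <- 2 * design$n_individuals
    poolFreq <- vapply(seq_len(nPools), function(j) {
      f <- baseFreq + if (design$phenotype[j] == "case") eff else 0
      rbinom(nSnps, chrom2[j], f) / chrom2[j]
    }, numeric(nSnps))
    trueArctan <- atan2(poolFreq, 1 - poolFreq)
    nRep <- design$n_replicates
    arr <- do.call(cbind, lapply(seq_len(nPools), function(j) {
      vals <- trueArctan[, j] +
        matrix(rnorm(nSnps * nRep[j], 0, noise$replicateSd), nSnps)
      pmin(pmax(vals, 0), pi / 2)
    }))
    PoolPanel(arr, map,
              poolId = rep(design$pool_id, nRep),
              replicate = unlist(lapply(nRep, seq_len)),
              phenotype = rep(design$phenotype, nRep),
              sampleLabel = rep(design$sample_label, nRep),
              nIndividuals = rep(design$n_individuals, nRep))
  })
}

#' Simulate a complete two-sample pooled study
#'
#' Convenience wrapper reproducing the full study structure: a map and
#' gene annotation, two populations with divergent allele frequencies,
#' planted clustered effects shared across populations, and one
#' \code{\link{PoolPanel}} per sample. All randomness flows from one
#' master seed through named substreams (map, freq, truth, pools.A,
#' pools.B).
#'
#' @param nSnps SNPs (default 20000).
#' @param nGenes genes (default nSnps / 100).
#' @param nChromosomes autosomes (default 2).
#' @param designA,designB c(case, control) pool counts per sample
#'   (defaults 20+14 and 35+12, the study's pool counts).
#' @param nLoci planted effect blocks (default 0: pure null).
#' @param effectSize planted allele-frequency difference (default
#'   0.10).
#' @param blockSpan,snpsPerBlock block geometry (defaults 25 kb, 6).
#' @param tagging "shared" or "disjoint" per-population tagging.
#' @param nIndividuals individuals per pool (default 20).
#' @param nReplicates replicate arrays per pool (default 3).
#' @param divergenceSd between-population frequency-shift SD.
#' @param noise \code{\link{noiseModel}}.
#' @param seed master seed.
#' @return list with \code{map}, \code{genes}, \code{freqs},
#'   \code{truth}, \code{panels} (list \code{A}, \code{B}).
#' @examples
#' study <- simulateStudy(nSnps = 500, nGenes = 5, nLoci = 1, seed = 1)
#' @export
simulateStudy <- function(nSnps = 20000, nGenes = round(nSnps / 100),
                          nChromosomes = 2,
                          designA = c(case = 20, control = 14),
                          designB = c(case = 35, control = 12),
                          nLoci = 0, effectSize = 0.10,
                          blockSpan = 25000, snpsPerBlock = 6,
                          tagging = "shared", nIndividuals = 20,
                          nReplicates = 3, divergenceSd = 0.05,
                          noise = noiseModel(), seed = NULL) {
  mg <- simulateMapAndGenes(nSnps, nChromosomes, nGenes,
                            seed = deriveSeed(seed, "map"))
  freqs <- simulateAlleleFreqs(mg$map, c("A", "B"),
                               divergenceSd = divergenceSd,
                               seed = deriveSeed(seed, "freq"))
  truth <- plantEffects(mg$map, mg$genes, nLoci, effectSize, blockSpan,
                        snpsPerBlock, c("A", "B"), tagging,
                        seed = deriveSeed(seed, "truth"))
  dA <- poolDesignTable(designA[1], designA[2], "A", nIndividuals,
                        nReplicates)
  dB <- poolDesignTable(designB[1], designB[2], "B", nIndividuals,
                        nReplicates)
  panels <- list(
    A = simulatePools(mg$map, dA, freqs[, "A"], truth, "A", noise,
                      deriveSeed(seed, "pools.A")),
    B = simulatePools(mg$map, dB, freqs[, "B"], truth, "B", noise,
                      deriveSeed(seed, "pools.B")))
  list(map = mg$map, genes = mg$genes, freqs = freqs, truth = truth,
       panels = panels)
}

#' Simulate the pooled-vs-individual validation design
#'
#' Individuals with known simulated genotypes are assigned to pools of
#' several sizes; "expected" allele frequencies are the realized pooled
#' genotype frequencies, and "observed" values are the arctan measure
#' of those frequencies plus replicate noise. The agreement between
#' the two, summarized by \code{\link{validationCorrelation}} over
#' SNPs whose expected frequencies spread by at least 10 percent
#' across pools, validates the pooled measure.
#'
#' @param nSnps SNPs to simulate (default 2000).
#' @param poolSizes individuals per pool; the default
#'   \code{rep(c(2, 5, 15), c(3, 3, 4))} assigns 81 individuals to
#'   three sets of pools of 2, 5 and 15.
#' @param nReplicates replicate arrays per pool (default 3).
#' @param freqRange allele-frequency range for simulated SNPs.
#' @param noise \code{\link{noiseModel}}.
#' @param seed RNG seed.
#' @return list with \code{expectedFreq} and \code{observedArctan}
#'   (SNPs x pools matrices) and \code{poolSizes}.
#' @export
simulateValidationDesign <- function(nSnps = 2000,
                                     poolSizes = rep(c(2, 5, 15),
                                                     c(3, 3, 4)),
                                     nReplicates = 3,
                                     freqRange = c(0.05, 0.95),
                                     noise = noiseModel(),
                                     seed = NULL) {
  nInd <- sum(poolSizes)
  nPools <- length(poolSizes)
  withSeed(seed, {
    f <- runif(nSnps, freqRange[1], freqRange[2])
    geno <- matrix(rbinom(nSnps * nInd, 2, rep(f, nInd)), nSnps)
    poolOf <- rep(seq_len(nPools), poolSizes)
    expected <- vapply(seq_len(nPools), function(j) {
      rowSums(geno[, poolOf == j, drop = FALSE]) / (2 * poolSizes[j])
    }, numeric(nSnps))
    trueArctan <- atan2(expected, 1 - expected)
    observed <- vapply(seq_len(nPools), function(j) {
      reps <- trueArctan[, j] +
        matrix(rnorm(nSnps * nReplicates, 0, noise$replicateSd), nSnps)
      rowMeans(pmin(pmax(reps, 0), pi / 2))
    }, numeric(nSnps))
    dimnames(expected) <- dimnames(observed) <-
      list(paste0("snp", seq_len(nSnps)), paste0("pool", seq_len(nPools)))
    list(expectedFreq = expected, observedArctan = observed,
         poolSizes = poolSizes)
  })
}

#' @param vd result of \code{\link{simulateValidationDesign}}.
#' @param minSpread minimum across-pool spread of expected frequencies
#'   for a SNP to enter the correlation (default 0.10).
#' @rdname simulateValidationDesign
#' @export
validationCorrelation <- function(vd, minSpread = 0.10) {
  spread <- apply(vd$expectedFreq, 1, function(z) max(z) - min(z))
  keep <- spread >= minSpread
  if (!any(keep)) stop("no SNPs reach the required frequency spread")
  expArctan <- atan2(vd$expectedFreq[keep, ], 1 - vd$expectedFreq[keep, ])
  stats::cor(as.vector(expArctan), as.vector(vd$observedArctan[keep, ]))
}
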