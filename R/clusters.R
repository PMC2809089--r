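# Distance-based clustering of positive SNPs.

# Core single-linkage chain finder on one chromosome's sorted,
# deduplicated positions: a cluster is a maximal run in which every
# consecutive gap is <= maxGap, reported when its size >= minSize.
# Returns start/end indices into `pos` for each qualifying cluster.
chainClusters <- function(pos, maxGap, minSize) {
  if (is.unsorted(pos, strictly = TRUE))
    stop("positions must be sorted and deduplicated")
  n <- length(pos)
  if (n == 0L)
    return(data.frame(first = integer(), last = integer(),
                      size = integer()))
  newRun <- c(TRUE, diff(pos) > maxGap)
  runId <- cumsum(newRun)
  first <- which(newRun)
  last <- c(first[-1] - 1L, n)
  size <- last - first + 1L
  keep <- size >= minSize
  data.frame(first = first[keep], last = last[keep], size = size[keep])
}

#' Find clusters of positive SNPs
#'
#' Chains SNPs on each chromosome into maximal clusters in which every
#' consecutive pair of members is separated by at most
#' \code{maxGap(criteria)} bp, and keeps clusters of at least
#' \code{minSize(criteria)} members. Chaining (single linkage on
#' consecutive gaps) is used rather than a diameter rule because it is
#' deterministic and yields a unique maximal partition; clusters on a
#' chromosome are disjoint, every positive SNP belongs to at most one
#' cluster, and the output is independent of input order.
#'
#' @param snps width-1 \code{GRanges} of positive SNPs, named by SNP id
#'   (e.g. a subset of a SNP map).
#' @param criteria a \code{\link{ConvergenceCriteria}} object.
#' @return \code{GRanges} of cluster spans (first to last member) with
#'   metadata columns \code{n_snps}, \code{snp_id} (CharacterList of
#'   members in positional order) and \code{snp_pos} (IntegerList).
#' @examples
#' m <- makeSnpMap(data.frame(snp_id = paste0("s", 1:3), chrom = "chr1",
#'                            pos = c(100, 10100, 20100)))
#' findClusters(m, convergenceCriteria(3, 25000))
#' @export
findClusters <- function(snps, criteria = convergenceCriteria()) {
  stopifnot(is(snps, "GRanges"), is(criteria, "ConvergenceCriteria"))
  if (is.null(names(snps))) stop("SNPs must be named by identifier")
  o <- order(as.factor(seqnames(snps)), start(snps))
  snps <- snps[o]
  chrs <- as.character(seqnames(snps))
  out <- lapply(unique(chrs), function(ch) {
    sub <- snps[chrs == ch]
    cc <- chainClusters(start(sub), criteria@maxGap, criteria@minSize)
    if (nrow(cc) == 0L) return(NULL)
    gr <- GRanges(ch, IRanges(start(sub)[cc$first], start(sub)[cc$last]))
    gr$n_snps <- cc$size
    memIdx <- sequence(cc$size, from = cc$first)
    fac <- factor(rep(seq_len(nrow(cc)), cc$size))
    gr$snp_id <- unname(splitAsList(names(sub)[memIdx], fac))
    gr$snp_pos <- unname(splitAsList(start(sub)[memIdx], fac))
    gr
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    g <- GRanges()
    mcols(g) <- DataFrame(n_snps = integer(), snp_id = CharacterList(),
                          snp_pos = IntegerList())
    return(g)
  }
  unname(suppressWarnings(do.call(c, out)))
}

# Total number of SNPs lying in qualifying clusters --- the
# "clustered SNP" count reported in the summary tables. Fast path on precomputed global coordinates
# (chromosomes offset far apart so chains never span chromosomes).
clusteredSnpCount <- function(globalPos, maxGap, minSize) {
  sp <- sort(globalPos)
  if (length(sp) == 0L) return(0L)
  newRun <- c(TRUE, diff(sp) > maxGap)
  first <- which(newRun)
  size <- diff(c(first, length(sp) + 1L))
  sum(size[size >= minSize])
}

# Encode (chromosome, position) as a single numeric coordinate with
# chromosomes separated by more than any physical gap, for fast
# resampling arithmetic.
.globalEncode <- function(map) {
  levels <- unique(as.character(seqnames(map)))
  offset <- max(as.numeric(end(map))) + 1e9
  list(levels = levels, offset = offset,
       snp = match(as.character(seqnames(map)), levels) * offset +
         as.numeric(start(map)))
}

globalCoords <- function(map) .globalEncode(map)$snp

# Closure computing, for sorted global positive coordinates of the two
# samples, the number of genes supported by a qualifying cluster from
# each --- the Monte Carlo II trial statistic, without any GRanges
# allocation per trial. Semantics mirror assignClustersToGenes: a
# cluster qualifies globally (>= minSize members) and supports a gene
# when >= `need` of its members fall in the flanked gene interval.
.mc2Machine <- function(map, genes, criteria, flank, rule) {
  enc <- .globalEncode(map)
  gi <- match(as.character(seqnames(genes)), enc$levels)
  keep <- which(!is.na(gi))
  lo <- gi[keep] * enc$offset + pmax(start(genes)[keep] - flank, 1)
  hi <- gi[keep] * enc$offset + end(genes)[keep] + flank
  need <- if (rule == "minSize") criteria@minSize else 1L
  minSize <- criteria@minSize
  maxGap <- criteria@maxGap
  supported <- function(sp) {
    out <- logical(length(lo))
    m <- length(sp)
    if (m == 0L) return(out)
    first <- which(c(TRUE, diff(sp) > maxGap))
    last <- c(first[-1] - 1L, m)
    ok <- (last - first + 1L) >= minSize
    a <- findInterval(lo - 1, sp) + 1L
    b <- findInterval(hi, sp)
    for (gj in which(b - a + 1L >= need)) {
      r1 <- findInterval(a[gj], first)
      r2 <- findInterval(b[gj], first)
      for (r in r1:r2) {
        if (!ok[r]) next
        if (min(last[r], b[gj]) - max(first[r], a[gj]) + 1L >= need) {
          out[gj] <- TRUE
          break
        }
      }
    }
    out
  }
  list(coords = enc$snp,
       count = function(spA, spB) sum(supported(spA) & supported(spB)))
}
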