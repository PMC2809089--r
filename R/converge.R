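# The two convergence strategies across independent samples.

.checkUniverse <- function(assocA, assocB) {
  common <- intersect(assocA$snp_id, assocB$snp_id)
  if (length(common) == 0L)
    stop("the two samples share no SNPs: disjoint SNP universes")
  common
}

#' Converge then cluster (approach 1)
#'
#' Intersects the two samples' nominally positive SNP sets first
#' ("reproducibly positive" SNPs: nominally significant in both
#' samples, with no requirement on the direction of effect), then
#' clusters the shared SNPs by genomic distance and assigns clusters to
#' genes. A gene is reported when a qualifying cluster places at least
#' \code{minSize(criteria)} reproducible SNPs inside the gene's flanked
#' interval.
#'
#' @param assocA,assocB association tables from \code{\link{snpTTest}}
#'   for the two independent samples (same SNP universe).
#' @param map SNP map \code{GRanges} named by SNP id.
#' @param genes gene annotation \code{GRanges} named by gene id.
#' @param criteria \code{\link{ConvergenceCriteria}} (cluster size,
#'   gap, nominal alpha).
#' @param flank gene flanking distance in bp (default 10000).
#' @param rule gene-support rule, see
#'   \code{\link{assignClustersToGenes}}.
#' @return A list: \code{reproducibleSnps} (character),
#'   \code{clusters} (\code{GRanges}), \code{geneHits}
#'   (\code{DataFrame}), \code{nPositiveA}, \code{nPositiveB},
#'   \code{nClusteredSnps}.
#' @seealso \code{\link{clusterThenConverge}} for the complementary
#'   strategy that tolerates different tagging SNPs per sample.
#' @export
convergeThenCluster <- function(assocA, assocB, map, genes,
                                criteria = convergenceCriteria(),
                                flank = 10000,
                                rule = c("minSize", "anyOverlap")) {
  rule <- match.arg(rule)
  .checkUniverse(assocA, assocB)
  posA <- nominalPositives(assocA, criteria@alpha)
  posB <- nominalPositives(assocB, criteria@alpha)
  repro <- intersect(posA, posB)
  snps <- map[names(map) %in% repro]
  clusters <- findClusters(snps, criteria)
  geneHits <- assignClustersToGenes(clusters, genes, criteria, flank,
                                    rule)
  list(reproducibleSnps = repro, clusters = clusters,
       geneHits = geneHits, nPositiveA = length(posA),
       nPositiveB = length(posB),
       nClusteredSnps = sum(clusters$n_snps))
}

#' Cluster then converge (approach 2)
#'
#' Clusters each sample's own nominally positive SNPs first, assigns
#' each sample's clusters to genes, and reports the genes tagged by at
#' least one qualifying cluster from \emph{each} sample. Because the
#' two samples need not share any individual positive SNP, this
#' approach tolerates allelic heterogeneity and population differences
#' in linkage disequilibrium that make the same underlying signal tag
#' different SNPs in different samples.
#'
#' @inheritParams convergeThenCluster
#' @return A list: \code{geneHits} (\code{DataFrame} with per-sample
#'   supporting SNP counts \code{n_snps_a}, \code{n_snps_b}),
#'   \code{clustersA}, \code{clustersB}, \code{hitsA}, \code{hitsB}
#'   (per-sample assignments), \code{nClusteredA}, \code{nClusteredB}
#'   (SNPs in qualifying clusters per sample), and
#'   \code{nConvergentSnps} (clustered SNPs, both samples pooled, whose
#'   clusters support a convergent gene).
#' @export
clusterThenConverge <- function(assocA, assocB, map, genes,
                                criteria = convergenceCriteria(),
                                flank = 10000,
                                rule = c("minSize", "anyOverlap")) {
  rule <- match.arg(rule)
  .checkUniverse(assocA, assocB)
  posA <- nominalPositives(assocA, criteria@alpha)
  posB <- nominalPositives(assocB, criteria@alpha)
  clustersToGenes <- function(pos) {
    snps <- map[names(map) %in% pos]
    cl <- findClusters(snps, criteria)
    list(clusters = cl,
         hits = assignClustersToGenes(cl, genes, criteria, flank, rule))
  }
  a <- clustersToGenes(posA)
  b <- clustersToGenes(posB)
  shared <- intersect(a$hits$gene_id, b$hits$gene_id)
  ia <- match(shared, a$hits$gene_id)
  ib <- match(shared, b$hits$gene_id)
  geneHits <- DataFrame(
    gene_id = shared,
    chromosome = a$hits$chromosome[ia],
    start = a$hits$start[ia], end = a$hits$end[ia],
    n_snps_a = a$hits$n_snps[ia], n_snps_b = b$hits$n_snps[ib],
    snp_id_a = a$hits$snp_id[ia], snp_id_b = b$hits$snp_id[ib])
  convergent <- length(unique(c(
    unlist(geneHits$snp_id_a, use.names = FALSE),
    unlist(geneHits$snp_id_b, use.names = FALSE))))
  list(geneHits = geneHits, clustersA = a$clusters,
       clustersB = b$clusters, hitsA = a$hits, hitsB = b$hits,
       nClusteredA = sum(a$clusters$n_snps),
       nClusteredB = sum(b$clusters$n_snps),
       nConvergentSnps = convergent)
}

#' Criteria-grid summary of both convergence approaches
#'
#' Runs both convergence strategies over a grid of clustering criteria
#' and tabulates, per row: the approach, the criteria, per-sample
#' clustered-SNP counts (approach 2), the convergent/reproducible
#' clustered SNP count, the number of genes found, and the overlap of
#' each gene set with the gene set of the first grid row (the primary,
#' preplanned analysis). Stricter criteria always yield gene subsets of
#' looser ones.
#'
#' @inheritParams convergeThenCluster
#' @param grid list of \code{\link{ConvergenceCriteria}}; default
#'   crosses sizes \{3, 4\} with gaps \{25 kb, 10 kb\}.
#' @return data.frame, one row per (approach, criteria).
#' @export
criteriaGridSummary <- function(assocA, assocB, map, genes,
                                grid = defaultCriteriaGrid(),
                                flank = 10000,
                                rule = c("minSize", "anyOverlap")) {
  rule <- match.arg(rule)
  rows <- list(); primary1 <- NULL; primaryGenes <- character()
  for (approach in 1:2) for (cr in grid) {
    if (approach == 1) {
      r <- convergeThenCluster(assocA, assocB, map, genes, cr, flank,
                               rule)
      gs <- r$geneHits$gene_id
      if (is.null(primary1)) { primary1 <- r; primaryGenes <- gs }
      rows[[length(rows) + 1L]] <- data.frame(
        approach = 1L, min_size = cr@minSize, max_gap = cr@maxGap,
        clustered_a = NA_integer_, clustered_b = NA_integer_,
        convergent_snps = r$nClusteredSnps, n_genes = length(gs),
        overlap_primary = length(intersect(gs, primaryGenes)))
    } else {
      r <- clusterThenConverge(assocA, assocB, map, genes, cr, flank,
                               rule)
      gs <- r$geneHits$gene_id
      rows[[length(rows) + 1L]] <- data.frame(
        approach = 2L, min_size = cr@minSize, max_gap = cr@maxGap,
        clustered_a = r$nClusteredA, clustered_b = r$nClusteredB,
        convergent_snps = r$nConvergentSnps, n_genes = length(gs),
        overlap_primary = length(intersect(gs, primaryGenes)))
    }
  }
  do.call(rbind, rows)
}

#' @rdname criteriaGridSummary
#' @param alpha nominal significance level for the grid's criteria.
#' @export
defaultCriteriaGrid <- function(alpha = 0.05) {
  list(convergenceCriteria(3, 25000, alpha),
       convergenceCriteria(3, 10000, alpha),
       convergenceCriteria(4, 25000, alpha),
       convergenceCriteria(4, 10000, alpha))
}
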