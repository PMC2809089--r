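#' Read and flank gene annotation
#'
#' \code{readGeneAnnotation} imports gene intervals from BED (0-based
#' half-open, converted to 1-based inclusive on read), GFF3 (1-based;
#' rows with \code{type == "gene"} are kept when present) or a
#' tab-delimited table with columns \code{gene_id}, \code{chrom},
#' \code{start}, \code{end}. \code{flankGenes} extends every interval
#' by \code{flank} bp on each side (default 10 kb --- the flanking
#' sequence considered part of a gene's territory), clipped at
#' position 1.
#'
#' @param file annotation file path.
#' @param format "auto" (by extension), "bed", "gff3" or "tsv".
#' @return \code{GRanges} named by gene id.
#' @export
readGeneAnnotation <- function(file, format = c("auto", "bed", "gff3",
                                                "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", file, ignore.case = TRUE)) "bed"
      else if (grepl("\\.gff3?$", file, ignore.case = TRUE)) "gff3"
      else "tsv"
  }
  if (format == "tsv") {
    df <- read.table(file, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "#")
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    names(gr) <- df$gene_id
    return(gr)
  }
  gr <- rtracklayer::import(file, format = format)
  if (format == "gff3" && "type" %in% colnames(mcols(gr)) &&
      any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$Name)) gr$Name
    else if (!is.null(gr$name)) gr$name
    else if (!is.null(gr$ID)) gr$ID
    else paste0("gene", seq_along(gr))
  names(gr) <- as.character(ids)
  mcols(gr) <- NULL
  gr
}

#' @param genes \code{GRanges} of gene intervals named by gene id.
#' @param flank flanking distance in bp added to each side (default
#'   10000).
#' @rdname readGeneAnnotation
#' @export
flankGenes <- function(genes, flank = 10000) {
  out <- genes
  start(out) <- pmax(start(genes) - flank, 1)
  end(out) <- end(genes) + flank
  out
}

#' @param file path for \code{writeGeneAnnotation} (tab-delimited).
#' @rdname readGeneAnnotation
#' @export
writeGeneAnnotation <- function(genes, file) {
  write.table(
    data.frame(gene_id = names(genes),
               chrom = as.character(seqnames(genes)),
               start = start(genes), end = end(genes)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Assign SNP clusters to genes
#'
#' A cluster supports a gene when at least \code{minSize(criteria)} of
#' its member SNPs lie within the gene's flanked interval (gene span
#' plus \code{flank} bp on each side, boundaries inclusive) --- the
#' strict reading; set \code{rule = "anyOverlap"} to accept any member
#' SNP inside the interval. One cluster may support several overlapping
#' genes, and a gene may be supported by several clusters.
#'
#' @param clusters cluster \code{GRanges} from
#'   \code{\link{findClusters}}.
#' @param genes gene annotation \code{GRanges} named by gene id
#'   (unflanked; flanks are applied here).
#' @param criteria \code{\link{ConvergenceCriteria}}; its
#'   \code{minSize} is the per-cluster support threshold.
#' @param flank flanking distance in bp (default 10000).
#' @param rule "minSize" (default) or "anyOverlap".
#' @return \code{DataFrame} of gene hits: \code{gene_id},
#'   \code{chromosome}, \code{start}, \code{end}, \code{n_clusters},
#'   \code{n_snps} (member SNPs of supporting clusters inside the
#'   flanked interval) and \code{snp_id} (CharacterList of those SNPs).
#' @export
assignClustersToGenes <- function(clusters, genes,
                                  criteria = convergenceCriteria(),
                                  flank = 10000,
                                  rule = c("minSize", "anyOverlap")) {
  rule <- match.arg(rule)
  stopifnot(is(clusters, "GRanges"), is(genes, "GRanges"))
  if (all(start(genes) > end(genes)))
    stop("invalid gene intervals")
  emptyHits <- DataFrame(gene_id = character(), chromosome = character(),
                         start = integer(), end = integer(),
                         n_clusters = integer(), n_snps = integer(),
                         snp_id = CharacterList())
  if (length(clusters) == 0L || length(genes) == 0L) return(emptyHits)
  fl <- flankGenes(genes, flank)
  memberId <- unlist(clusters$snp_id, use.names = FALSE)
  memberPos <- unlist(clusters$snp_pos, use.names = FALSE)
  memberCluster <- rep(seq_along(clusters), clusters$n_snps)
  members <- GRanges(rep(seqnames(clusters), clusters$n_snps),
                     IRanges(memberPos, width = 1))
  ov <- findOverlaps(members, fl)
  if (length(ov) == 0L) return(emptyHits)
  key <- data.frame(cluster = memberCluster[queryHits(ov)],
                    gene = subjectHits(ov),
                    snp = queryHits(ov))
  counts <- table(paste(key$cluster, key$gene))
  need <- if (rule == "minSize") criteria@minSize else 1L
  okPairs <- names(counts)[counts >= need]
  key <- key[paste(key$cluster, key$gene) %in% okPairs, , drop = FALSE]
  if (nrow(key) == 0L) return(emptyHits)
  geneIdx <- sort(unique(key$gene))
  hits <- lapply(geneIdx, function(g) {
    sub <- key[key$gene == g, , drop = FALSE]
    snps <- unique(memberId[sub$snp])
    list(n_clusters = length(unique(sub$cluster)),
         n_snps = length(snps), snp_id = snps)
  })
  DataFrame(
    gene_id = names(genes)[geneIdx],
    chromosome = as.character(seqnames(genes))[geneIdx],
    start = start(genes)[geneIdx], end = end(genes)[geneIdx],
    n_clusters = vapply(hits, `[[`, integer(1), "n_clusters"),
    n_snps = vapply(hits, `[[`, integer(1), "n_snps"),
    snp_id = CharacterList(lapply(hits, `[[`, "snp_id")))
}
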