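# End-to-end pipeline: associations -> positive sets -> both
# convergence analyses over the criteria grid -> empirical
# significance -> tables.

#' Pipeline configuration
#'
#' Collects every tunable of \code{\link{runPipeline}}: the nominal
#' level, the gene flank and support rule, the primary criteria of the
#' two approaches (approach 1: 3 SNPs within 25 kb; approach 2: 4 SNPs
#' within 10 kb --- chosen so the two approaches yield comparable
#' expected true-gene fractions), the criteria grid, trial counts per
#' empirical test, and the master seed from which every stochastic
#' stage derives a named substream. \code{writeConfig} /
#' \code{readConfig} serialize it losslessly as JSON.
#'
#' @param alpha nominal per-SNP level (default 0.05).
#' @param flank gene flanking distance in bp (default 10000).
#' @param rule gene-support rule ("minSize" or "anyOverlap").
#' @param primary1 c(minSize, maxGap) for approach 1.
#' @param primary2 c(minSize, maxGap) for approach 2.
#' @param gridSizes,gridGaps criteria grid axes.
#' @param overlapTrials,clusterTrials,geneConvergenceTrials,geneLevelTrials,permutationTrials
#'   trial counts for the empirical tests; set a count to 0 to skip
#'   that test.
#' @param seed master seed.
#' @return list of class \code{poolConvergeConfig}.
#' @export
pipelineConfig <- function(alpha = 0.05, flank = 10000,
                           rule = "minSize",
                           primary1 = c(3, 25000),
                           primary2 = c(4, 10000),
                           gridSizes = c(3, 4),
                           gridGaps = c(25000, 10000),
                           overlapTrials = 10000, clusterTrials = 500,
                           geneConvergenceTrials = 200,
                           geneLevelTrials = 1000,
                           permutationTrials = 0, seed = 1) {
  structure(list(
    alpha = alpha, flank = flank, rule = rule,
    primary1 = as.numeric(primary1), primary2 = as.numeric(primary2),
    gridSizes = as.numeric(gridSizes), gridGaps = as.numeric(gridGaps),
    overlapTrials = overlapTrials, clusterTrials = clusterTrials,
    geneConvergenceTrials = geneConvergenceTrials,
    geneLevelTrials = geneLevelTrials,
    permutationTrials = permutationTrials, seed = seed),
    class = "poolConvergeConfig")
}

#' @param config a \code{poolConvergeConfig}.
#' @param file JSON path.
#' @rdname pipelineConfig
#' @export
writeConfig <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE,
                       digits = NA)
}

#' @rdname pipelineConfig
#' @export
readConfig <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(pipelineConfig, raw)
}

.configHash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                           digits = NA)
  h <- 0
  for (c in utf8ToInt(as.character(json))) h <- (h * 131 + c) %% 1e9
  sprintf("%09d", h)
}

#' Run the full convergence pipeline
#'
#' From two samples' pooled panels to gene tables: per-sample QC and
#' associations, nominal positive sets, both convergence analyses over
#' the criteria grid, the primary analyses under the preplanned
#' criteria, Monte Carlo significance (set overlap, clustering extent,
#' cross-sample gene convergence, per-gene segment resampling),
#' optional phenotype permutation, and the expected true-gene
#' fraction. Fully reproducible from the config's master seed.
#'
#' @param panelA,panelB \code{\link{PoolPanel}}s of the two samples.
#' @param map SNP map \code{GRanges} (filtered with
#'   \code{\link{filterSnps}} internally).
#' @param genes gene annotation \code{GRanges}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional directory for TSV outputs.
#' @return list: \code{assoc} (per sample), \code{qc}, \code{summary}
#'   (criteria grid), \code{approach1}, \code{approach2} (primary
#'   results; approach-1 gene hits carry a Monte Carlo \code{p}
#'   column), \code{significance} (named \code{\link{EmpiricalP}}
#'   list), \code{trueGeneFraction}, \code{config}.
#' @export
runPipeline <- function(panelA, panelB, map, genes,
                        config = pipelineConfig(), outDir = NULL) {
  map <- filterSnps(map)
  common <- intersect(intersect(rownames(panelA), rownames(panelB)),
                      names(map))
  if (length(common) == 0L)
    stop("panels and map share no SNPs: inconsistent inputs")
  panelA <- panelA[common, ]; panelB <- panelB[common, ]
  map <- map[common]
  seed <- config$seed
  cr1 <- convergenceCriteria(config$primary1[1], config$primary1[2],
                             config$alpha)
  cr2 <- convergenceCriteria(config$primary2[1], config$primary2[2],
                             config$alpha)
  grid <- unlist(lapply(config$gridSizes, function(s)
    lapply(config$gridGaps, function(g)
      convergenceCriteria(s, g, config$alpha))))

  qc <- list(A = qcReport(panelA), B = qcReport(panelB))
  assocA <- snpTTest(panelA); assocB <- snpTTest(panelB)
  posA <- nominalPositives(assocA, config$alpha)
  posB <- nominalPositives(assocB, config$alpha)
  pcInfo("nominal positives: ", length(posA), " (A), ", length(posB),
         " (B) of ", length(common), " SNPs")

  summary <- criteriaGridSummary(assocA, assocB, map, genes, grid,
                                 config$flank, config$rule)
  a1 <- convergeThenCluster(assocA, assocB, map, genes, cr1,
                            config$flank, config$rule)
  a2 <- clusterThenConverge(assocA, assocB, map, genes, cr2,
                            config$flank, config$rule)
  pcInfo("reproducible SNPs: ", length(a1$reproducibleSnps),
         "; clustered: ", a1$nClusteredSnps, " in ",
         length(a1$clusters), " clusters; approach-1 genes: ",
         nrow(a1$geneHits), "; approach-2 genes: ", nrow(a2$geneHits))

  sig <- list()
  if (config$overlapTrials > 0)
    sig$overlap <- mcOverlapP(length(common), length(posA),
                              length(posB),
                              length(a1$reproducibleSnps),
                              config$overlapTrials,
                              deriveSeed(seed, "mc.overlap"))
  if (config$clusterTrials > 0)
    sig$clustering <- mcClusterP(map, length(a1$reproducibleSnps), cr1,
                                 a1$nClusteredSnps,
                                 config$clusterTrials,
                                 deriveSeed(seed, "mc.cluster"))
  if (config$geneConvergenceTrials > 0)
    sig$geneConvergence <- mcGeneConvergenceP(
      map, genes, length(posA), length(posB), cr2, nrow(a2$geneHits),
      config$geneConvergenceTrials, deriveSeed(seed, "mc.converge"),
      config$flank, config$rule)
  if (config$permutationTrials > 0)
    sig$permutation <- permutationP(panelA, panelB, config$alpha,
                                    config$permutationTrials,
                                    deriveSeed(seed, "permute"))

  if (config$geneLevelTrials > 0 && nrow(a1$geneHits) > 0) {
    a1$geneHits$p <- vapply(seq_len(nrow(a1$geneHits)), function(i)
      pValue(mcGeneLevelP(a1$geneHits$gene_id[i], genes, map, posA,
                          posB, cr1, approach = 1,
                          nTrials = config$geneLevelTrials,
                          seed = deriveSeed(seed, paste0("mc.gene.", i)),
                          flank = config$flank)), numeric(1))
  }
  tgf <- if (!is.null(sig$geneConvergence) && nrow(a2$geneHits) > 0)
    truePositiveFraction(nrow(a2$geneHits), sig$geneConvergence)
  else NA_real_

  result <- list(assoc = list(A = assocA, B = assocB), qc = qc,
                 summary = summary, approach1 = a1, approach2 = a2,
                 significance = sig, trueGeneFraction = tgf,
                 config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(paste0("# config ", .configHash(config)),
             paste0("# seed ", seed))
    writeSummaryTable(summary, file.path(outDir, "summary.tsv"), hdr)
    writeGeneTable(a1$geneHits, file.path(outDir, "genes_approach1.tsv"),
                   c(hdr, sprintf("# criteria %d/%d", cr1@minSize,
                                  cr1@maxGap)))
    writeGeneTable(a2$geneHits, file.path(outDir, "genes_approach2.tsv"),
                   c(hdr, sprintf("# criteria %d/%d", cr2@minSize,
                                  cr2@maxGap)))
    if (length(sig))
      writeSignificanceReport(sig, file.path(outDir, "significance.tsv"),
                              hdr)
    writeQcReport(qc$A, file.path(outDir, "qc_A.tsv"), hdr)
    writeQcReport(qc$B, file.path(outDir, "qc_B.tsv"), hdr)
    writeConfig(config, file.path(outDir, "config.json"))
  }
  result
}
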