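# Readers and writers for panels, designs and result tables. All
# tables are tab-delimited; writers prepend "# " comment lines
# recording the package version and seeds so every number is traceable.

.headerLines <- function(extra = character()) {
  c(paste0("# poolConverge ",
           as.character(utils::packageVersion("poolConverge"))), extra)
}

.writeTsv <- function(df, file, extra = character()) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(.headerLines(extra), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read and write pooled intensity panels
#'
#' The on-disk form is a long tab-delimited table with columns
#' \code{pool_id}, \code{replicate}, \code{snp_id} and either
#' \code{arctan_ab} (radians) or raw \code{a_intensity} /
#' \code{b_intensity} (converted with \code{\link{arctanAB}} on read),
#' plus a pool design table (\code{pool_id}, \code{sample_label},
#' \code{phenotype}, \code{n_individuals}). Write-then-read
#' round-trips the in-memory \code{\link{PoolPanel}}.
#'
#' @param panelFile long-format measurement table path.
#' @param designFile pool design table path.
#' @param map \code{GRanges} SNP map naming every SNP in the panel.
#' @return \code{readPanel} returns a \code{\link{PoolPanel}}.
#' @export
readPanel <- function(panelFile, designFile, map) {
  long <- read.table(panelFile, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "#")
  design <- read.table(designFile, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, comment.char = "#")
  need <- c("pool_id", "replicate", "snp_id")
  if (!all(need %in% colnames(long)))
    stop("panel file lacks columns: ",
         paste(setdiff(need, colnames(long)), collapse = ", "))
  if (!"arctan_ab" %in% colnames(long)) {
    if (!all(c("a_intensity", "b_intensity") %in% colnames(long)))
      stop("panel file needs arctan_ab or a_intensity/b_intensity")
    long$arctan_ab <- arctanAB(long$a_intensity, long$b_intensity)
  }
  snps <- unique(long$snp_id)
  if (!all(snps %in% names(map)))
    stop("panel contains SNPs absent from the map")
  arrays <- unique(long[, c("pool_id", "replicate")])
  arrays <- arrays[order(match(arrays$pool_id, design$pool_id),
                         arrays$replicate), ]
  key <- paste(long$pool_id, long$replicate)
  arrKey <- paste(arrays$pool_id, arrays$replicate)
  mat <- matrix(NA_real_, length(snps), nrow(arrays),
                dimnames = list(snps, arrKey))
  mat[cbind(match(long$snp_id, snps), match(key, arrKey))] <-
    long$arctan_ab
  di <- match(arrays$pool_id, design$pool_id)
  PoolPanel(mat, map[snps], poolId = arrays$pool_id,
            replicate = arrays$replicate,
            phenotype = design$phenotype[di],
            sampleLabel = design$sample_label[di],
            nIndividuals = design$n_individuals[di])
}

#' @param panel a \code{\link{PoolPanel}} to write.
#' @rdname readPanel
#' @export
writePanel <- function(panel, panelFile, designFile) {
  a <- assay(panel, "arctan")
  cd <- colData(panel)
  long <- data.frame(
    pool_id = rep(cd$pool_id, each = nrow(a)),
    replicate = rep(cd$replicate, each = nrow(a)),
    snp_id = rep(rownames(a), ncol(a)),
    arctan_ab = as.vector(a))
  write.table(long, panelFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(poolDesign(panel))[
    , c("pool_id", "sample_label", "phenotype", "n_individuals")],
    designFile, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write result tables
#'
#' \code{writeGeneTable} writes a per-gene hit table (either
#' approach); \code{writeSummaryTable} writes the criteria-grid
#' summary; \code{writeSignificanceReport} writes one row per
#' empirical test (statistic name, observed, trials, exceedances, p,
#' seed); \code{writeQcReport} writes per-pool and per-group SEMs.
#'
#' @param hits gene-hit \code{DataFrame} from a convergence analysis.
#' @param file output path.
#' @param extra extra "# " header lines (e.g. criteria used).
#' @export
writeGeneTable <- function(hits, file, extra = character()) {
  df <- as.data.frame(hits[, !vapply(hits, is, logical(1), "List"),
                           drop = FALSE])
  for (col in colnames(hits)[vapply(hits, is, logical(1), "List")])
    df[[col]] <- vapply(hits[[col]], paste, character(1),
                        collapse = ",")
  .writeTsv(df, file, extra)
}

#' @param summary data.frame from \code{\link{criteriaGridSummary}}.
#' @rdname writeGeneTable
#' @export
writeSummaryTable <- function(summary, file, extra = character()) {
  .writeTsv(summary, file, extra)
}

#' @param tests named list of \code{\link{EmpiricalP}} objects.
#' @rdname writeGeneTable
#' @export
writeSignificanceReport <- function(tests, file, extra = character()) {
  df <- do.call(rbind, lapply(names(tests), function(nm) {
    e <- tests[[nm]]
    data.frame(statistic = nm, observed = e@observed,
               trials = e@nTrials, exceedances = e@nExceed, p = e@p,
               exact = e@exact, seed = e@seed,
               null_mean = e@nullMean, null_sd = e@nullSd)
  }))
  .writeTsv(df, file, extra)
}

#' @param qc a \code{\link{QcReport}}.
#' @rdname writeGeneTable
#' @export
writeQcReport <- function(qc, file, extra = character()) {
  df <- rbind(
    data.frame(kind = "pool_replicate_sem", unit = names(qc@poolSEM),
               value = unname(qc@poolSEM)),
    data.frame(kind = "group_pool_sem", unit = names(qc@groupSEM),
               value = unname(qc@groupSEM)),
    if (length(qc@flaggedArrays))
      data.frame(kind = "flagged_array", unit = qc@flaggedArrays,
                 value = NA_real_))
  .writeTsv(df, file, extra)
}
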