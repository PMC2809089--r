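#' Quality-control variance report for a pooled panel
#'
#' Summarizes the two variance components the pooled design monitors:
#' the replicate-to-replicate SEM within each pool (per-SNP variance
#' across a pool's replicate arrays, root-mean-squared over SNPs, per
#' sqrt(replicates)) and the pool-to-pool SEM within each
#' sample:phenotype group (per-SNP variance across the group's pool
#' means, root-mean-squared over SNPs, per sqrt(pools)). Also reports,
#' per array, the mean of its highest and lowest 5 percent of values,
#' and flags arrays whose mean signal deviates from the median of
#' their pool's replicates by more than \code{flagMultiple} pooled
#' replicate SDs (a whole-array artifact, not per-SNP noise).
#'
#' @param panel a \code{\link{PoolPanel}} (>= 2 replicates per pool for
#'   the replicate SEM; single-replicate pools get NA and a warning
#'   message).
#' @param flagMultiple array-flagging threshold in units of the pooled
#'   replicate SD (default 1).
#' @return A \code{\link{QcReport}}.
#' @export
qcReport <- function(panel, flagMultiple = 1) {
  a <- assay(panel, "arctan")
  cd <- colData(panel)
  pools <- unique(cd$pool_id)
  repVar <- vapply(pools, function(p) {
    cols <- which(cd$pool_id == p)
    if (length(cols) < 2L) return(NA_real_)
    mean(rowVarsFast(a[, cols, drop = FALSE]))
  }, numeric(1))
  nRep <- vapply(pools, function(p) sum(cd$pool_id == p), integer(1))
  if (anyNA(repVar))
    pcWarn("replicate SEM undefined for single-replicate pool(s): ",
           paste(pools[is.na(repVar)], collapse = ", "))
  poolSEM <- sqrt(repVar) / sqrt(nRep)
  names(poolSEM) <- pools

  pm <- poolMeans(panel)
  d <- poolDesign(panel)
  grp <- paste(d$sample_label, d$phenotype, sep = ":")
  groupSEM <- vapply(unique(grp), function(g) {
    cols <- d$pool_id[grp == g]
    if (length(cols) < 2L) return(NA_real_)
    sqrt(mean(rowVarsFast(pm[, cols, drop = FALSE]))) /
      sqrt(length(cols))
  }, numeric(1))

  arraySummary <- data.frame(
    array = colnames(a),
    bottom5_mean = apply(a, 2, function(z)
      mean(z[z <= quantile(z, 0.05, na.rm = TRUE)], na.rm = TRUE)),
    top5_mean = apply(a, 2, function(z)
      mean(z[z >= quantile(z, 0.95, na.rm = TRUE)], na.rm = TRUE)),
    mean = colMeans(a, na.rm = TRUE))

  pooledSd <- sqrt(mean(repVar, na.rm = TRUE))
  arrayMean <- colMeans(a, na.rm = TRUE)
  offset <- vapply(seq_len(ncol(a)), function(j) {
    sib <- arrayMean[cd$pool_id == cd$pool_id[j]]
    arrayMean[j] - median(sib)
  }, numeric(1))
  flagged <- colnames(a)[!is.na(pooledSd) & pooledSd > 0 &
                           abs(offset) > flagMultiple * pooledSd]
  if (length(flagged))
    pcWarn("aberrant array signal: ", paste(flagged, collapse = ", "))
  new("QcReport", poolSEM = poolSEM, groupSEM = groupSEM,
      arraySummary = arraySummary, flaggedArrays = flagged)
}
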