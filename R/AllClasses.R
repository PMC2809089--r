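#' Clustering and convergence criteria
#'
#' Bundles the three thresholds that define a qualifying cluster of
#' nominally positive SNPs: the minimum number of member SNPs, the
#' maximum base-pair gap between consecutive members, and the nominal
#' per-SNP significance level. The canonical grid crosses cluster sizes
#' \{3, 4\} with gaps \{25 kb, 10 kb\}.
#'
#' @slot minSize integer, minimum SNPs per cluster (>= 2).
#' @slot maxGap integer, maximum gap in bp between consecutive members.
#' @slot alpha numeric in (0, 1), nominal per-SNP significance level.
#'
#' @aliases ConvergenceCriteria
#' @exportClass ConvergenceCriteria
setClass("ConvergenceCriteria",
  representation(minSize = "integer", maxGap = "integer", alpha = "numeric"),
  prototype(minSize = 3L, maxGap = 25000L, alpha = 0.05))

setValidity("ConvergenceCriteria", function(object) {
  msg <- character()
  if (length(object@minSize) != 1L || is.na(object@minSize) ||
      object@minSize < 2L)
    msg <- c(msg, "minSize must be a single integer >= 2")
  if (length(object@maxGap) != 1L || is.na(object@maxGap) ||
      object@maxGap <= 0L)
    msg <- c(msg, "maxGap must be a single positive integer")
  if (length(object@alpha) != 1L || is.na(object@alpha) ||
      object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param minSize minimum number of SNPs per cluster (default 3).
#' @param maxGap maximum gap between consecutive cluster members in bp
#'   (default 25000).
#' @param alpha nominal per-SNP significance level (default 0.05).
#' @return A \code{ConvergenceCriteria} object.
#' @examples
#' convergenceCriteria(4, 10000)
#' @rdname ConvergenceCriteria-class
#' @export
convergenceCriteria <- function(minSize = 3, maxGap = 25000, alpha = 0.05) {
  new("ConvergenceCriteria", minSize = as.integer(minSize),
      maxGap = as.integer(maxGap), alpha = as.numeric(alpha))
}

setMethod("show", "ConvergenceCriteria", function(object) {
  cat(sprintf(
    "ConvergenceCriteria: >=%d SNPs, consecutive gap <=%d bp, alpha=%g\n",
    object@minSize, object@maxGap, object@alpha))
})

#' Panel of pooled-array allele-frequency proxies
#'
#' A \code{SummarizedExperiment} holding one arctan(A/B) hybridization
#' measure per (SNP, array), where each array is one replicate
#' hybridization of one DNA pool. Rows are SNPs (with genomic
#' coordinates in \code{rowRanges}); columns are arrays, annotated in
#' \code{colData} with \code{pool_id}, \code{replicate},
#' \code{sample_label}, \code{phenotype} ("case"/"control") and
#' \code{n_individuals}. All stored values lie in [0, pi/2] (or NA).
#'
#' @aliases PoolPanel
#' @exportClass PoolPanel
setClass("PoolPanel", contains = "RangedSummarizedExperiment")

.POOL_COLS <- c("pool_id", "replicate", "sample_label", "phenotype",
                "n_individuals")

setValidity("PoolPanel", function(object) {
  msg <- character()
  if (!"arctan" %in% assayNames(object))
    msg <- c(msg, "assay 'arctan' is required")
  miss <- setdiff(.POOL_COLS, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if ("arctan" %in% assayNames(object)) {
    a <- assay(object, "arctan")
    if (any(a < 0 | a > pi / 2 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "arctan values must lie in [0, pi/2]")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "rows must carry unique SNP identifiers")
  if (!length(msg) && "phenotype" %in% colnames(colData(object))) {
    ph <- unique(as.character(object$phenotype))
    if (!all(ph %in% c("case", "control")))
      msg <- c(msg, "phenotype must be 'case' or 'control'")
  }
  if (length(msg)) msg else TRUE
})

#' @param arctan numeric matrix, SNPs x arrays, of arctan(A/B) values in
#'   radians; rownames are SNP identifiers.
#' @param map \code{GRanges} of SNP positions named by SNP identifier
#'   (one per row of \code{arctan}).
#' @param poolId character, pool of each array (column).
#' @param replicate integer, replicate index of each array within its pool.
#' @param phenotype character, "case" or "control" per array.
#' @param sampleLabel character, independent-sample label per array
#'   (e.g. the two population samples); scalar recycled.
#' @param nIndividuals integer, individuals pooled per array's pool
#'   (default 20); scalar recycled.
#' @return A \code{PoolPanel}.
#' @rdname PoolPanel-class
#' @export
PoolPanel <- function(arctan, map, poolId, replicate, phenotype,
                      sampleLabel = "S1", nIndividuals = 20L) {
  arctan <- as.matrix(arctan)
  nArr <- ncol(arctan)
  if (is.null(rownames(arctan))) rownames(arctan) <- names(map)
  map <- map[rownames(arctan)]
  cd <- DataFrame(
    pool_id = as.character(rep_len(poolId, nArr)),
    replicate = as.integer(rep_len(replicate, nArr)),
    sample_label = as.character(rep_len(sampleLabel, nArr)),
    phenotype = as.character(rep_len(phenotype, nArr)),
    n_individuals = as.integer(rep_len(nIndividuals, nArr)))
  colnames(arctan) <- paste(cd$pool_id, cd$replicate, sep = ".")
  rownames(cd) <- colnames(arctan)
  se <- SummarizedExperiment(assays = list(arctan = arctan),
                             rowRanges = map, colData = cd)
  new("PoolPanel", se)
}

setMethod("show", "PoolPanel", function(object) {
  d <- poolDesign(object)
  cat(sprintf(
    "PoolPanel: %d SNPs, %d arrays (%d pools; %s)\n",
    nrow(object), ncol(object), nrow(d),
    paste(sprintf("%s:%d case/%d control", unique(d$sample_label),
                  sapply(unique(d$sample_label), function(s)
                    sum(d$phenotype == "case" & d$sample_label == s)),
                  sapply(unique(d$sample_label), function(s)
                    sum(d$phenotype == "control" & d$sample_label == s))),
          collapse = ", ")))
})

#' Empirical (Monte Carlo / permutation) p-value
#'
#' The result of comparing an observed statistic against resampled null
#' trials. With sampled trials, p = (exceedances + 1) / (trials + 1),
#' where an exceedance is a trial whose statistic matched or exceeded
#' the observation; with exhaustive enumeration (\code{exact = TRUE}),
#' p = exceedances / trials over all distinct relabelings.
#'
#' @slot observed numeric, the observed statistic.
#' @slot nTrials numeric, number of null trials (or enumerated states).
#' @slot nExceed numeric, trials with null statistic >= observed.
#' @slot p numeric in (0, 1], the empirical p-value.
#' @slot seed integer seed used for the trials (NA if none).
#' @slot exact logical, TRUE when the null was enumerated exhaustively.
#' @slot nullMean,nullSd numeric, moments of the null trial statistics.
#' @slot nullQuantiles named numeric, quantiles of the null statistics.
#'
#' @aliases EmpiricalP
#' @exportClass EmpiricalP
setClass("EmpiricalP",
  representation(observed = "numeric", nTrials = "numeric",
                 nExceed = "numeric", p = "numeric", seed = "integer",
                 exact = "logical", nullMean = "numeric",
                 nullSd = "numeric", nullQuantiles = "numeric"))

setValidity("EmpiricalP", function(object) {
  msg <- character()
  if (object@nTrials < 1) msg <- c(msg, "nTrials must be >= 1")
  if (object@nExceed < 0 || object@nExceed > object@nTrials)
    msg <- c(msg, "nExceed must lie in [0, nTrials]")
  expect <- if (object@exact) object@nExceed / object@nTrials
            else (object@nExceed + 1) / (object@nTrials + 1)
  if (abs(object@p - expect) > 1e-12)
    msg <- c(msg, "p inconsistent with exceedance convention")
  if (object@p > 1) msg <- c(msg, "p must be <= 1")
  if (length(msg)) msg else TRUE
})

# Build an EmpiricalP from a vector of null trial statistics.
empiricalPFromTrials <- function(observed, trials, seed = NULL,
                                 exact = FALSE) {
  n <- length(trials)
  x <- sum(trials >= observed)
  p <- if (exact) x / n else (x + 1) / (n + 1)
  new("EmpiricalP", observed = as.numeric(observed), nTrials = as.numeric(n),
      nExceed = as.numeric(x), p = p,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      exact = exact, nullMean = mean(trials), nullSd = sd(trials),
      nullQuantiles = quantile(trials, c(0, .25, .5, .75, .95, .99, 1)))
}

setMethod("show", "EmpiricalP", function(object) {
  cat(sprintf(
    "EmpiricalP: observed %g; %s trials %g; exceedances %g; p = %.3g\n",
    object@observed, if (object@exact) "enumerated" else "sampled",
    object@nTrials, object@nExceed, object@p))
  cat(sprintf("  null mean %.4g, sd %.4g\n", object@nullMean,
              object@nullSd))
})

#' Planted ground truth of a synthetic study
#'
#' Records which SNPs carry planted case-control allele-frequency
#' effects, the LD-like blocks (runs of nearby SNPs that shift
#' together) they form, the genes that host them, and which SNPs tag
#' the effect in each population sample.
#'
#' @slot loci data.frame, one row per planted block: locus, gene_id,
#'   chromosome, start, end, n_snps.
#' @slot effectSnps character, all SNP ids carrying an effect.
#' @slot tagged named list of character vectors: SNP ids tagging the
#'   effect in each population.
#' @slot effectSize numeric, case-minus-control allele-frequency shift.
#' @slot seed integer seed used to plant the effects.
#'
#' @aliases SyntheticTruth
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(loci = "data.frame", effectSnps = "character",
                 tagged = "list", effectSize = "numeric", seed = "integer"))

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d loci, %d effect SNPs, effect %.3g (seed %d)\n",
    nrow(object@loci), length(object@effectSnps), object@effectSize,
    object@seed))
})

#' Quality-control summary of a pooled panel
#'
#' Per-pool replicate standard errors, across-pool standard errors per
#' phenotype group, per-array intensity-extreme summaries, and arrays
#' flagged for aberrant mean signal. SEMs use the root-mean-square of
#' per-SNP variances (unbiased for the underlying sigma/sqrt(n)).
#'
#' @slot poolSEM named numeric, per-pool replicate SEM averaged over SNPs.
#' @slot groupSEM named numeric, across-pool SEM per sample:phenotype group.
#' @slot arraySummary data.frame, per-array mean of the top and bottom
#'   5 percent of values plus overall mean.
#' @slot flaggedArrays character, arrays whose mean signal deviates
#'   aberrantly from their pool's other replicates.
#'
#' @aliases QcReport
#' @exportClass QcReport
setClass("QcReport",
  representation(poolSEM = "numeric", groupSEM = "numeric",
                 arraySummary = "data.frame", flaggedArrays = "character"))

setMethod("show", "QcReport", function(object) {
  cat(sprintf(
    "QcReport: mean replicate SEM %.4f; mean across-pool SEM %.4f\n",
    mean(object@poolSEM, na.rm = TRUE), mean(object@groupSEM)))
  if (length(object@flaggedArrays))
    cat("  flagged arrays:", paste(object@flaggedArrays, collapse = ", "),
        "\n")
  else cat("  no arrays flagged\n")
})
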