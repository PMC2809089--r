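#' Accessors for poolConverge classes
#'
#' \code{poolDesign} returns one row per pool (pool id, sample label,
#' phenotype, individuals, replicate count); \code{poolMeans} collapses
#' replicate arrays to one mean arctan value per (SNP, pool) --- the
#' experimental unit of every downstream test. \code{pValue},
#' \code{observedStat}, \code{nullTrials}, \code{nullExceed},
#' \code{nullMean} and \code{nullSd} read the corresponding components
#' of an \code{\link{EmpiricalP}}. \code{replicateSEM} and
#' \code{groupSEM} read the SEM components of a \code{\link{QcReport}};
#' \code{flaggedArrays} lists aberrant arrays. \code{effectSnps} lists
#' the planted SNPs of a \code{\link{SyntheticTruth}}.
#'
#' @param x a poolConverge object.
#' @return See each accessor's description.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("poolDesign", function(x) standardGeneric("poolDesign"))

#' @rdname accessors
#' @export
setGeneric("poolMeans", function(x) standardGeneric("poolMeans"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))

#' @rdname accessors
#' @export
setGeneric("nullTrials", function(x) standardGeneric("nullTrials"))

#' @rdname accessors
#' @export
setGeneric("nullExceed", function(x) standardGeneric("nullExceed"))

#' @rdname accessors
#' @export
setGeneric("nullMean", function(x) standardGeneric("nullMean"))

#' @rdname accessors
#' @export
setGeneric("nullSd", function(x) standardGeneric("nullSd"))

#' @rdname accessors
#' @export
setGeneric("replicateSEM", function(x) standardGeneric("replicateSEM"))

#' @rdname accessors
#' @export
setGeneric("groupSEM", function(x) standardGeneric("groupSEM"))

#' @rdname accessors
#' @export
setGeneric("flaggedArrays", function(x) standardGeneric("flaggedArrays"))

#' @rdname accessors
#' @export
setGeneric("effectSnps", function(x) standardGeneric("effectSnps"))

#' @rdname accessors
setMethod("pValue", "EmpiricalP", function(x) x@p)

#' @rdname accessors
setMethod("observedStat", "EmpiricalP", function(x) x@observed)

#' @rdname accessors
setMethod("nullTrials", "EmpiricalP", function(x) x@nTrials)

#' @rdname accessors
setMethod("nullExceed", "EmpiricalP", function(x) x@nExceed)

#' @rdname accessors
setMethod("nullMean", "EmpiricalP", function(x) x@nullMean)

#' @rdname accessors
setMethod("nullSd", "EmpiricalP", function(x) x@nullSd)

#' @rdname accessors
setMethod("replicateSEM", "QcReport", function(x) x@poolSEM)

#' @rdname accessors
setMethod("groupSEM", "QcReport", function(x) x@groupSEM)

#' @rdname accessors
setMethod("flaggedArrays", "QcReport", function(x) x@flaggedArrays)

#' @rdname accessors
setMethod("effectSnps", "SyntheticTruth", function(x) x@effectSnps)

#' @rdname accessors
setMethod("poolDesign", "PoolPanel", function(x) {
  cd <- colData(x)
  first <- !duplicated(cd$pool_id)
  d <- cd[first, c("pool_id", "sample_label", "phenotype",
                   "n_individuals"), drop = FALSE]
  d$n_replicates <- as.integer(table(cd$pool_id)[d$pool_id])
  rownames(d) <- d$pool_id
  d
})

#' @rdname accessors
setMethod("poolMeans", "PoolPanel", function(x) {
  a <- assay(x, "arctan")
  pools <- unique(colData(x)$pool_id)
  out <- vapply(pools, function(p) {
    rowMeans(a[, colData(x)$pool_id == p, drop = FALSE])
  }, numeric(nrow(a)))
  out <- matrix(out, nrow = nrow(a),
                dimnames = list(rownames(x), pools))
  out
})
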