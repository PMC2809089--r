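#' Arctangent allele-frequency proxy
#'
#' \code{arctanAB} converts A- and B-allele hybridization intensities to
#' the bounded allele-frequency proxy arctan(A/B) in radians: 0 when the
#' pool carries only B alleles, pi/4 at equal intensities, pi/2 when it
#' carries only A alleles. The measure is monotone in the A/B ratio and
#' bounded in [0, pi/2], so a handful of aberrant probes cannot produce
#' unbounded frequency estimates.
#'
#' \code{summarizeSnpArray} applies the measure to one SNP on one array:
#' the 3-4 perfect-match probe intensities per allele are averaged
#' first, and the arctangent is taken of the ratio of those means
#' (mean-then-arctan, not arctan-then-mean).
#'
#' @param a,b nonnegative A- and B-allele intensities (vectorized).
#' @return Radians in [0, pi/2].
#' @examples
#' arctanAB(1, 1)            # pi/4
#' summarizeSnpArray(c(1, 3), c(1, 1))  # arctan(2)
#' @export
arctanAB <- function(a, b) {
  if (any(a < 0 | b < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  if (any(a == 0 & b == 0, na.rm = TRUE))
    stop("undefined measure: both allele intensities are zero")
  atan2(a, b)
}

#' @param probeA,probeB numeric vectors of perfect-match probe
#'   intensities for the A and B allele of one SNP on one array (1-4
#'   probes each).
#' @rdname arctanAB
#' @export
summarizeSnpArray <- function(probeA, probeB) {
  if (length(probeA) < 1L || length(probeB) < 1L)
    stop("at least one probe intensity per allele is required")
  arctanAB(mean(probeA), mean(probeB))
}
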