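# Pool-level case vs control tests on arctan allele-frequency proxies.

# Vectorized Welch two-sample t across rows; x = case matrix, y =
# control matrix (rows = SNPs, columns = pools). Returns per-row t,
# Welch-Satterthwaite df, two-sided p, group means and a degeneracy
# flag for rows with zero variance in both groups.
rowWelch <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop("at least 2 pools per group are required")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowVarsFast(x); v2 <- rowVarsFast(y)
  # variances below the double-rounding floor are treated as zero
  v1[v1 < 1e-14] <- 0; v2[v2 < 1e-14] <- 0
  se2 <- v1 / n1 + v2 / n2
  degenerate <- se2 == 0
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  if (any(degenerate)) {
    eq <- degenerate & (m1 == m2)
    t[eq] <- 0; p[eq] <- 1; df[eq] <- n1 + n2 - 2
    ne <- degenerate & (m1 != m2)
    t[ne] <- sign(m1[ne] - m2[ne]) * Inf
    p[ne] <- .Machine$double.xmin
    df[ne] <- n1 + n2 - 2
  }
  list(t = t, df = df, p = p, meanCase = m1, meanControl = m2,
       degenerate = degenerate)
}

#' Per-SNP case vs control t tests on pool means
#'
#' For every SNP, the three (or more) replicate arrays of each pool are
#' first averaged to one arctan(A/B) value per pool, and a two-sided
#' Welch t test then compares case pools against control pools --- the
#' pool, not the array or the individual, is the experimental unit.
#' The case/control mean ratio is reported as a descriptive column
#' only; significance rests on the t statistic. SNPs with zero
#' variance in both groups are flagged \code{degenerate} (t = 0, p = 1
#' when the means agree). SNPs with missing values in any pool are
#' dropped with a message.
#'
#' @param panel a \code{\link{PoolPanel}} containing one sample's case
#'   and control pools.
#' @return A \code{DataFrame} with one row per SNP: \code{snp_id},
#'   \code{t}, \code{df}, \code{p}, \code{direction} (sign of case
#'   minus control mean), \code{ratio} (case/control mean arctan),
#'   \code{n_case_pools}, \code{n_control_pools}, \code{degenerate}.
#' @seealso \code{\link{nominalPositives}}, \code{\link{qqData}}
#' @export
snpTTest <- function(panel) {
  stopifnot(is(panel, "PoolPanel"))
  pm <- poolMeans(panel)
  d <- poolDesign(panel)
  if (length(unique(d$sample_label)) > 1L)
    stop("panel mixes sample labels; test one sample at a time")
  caseIdx <- d$pool_id[d$phenotype == "case"]
  ctrlIdx <- d$pool_id[d$phenotype == "control"]
  complete <- rowSums(is.na(pm)) == 0L
  if (!all(complete))
    pcInfo(sum(!complete), " SNP(s) dropped for missing pool values")
  pm <- pm[complete, , drop = FALSE]
  w <- rowWelch(pm[, caseIdx, drop = FALSE], pm[, ctrlIdx, drop = FALSE])
  DataFrame(snp_id = rownames(pm), t = unname(w$t), df = unname(w$df),
            p = unname(w$p),
            direction = unname(sign(w$meanCase - w$meanControl)),
            ratio = unname(w$meanCase / w$meanControl),
            n_case_pools = length(caseIdx),
            n_control_pools = length(ctrlIdx),
            degenerate = unname(w$degenerate))
}

#' Nominally positive SNP set
#'
#' SNPs whose per-SNP test gives p strictly below \code{alpha} (default
#' 0.05), with no multiple-testing correction --- the raw material of
#' both convergence analyses.
#'
#' @param assoc association table from \code{\link{snpTTest}}.
#' @param alpha nominal significance level; strict inequality, so ties
#'   at exactly \code{alpha} are excluded.
#' @return Character vector of SNP ids.
#' @export
nominalPositives <- function(assoc, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  as.character(assoc$snp_id[assoc$p < alpha])
}

#' Observed vs expected t quantiles (QQ report data)
#'
#' Pairs the sorted observed t statistics against quantiles of a null t
#' distribution simulated with the same case/control pool counts
#' (standard-normal pool values), the plot-ready form of a QQ
#' comparison. Constant observed input is flagged with attribute
#' \code{degenerate}.
#'
#' @param assoc association table from \code{\link{snpTTest}}.
#' @param nNullDraws number of simulated null t statistics (default
#'   10000).
#' @param seed RNG seed for the null simulation.
#' @return data.frame with columns \code{expected} and \code{observed},
#'   one row per SNP.
#' @export
qqData <- function(assoc, nNullDraws = 10000, seed = NULL) {
  if (nrow(assoc) < 2L) stop("at least 2 associations are required")
  n1 <- assoc$n_case_pools[1]; n2 <- assoc$n_control_pools[1]
  nullT <- withSeed(seed, {
    x <- matrix(rnorm(nNullDraws * n1), nNullDraws)
    y <- matrix(rnorm(nNullDraws * n2), nNullDraws)
    rowWelch(x, y)$t
  })
  obs <- sort(assoc$t)
  out <- data.frame(
    expected = quantile(nullT, ppoints(length(obs)), names = FALSE),
    observed = obs)
  attr(out, "degenerate") <- length(unique(obs)) == 1L
  out
}
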