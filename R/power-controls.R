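# Supporting analyses: t-test power, stratification and noise controls.

#' Power of the two-sided two-sample t test
#'
#' Noncentral-t power for detecting a mean difference \code{delta} (on
#' the arctan measurement scale, where allele-frequency differences
#' translate approximately linearly) between groups of \code{n1} and
#' \code{n2} pools with common standard deviation \code{sd}, at
#' two-sided level \code{alpha}. Degrees of freedom follow the
#' Welch-Satterthwaite formula evaluated at equal group variances, so
#' the prediction matches the Welch test the pipeline actually runs
#' (for balanced groups this coincides with the classical pooled-df
#' calculation). At \code{delta = 0} the power equals \code{alpha};
#' power is increasing in \code{delta}, \code{n1} and \code{n2} and
#' decreasing in \code{sd}.
#'
#' @param delta true mean difference (vectorized).
#' @param sd common per-pool standard deviation (> 0).
#' @param n1,n2 pools per group (>= 2).
#' @param alpha two-sided test level (default 0.05).
#' @return Power in (0, 1), vectorized over \code{delta}.
#' @examples
#' tTestPower(0.05, sd = 0.052, n1 = 20, n2 = 14)
#' @export
tTestPower <- function(delta, sd, n1, n2, alpha = 0.05) {
  stopifnot(sd > 0, n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  a1 <- 1 / n1; a2 <- 1 / n2
  df <- (a1 + a2)^2 / (a1^2 / (n1 - 1) + a2^2 / (n2 - 1))
  ncp <- abs(delta) / (sd * sqrt(a1 + a2))
  tc <- qt(1 - alpha / 2, df)
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}

#' @param deltas vector of mean differences for the table.
#' @param n1s,n2s vectors of group sizes, crossed with \code{deltas}.
#' @rdname tTestPower
#' @export
powerTable <- function(deltas, sd, n1s, n2s, alpha = 0.05) {
  grid <- expand.grid(delta = deltas, n1 = n1s, n2 = n2s)
  grid$power <- mapply(function(d, a, b) tTestPower(d, sd, a, b, alpha),
                       grid$delta, grid$n1, grid$n2)
  grid
}

#' Overlap control against suspect SNP sets
#'
#' Tests whether identified hit SNPs overlap a suspect set (e.g. the
#' SNPs with the largest between-population allele-frequency
#' differences, or the noisiest assays) more than chance: reports the
#' observed intersection, the chance expectation |hits| x |suspects| /
#' |universe|, and a two-sided hypergeometric (Fisher) p-value. An
#' observed count near the expectation indicates the hits are not
#' driven by the suspect property.
#'
#' @param hits,suspects character vectors of SNP ids, subsets of
#'   \code{universe}.
#' @param universe character vector of all tested SNP ids.
#' @return list with \code{observed}, \code{expected} and \code{p}.
#' @export
overlapControl <- function(hits, suspects, universe) {
  if (length(universe) == 0L) stop("empty universe")
  hits <- unique(hits); suspects <- unique(suspects)
  universe <- unique(universe)
  stopifnot(all(hits %in% universe), all(suspects %in% universe))
  obs <- length(intersect(hits, suspects))
  expd <- length(hits) * length(suspects) / length(universe)
  tab <- matrix(c(obs, length(hits) - obs, length(suspects) - obs,
                  length(universe) - length(hits) - length(suspects) +
                    obs), 2)
  list(observed = obs, expected = expd,
       p = fisher.test(tab)$p.value)
}

#' Quantile-based suspect SNP sets
#'
#' Convenience selector for \code{\link{overlapControl}}: the top
#' \code{quantile} fraction of SNPs by a per-SNP score (e.g. absolute
#' between-population frequency difference, or assay noise).
#'
#' @param score named numeric vector of per-SNP scores.
#' @param quantile fraction of SNPs to flag (default 0.10).
#' @return Character vector of flagged SNP ids.
#' @export
suspectSnps <- function(score, quantile = 0.10) {
  stopifnot(!is.null(names(score)), quantile > 0, quantile <= 1)
  names(score)[rank(-score, ties.method = "first") <=
                 ceiling(quantile * length(score))]
}

#' Principal-component separation of pools
#'
#' Principal components of the pool x SNP matrix of mean arctan values
#' (columns centered), with a label-permutation test of how cleanly
#' each component separates phenotype groups: the statistic is the
#' absolute difference of phenotype-group mean scores per component,
#' compared against label permutations. Ancestry differences between
#' populations dominate the leading components; phenotype separation on
#' components orthogonal to ancestry would indicate a true (or
#' stratification-free) case/control signal.
#'
#' @param poolMat numeric matrix, pools x SNPs (e.g.
#'   \code{t(poolMeans(panel))}).
#' @param labels character/factor phenotype label per pool.
#' @param nComponents components to assess (default up to 5).
#' @param nTrials label permutations per component (default 1000).
#' @param seed RNG seed.
#' @return list with \code{scores} (pools x components),
#'   \code{varianceFraction} (all components; sums to 1) and
#'   \code{separationP} (empirical p per assessed component).
#' @export
pcaSeparation <- function(poolMat, labels, nComponents = 5,
                          nTrials = 1000, seed = NULL) {
  stopifnot(nrow(poolMat) >= 3, nrow(poolMat) == length(labels))
  if (all(apply(poolMat, 2, function(z) length(unique(z)) == 1L)))
    stop("constant matrix: no principal components")
  pc <- prcomp(poolMat, center = TRUE, scale. = FALSE)
  varFrac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(nComponents, ncol(pc$x))
  labels <- as.character(labels)
  groups <- unique(labels)
  stopifnot(length(groups) == 2L)
  sepStat <- function(scores, lab)
    abs(mean(scores[lab == groups[1]]) - mean(scores[lab == groups[2]]))
  separationP <- withSeed(seed, {
    vapply(seq_len(k), function(j) {
      obs <- sepStat(pc$x[, j], labels)
      null <- vapply(seq_len(nTrials), function(i)
        sepStat(pc$x[, j], sample(labels)), numeric(1))
      (sum(null >= obs) + 1) / (nTrials + 1)
    }, numeric(1))
  })
  list(scores = pc$x, varianceFraction = varFrac,
       separationP = separationP)
}
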