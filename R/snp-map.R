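#' Build, read and filter SNP maps
#'
#' A SNP map is a width-1 \code{GRanges} named by SNP identifier.
#' \code{makeSnpMap} builds one from a data frame with columns
#' \code{snp_id}, \code{chrom}, \code{pos} (1-based). \code{readSnpMap}
#' reads the same three columns from a tab-delimited file;
#' \code{readBim} reads PLINK .bim-style 6-column files (chrom, id,
#' cM, pos, allele1, allele2, no header). \code{writeSnpMap} writes the
#' 3-column form.
#'
#' @param df data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos}.
#' @return A \code{GRanges} named by SNP id.
#' @examples
#' makeSnpMap(data.frame(snp_id = c("rs1", "rs2"),
#'                       chrom = "chr1", pos = c(100, 2000)))
#' @export
makeSnpMap <- function(df) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% colnames(df)))
  if (anyDuplicated(df$snp_id)) stop("snp_id values must be unique")
  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- is.na(pos) | pos <= 0
  if (any(bad)) pos[bad] <- 1  # placeholder; filterSnps drops them
  gr <- GRanges(as.character(df$chrom), IRanges(pos, width = 1))
  names(gr) <- as.character(df$snp_id)
  gr$position_missing <- bad
  gr
}

#' @param file path to a tab-delimited SNP map (header: snp_id, chrom,
#'   pos) or a PLINK .bim file.
#' @rdname makeSnpMap
#' @export
readSnpMap <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  makeSnpMap(df)
}

#' @rdname makeSnpMap
#' @export
readBim <- function(file) {
  df <- read.table(file, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "snp_id", "cm", "pos",
                                 "allele1", "allele2"))
  makeSnpMap(df[, c("snp_id", "chrom", "pos")])
}

#' @param map \code{GRanges} SNP map.
#' @rdname makeSnpMap
#' @export
writeSnpMap <- function(map, file) {
  write.table(
    data.frame(snp_id = names(map), chrom = as.character(seqnames(map)),
               pos = start(map)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Restrict a SNP map to mappable autosomal SNPs
#'
#' Drops SNPs on sex chromosomes (so male and female subjects can be
#' pooled together) and SNPs whose chromosomal position is missing or
#' could not be determined (unplaced contigs). Idempotent; input order
#' is preserved.
#'
#' @param map \code{GRanges} SNP map from \code{\link{makeSnpMap}}.
#' @return The filtered \code{GRanges}.
#' @examples
#' m <- makeSnpMap(data.frame(snp_id = c("a", "b"),
#'                            chrom = c("chr1", "chrX"),
#'                            pos = c(1000, 500)))
#' filterSnps(m)
#' @export
filterSnps <- function(map) {
  chr <- as.character(seqnames(map))
  autosomal <- grepl("^(chr)?(2[0-2]|1[0-9]|[1-9])$", chr)
  placed <- start(map) > 0
  if (!is.null(map$position_missing))
    placed <- placed & !map$position_missing
  out <- map[autosomal & placed]
  # drop levels so repeated application and comparisons are stable
  seqlevels(out) <- seqlevelsInUse(out)
  out
}
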