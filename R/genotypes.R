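#' Genotype dosage matrix
#'
#' Container for biallelic genotype dosages (copies of the alternate allele,
#' `0`/`1`/`2`, `NA` for missing) for n samples at m SNPs, together with a
#' marker map. Positions must be non-decreasing within a chromosome.
#'
#' @param dosages Numeric/integer n x m matrix, rows = samples (rownames =
#'   sample ids), columns = SNPs (colnames = SNP ids).
#' @param map Data frame with one row per SNP: columns `snp`, `chrom`, `pos`
#'   (1-based), optionally `ref`, `alt`.
#' @return Object of class `"genotypes"`: list with `dosages`, `map`,
#'   `sample_ids`.
#' @export
genotypes <- function(dosages, map) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) stop("dosage matrix needs sample id rownames")
  stopifnot(is.data.frame(map), all(c("snp", "chrom", "pos") %in% names(map)))
  if (nrow(map) != ncol(dosages)) stop("map rows must match dosage columns")
  if (is.null(colnames(dosages))) colnames(dosages) <- map$snp
  if (!identical(colnames(dosages), as.character(map$snp)))
    stop("dosage column names disagree with map$snp")
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p)) stop("positions not non-decreasing on chromosome ", ch)
  }
  structure(list(dosages = dosages, map = map,
                 sample_ids = rownames(dosages)),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat("Genotypes: ", nrow(x$dosages), " samples x ", ncol(x$dosages),
      " SNPs on ", length(unique(x$map$chrom)), " chromosome(s); ",
      format(100 * mean(is.na(x$dosages)), digits = 3), "% missing\n", sep = "")
  invisible(x)
}

#' Folded minor allele frequency per SNP
#'
#' @param G A [genotypes] object.
#' @return Named numeric vector of MAFs in `[0, 0.5]` (`NaN` where all
#'   genotypes are missing).
#' @export
maf <- function(G) {
  stopifnot(inherits(G, "genotypes"))
  p <- colMeans(G$dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Subset a genotype object
#'
#' @param G A [genotypes] object.
#' @param samples Sample ids or indices (default: all).
#' @param snps SNP ids or indices (default: all).
#' @return A [genotypes] object.
#' @export
subset_genotypes <- function(G, samples = NULL, snps = NULL) {
  stopifnot(inherits(G, "genotypes"))
  d <- G$dosages
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  map <- G$map
  if (!is.null(snps)) {
    j <- if (is.character(snps)) match(snps, map$snp) else snps
    d <- d[, j, drop = FALSE]
    map <- map[j, , drop = FALSE]
  }
  rownames(map) <- NULL
  genotypes(d, map)
}
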