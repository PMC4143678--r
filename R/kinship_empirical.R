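#' KING-robust kinship estimate for one sample pair
#'
#' Marker-based kinship from heterozygote and opposite-homozygote counts,
#' robust to allele-frequency misspecification and population structure:
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}(i) + N_{Aa}(j)}}
#' where counts run over SNPs non-missing in both samples: \eqn{N_{Aa,Aa}} is
#' the number of SNPs at which both samples are heterozygous,
#' \eqn{N_{AA,aa}} the number with opposite homozygotes, and \eqn{N_{Aa}(i)}
#' the heterozygous-SNP count of sample i.
#'
#' @param g_i,g_j Dosage vectors (0/1/2/NA) of equal length.
#' @return Kinship estimate (0.5 for duplicates/MZ twins, ~0.25
#'   parent-offspring, ~0 unrelated).
#' @export
king_robust_pair <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) stop("dosage vectors differ in length")
  ok <- !is.na(g_i) & !is.na(g_j)
  gi <- g_i[ok]; gj <- g_j[ok]
  het_i <- gi == 1; het_j <- gj == 1
  n_hh <- sum(het_i & het_j)
  n_opp <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  denom <- sum(het_i) + sum(het_j)
  if (denom == 0)
    stop("undefined KING-robust estimate: no heterozygous sites in either sample")
  (n_hh - 2 * n_opp) / denom
}

#' Empirical relatedness matrix (KING-robust)
#'
#' Computes R = 2*phi-hat for every sample pair by the KING-robust estimator
#' (see [king_robust_pair]), using either common variants
#' (`variant_set = "common"`, MAF >= `maf_cut`) or all polymorphic variants
#' (`variant_set = "all"`). SNPs with missingness above `max_missing` are
#' dropped globally; remaining missing genotypes are handled by
#' pairwise-complete deletion. The diagonal is fixed at 1 (no marker-based
#' inbreeding estimate). Because the raw estimator need not yield a positive
#' semidefinite matrix, the result is passed through [nearest_correlation]
#' when `repair = TRUE` (the default), as required before the matrix is
#' inverted in EGV computation.
#'
#' @param G A [genotypes] object.
#' @param variant_set `"common"` or `"all"`.
#' @param maf_cut MAF threshold defining common variants (default 0.05).
#' @param max_missing Per-SNP missingness ceiling (default 0.1).
#' @param repair Repair to the nearest correlation matrix (default `TRUE`).
#' @return A [relatedness] object with source `"snp"` (common) or `"seq"`
#'   (all variants).
#' @export
empirical_relatedness <- function(G, variant_set = c("common", "all"),
                                  maf_cut = 0.05, max_missing = 0.1,
                                  repair = TRUE) {
  variant_set <- match.arg(variant_set)
  stopifnot(inherits(G, "genotypes"))
  D <- G$dosages
  missr <- colMeans(is.na(D))
  fr <- maf(G)
  keep <- missr <= max_missing & !is.na(fr) & fr > 0
  if (variant_set == "common") keep <- keep & fr >= maf_cut
  if (!any(keep)) stop("no informative SNPs after filtering")
  D <- D[, keep, drop = FALSE]

  H <- (D == 1); H[is.na(H)] <- FALSE; storage.mode(H) <- "double"
  A0 <- (D == 0); A0[is.na(A0)] <- FALSE; storage.mode(A0) <- "double"
  A2 <- (D == 2); A2[is.na(A2)] <- FALSE; storage.mode(A2) <- "double"
  NM <- !is.na(D); storage.mode(NM) <- "double"

  n_hh <- tcrossprod(H)                       # both heterozygous
  S <- tcrossprod(A0, A2)                     # i hom-ref, j hom-alt
  n_opp <- S + t(S)
  n_het_pc <- tcrossprod(H, NM)               # het in i over pairwise-complete
  denom <- n_het_pc + t(n_het_pc)

  bad <- denom == 0
  diag(bad) <- FALSE
  if (any(bad)) {
    ij <- which(bad & upper.tri(bad), arr.ind = TRUE)
    pairs <- paste(rownames(D)[ij[, 1]], rownames(D)[ij[, 2]], sep = "/")
    stop("undefined KING-robust estimate (no heterozygous sites) for pair(s): ",
         paste(utils::head(pairs, 10L), collapse = ", "))
  }
  diag(denom) <- 1  # avoid 0/0 on the diagonal; overwritten below
  phi <- (n_hh - 2 * n_opp) / denom
  R <- 2 * phi
  diag(R) <- 1
  R <- (R + t(R)) / 2
  if (repair) R <- nearest_correlation(R)
  relatedness(R, ids = rownames(D),
              source = if (variant_set == "common") "snp" else "seq")
}
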