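#' Sliding-window LD pruning
#'
#' Greedy pruning for a low-LD marker subset: within each window of `window`
#' SNPs (per chromosome), the SNP belonging to the highest-r-squared pair is
#' repeatedly dropped until all surviving pairwise r-squared values are at
#' most `r2_max`; the window then advances by `step` SNPs. Of the two members
#' of the worst pair, the one with the larger summed r-squared against the
#' other survivors is dropped (ties: the later position). Deterministic.
#'
#' @param G A [genotypes] object with positions sorted within chromosome.
#' @param window Window size in SNPs (default 50, must be >= 2).
#' @param step Window step in SNPs (default 5).
#' @param r2_max Maximum tolerated pairwise r-squared (default 0.2).
#' @return Character vector of surviving SNP ids.
#' @export
ld_prune <- function(G, window = 50L, step = 5L, r2_max = 0.2) {
  stopifnot(inherits(G, "genotypes"))
  if (window < 2L) stop("window must be at least 2 SNPs")
  keep <- rep(TRUE, ncol(G$dosages))
  names(keep) <- G$map$snp
  for (ch in unique(G$map$chrom)) {
    idx <- which(G$map$chrom == ch)
    m <- length(idx)
    starts <- seq(1L, max(1L, m - 1L), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, m)]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      D <- G$dosages[, win, drop = FALSE]
      sdv <- apply(D, 2, stats::sd, na.rm = TRUE)
      win <- win[!is.na(sdv) & sdv > 0]
      if (length(win) < 2L) next
      r2 <- stats::cor(G$dosages[, win, drop = FALSE],
                       use = "pairwise.complete.obs")^2
      diag(r2) <- 0
      r2[is.na(r2)] <- 0
      alive <- rep(TRUE, length(win))
      while (TRUE) {
        cur <- r2[alive, alive, drop = FALSE]
        if (!length(cur) || max(cur) <= r2_max) break
        w <- which(cur == max(cur), arr.ind = TRUE)[1, ]
        pair <- which(alive)[c(w[1], w[2])]
        load <- rowSums(r2[pair, alive, drop = FALSE])
        drop_local <- pair[which.max(load + 1e-12 * seq_along(pair))]
        alive[drop_local] <- FALSE
      }
      keep[win[!alive]] <- FALSE
    }
  }
  names(keep)[keep]
}

#' Genotype PCA on an unrelated subset
#'
#' Principal components of standardised genotypes computed from the unrelated
#' individuals only, so family structure does not masquerade as ancestry.
#' SNPs are centred at twice the (unrelated-subset) allele frequency and, by
#' default, scaled by `sqrt(2p(1-p))`; SNPs monomorphic in the subset are
#' dropped. Scores for other genotyped individuals (e.g. all founders) are
#' obtained with [pc_scores] and propagated to relatives with
#' [project_scores].
#'
#' @param G A [genotypes] object (ideally LD-pruned, see [ld_prune]).
#' @param unrelated_ids Ids of the mutually unrelated individuals.
#' @param k Number of components to retain (default 3).
#' @param scaling `"binom"` (centre and scale by `sqrt(2p(1-p))`) or
#'   `"center"` (centre only).
#' @return List of class `"genotype_pca"`: `loadings` (m x k), `scores`
#'   (unrelated individuals x k), `explained` (variance fractions), `center`,
#'   `scale`, `snps`, `scaling`.
#' @export
pca_unrelated <- function(G, unrelated_ids, k = 3L,
                          scaling = c("binom", "center")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(G, "genotypes"))
  unrelated_ids <- as.character(unrelated_ids)
  if (!all(unrelated_ids %in% G$sample_ids)) stop("unrelated ids missing from genotypes")
  if (length(unrelated_ids) < 2L) stop("need at least 2 unrelated individuals")
  if (length(unrelated_ids) < k) stop("fewer unrelated individuals than components")
  D <- G$dosages[unrelated_ids, , drop = FALSE]
  D[is.na(D)] <- NA
  p <- colMeans(D, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no genotypic variance among the unrelated individuals")
  D <- D[, poly, drop = FALSE]
  p <- p[poly]
  ctr <- 2 * p
  scl <- if (scaling == "binom") sqrt(2 * p * (1 - p)) else rep(1, length(p))
  Z <- sweep(D, 2, ctr, "-")
  Z <- sweep(Z, 2, scl, "/")
  Z[is.na(Z)] <- 0  # missing standardised genotypes contribute nothing
  sv <- svd(Z, nu = 0, nv = min(k, ncol(Z)))
  if (max(sv$d) < 1e-10)
    stop("no genotypic variance among the unrelated individuals")
  loadings <- sv$v
  rownames(loadings) <- colnames(D)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  scores <- Z %*% loadings
  expl <- sv$d^2 / sum(sv$d^2)
  structure(list(loadings = loadings, scores = scores,
                 explained = expl[seq_len(ncol(loadings))],
                 center = ctr, scale = scl, snps = colnames(D),
                 scaling = scaling),
            class = "genotype_pca")
}

#' Score genotyped individuals on fitted principal components
#'
#' @param pca A `"genotype_pca"` from [pca_unrelated].
#' @param G A [genotypes] object containing the PCA SNPs.
#' @param ids Individuals to score (default: all samples in `G`).
#' @return Matrix of PC scores (individuals x k).
#' @export
pc_scores <- function(pca, G, ids = G$sample_ids) {
  stopifnot(inherits(pca, "genotype_pca"), inherits(G, "genotypes"))
  D <- G$dosages[as.character(ids), pca$snps, drop = FALSE]
  Z <- sweep(D, 2, pca$center, "-")
  Z <- sweep(Z, 2, pca$scale, "/")
  Z[is.na(Z)] <- 0
  Z %*% pca$loadings
}

#' Project PC scores onto relatives by parental means
#'
#' Every founder must carry a score; processing the pedigree in generation
#' order, each non-founder receives the mean of its two parents' scores. This
#' is the projection rule used to extend a founders-only PCA to a full
#' pedigree without letting relatedness distort the components.
#'
#' @param ped A [pedigree].
#' @param founder_scores Matrix of scores with rownames covering (at least)
#'   all founder ids.
#' @return Matrix of scores for every pedigree member, rows in pedigree
#'   order.
#' @export
project_scores <- function(ped, founder_scores) {
  stopifnot(inherits(ped, "pedigree"))
  founder_scores <- as.matrix(founder_scores)
  founders <- ped$id[ped$founder]
  missing <- setdiff(founders, rownames(founder_scores))
  if (length(missing))
    stop("founder(s) missing a score: ", paste(missing, collapse = ", "))
  k <- ncol(founder_scores)
  out <- matrix(NA_real_, nrow(ped), k,
                dimnames = list(ped$id, colnames(founder_scores)))
  out[founders, ] <- founder_scores[founders, , drop = FALSE]
  for (i in seq_len(nrow(ped))) {
    if (!ped$founder[i]) {
      out[i, ] <- (out[ped$father[i], ] + out[ped$mother[i], ]) / 2
    }
  }
  out
}

#' Assemble the fixed-effect covariate table
#'
#' @param ped A [pedigree].
#' @param age Named numeric vector of ages (years).
#' @param pcs Matrix of PC scores with rownames covering all ids (e.g. from
#'   [project_scores]).
#' @return Data frame (id, age, sex, PC1..PCk); sex coded 0 = male,
#'   1 = female.
#' @export
make_covariates <- function(ped, age, pcs) {
  stopifnot(inherits(ped, "pedigree"))
  ids <- ped$id
  if (!all(ids %in% names(age))) stop("age missing for some individuals")
  if (!all(ids %in% rownames(pcs))) stop("PC scores missing for some individuals")
  out <- data.frame(id = ids, age = as.numeric(age[ids]),
                    sex = as.integer(ped$sex == 2L),
                    stringsAsFactors = FALSE)
  pcs <- as.matrix(pcs)[ids, , drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  cbind(out, as.data.frame(pcs, row.names = NULL))
}
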