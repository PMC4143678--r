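#' Realised variance share of a causal gene
#'
#' Estimates the percentage of total phenotypic variance explained by one
#' causal gene's SNPs, by joint regression of the phenotype on all causal
#' dosages and covariates under the polygenic mixed model (GLS with the
#' pedigree covariance, so family-structured polygenic noise does not leak
#' into the gene's coefficients). The gene's realised contribution per
#' replicate is var(G_g beta_g) / var(y), debiased by the estimation-noise
#' term tr(Var(beta_g) Cov(G_g)); the mean over replicates estimates the
#' designed variance fraction.
#'
#' @param study An `"egv_study"` from [simulate_study].
#' @param gene Gene name from the study's causal architecture.
#' @param replicates Replicate indices to average over (default: all).
#' @return List: `share` (mean, as a fraction), `per_replicate` (vector),
#'   `gene`, `n`.
#' @export
gene_variance_share <- function(study, gene, replicates = NULL) {
  stopifnot(inherits(study, "egv_study"))
  ca <- study$arch$causal
  if (!gene %in% ca$gene) stop("unknown gene: ", gene)
  ids <- study$ped$id
  Gall <- study$G$dosages[ids, ca$snp, drop = FALSE]
  keep <- apply(Gall, 2, stats::var) > 0  # monomorphic causal sites drop out
  Gall <- Gall[, keep, drop = FALSE]
  ca <- ca[keep, , drop = FALSE]
  gsel <- ca$gene == gene
  if (!any(gsel)) stop("gene ", gene, " has no polymorphic causal SNPs")
  cv <- study$covariates
  X <- cbind(`(Intercept)` = 1, age = cv$age, sex = cv$sex, Gall)
  eig <- eigen(study$R_ped$M[ids, ids], symmetric = TRUE)
  Cg <- stats::cov(Gall[, gsel, drop = FALSE])
  jg <- which(gsel) + 3L
  if (is.null(replicates)) replicates <- sort(unique(study$pheno$replicate))
  per <- vapply(replicates, function(r) {
    pr <- study$pheno[study$pheno$replicate == r, ]
    y <- pr$y[match(ids, pr$id)]
    f <- polygenic_fit(y, X, eig = eig)
    bg <- stats::coef(f)[jg]
    Vg <- f$vcov[jg, jg, drop = FALSE]
    (stats::var(drop(Gall[, gsel, drop = FALSE] %*% bg)) -
        sum(diag(Vg %*% Cg))) / stats::var(y)
  }, numeric(1))
  list(share = mean(per), per_replicate = per, gene = gene,
       n = length(ids))
}
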