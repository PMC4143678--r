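#' Estimated genetic values (BLUP) from residualised phenotypes
#'
#' Solves the BLUP shrinkage equation
#' \deqn{\mathrm{EGV} = (I + R^{-1}\lambda)^{-1}(y - X\beta), \qquad
#'       \lambda = \sigma_e^2/\sigma_g^2,}
#' computed as R (R + lambda I)^{-1} (y - X beta) via a symmetric (Cholesky)
#' solve of R + lambda I — algebraically identical to the explicit-inverse
#' form but defined even when R itself is singular, and numerically safer.
#' At lambda = 0 the EGV equals the residual; as lambda grows it is shrunk
#' toward zero, borrowing strength across relatives through R.
#'
#' @param resid Residualised phenotype vector (y - X beta-hat).
#' @param R Relatedness matrix (matrix or [relatedness] object), positive
#'   semidefinite — repair empirical matrices first.
#' @param sigma_g2 Additive genetic variance (> 0).
#' @param sigma_e2 Environmental variance (>= 0).
#' @param ridge Diagonal ridge added to R before solving (default 0; use a
#'   small value such as 1e-8 for empirical matrices).
#' @return List of class `"egv"`: `ids`, `egv`, `lambda`, `sigma_g2`,
#'   `sigma_e2`, `source`, and `E` (NULL until [egv_error_variance] fills
#'   it).
#' @export
compute_egv <- function(resid, R, sigma_g2, sigma_e2, ridge = 0) {
  src <- "ped"
  if (inherits(R, "relatedness")) { src <- R$source; R <- R$M }
  R <- as.matrix(R)
  resid <- as.numeric(resid)
  n <- length(resid)
  if (nrow(R) != n) stop("relatedness matrix does not match residual length")
  if (!is.finite(sigma_g2) || sigma_g2 <= 0)
    stop("no additive variance (sigma_g2 <= 0); EGV undefined")
  if (sigma_e2 < 0) stop("sigma_e2 must be non-negative")
  lambda <- sigma_e2 / sigma_g2
  if (ridge > 0) R <- R + diag(ridge, n)
  A <- R + diag(lambda, n)
  ch <- tryCatch(chol(A), error = function(e)
    stop("R + lambda I is not positive definite (singular relatedness matrix?)"))
  egv <- drop(R %*% chol2inv(ch) %*% resid)
  ids <- rownames(R)
  if (!is.null(ids)) names(egv) <- ids
  structure(list(ids = ids, egv = egv, lambda = lambda,
                 sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 source = src, E = NULL),
            class = "egv")
}

#' Prediction-error variance of the EGV
#'
#' The error-variance matrix E of the BLUP genetic values,
#' \deqn{E = \mathrm{Var}(\widehat{g} - g)
#'         = \sigma_g^2 R - \sigma_g^2 R (R + \lambda I)^{-1} R
#'         = \sigma_g^2 \lambda\, R (R + \lambda I)^{-1},}
#' the standard prediction-error variance for this model. It vanishes as
#' sigma_e^2 -> 0 (perfect prediction) and equals
#' diag(sigma_g^2 lambda / (1 + lambda)) when R = I.
#'
#' @inheritParams compute_egv
#' @return Symmetric PSD matrix (phenotype units squared).
#' @export
egv_error_variance <- function(R, sigma_g2, sigma_e2, ridge = 0) {
  if (inherits(R, "relatedness")) R <- R$M
  R <- as.matrix(R)
  if (!is.finite(sigma_g2) || sigma_g2 <= 0)
    stop("no additive variance (sigma_g2 <= 0); EGV undefined")
  lambda <- sigma_e2 / sigma_g2
  n <- nrow(R)
  if (ridge > 0) R <- R + diag(ridge, n)
  A <- R + diag(lambda, n)
  E <- sigma_g2 * lambda * solve(A, R)
  E <- (E + t(E)) / 2
  dimnames(E) <- dimnames(R)
  E
}

#' @export
print.egv <- function(x, digits = 4, ...) {
  cat("Estimated genetic values (source: ", x$source, "), n = ",
      length(x$egv), "\n", sep = "")
  cat("  lambda = sigma_e2/sigma_g2 = ", format(x$lambda, digits = digits),
      "; sd(EGV) = ", format(stats::sd(x$egv), digits = digits), "\n", sep = "")
  if (!is.null(x$E))
    cat("  mean prediction-error variance: ",
        format(mean(diag(x$E)), digits = digits), "\n", sep = "")
  invisible(x)
}

#' EGVs from a fitted polygenic model
#'
#' Convenience wrapper chaining the fit's residuals and variance components
#' into [compute_egv] (and [egv_error_variance] when `pev = TRUE`). By
#' default the relatedness matrix of the fit is reused; supply `relatedness`
#' to predict with a different (e.g. empirical) matrix.
#'
#' @param fit A `"polygenic"` fit.
#' @param relatedness Optional [relatedness] object overriding the fit's
#'   matrix.
#' @param pev Also compute the error-variance matrix E (default `TRUE`).
#' @param ridge Diagonal ridge for empirical matrices (default 1e-8 for
#'   sources `"snp"`/`"seq"`, 0 for `"ped"`).
#' @return An `"egv"` object.
#' @export
egv <- function(fit, relatedness = NULL, pev = TRUE, ridge = NULL) {
  stopifnot(inherits(fit, "polygenic"))
  if (fit$boundary && fit$h2 == 0)
    stop("no additive variance (sigma_g2 <= 0); EGV undefined")
  if (is.null(relatedness)) {
    R <- fit$eigen$vectors %*% (pmax(fit$eigen$values, 0) * t(fit$eigen$vectors))
    rownames(R) <- colnames(R) <- fit$ids
    src <- "ped"
  } else {
    stopifnot(inherits(relatedness, "relatedness"))
    R <- relatedness$M[fit$ids, fit$ids]
    src <- relatedness$source
  }
  if (is.null(ridge)) ridge <- if (src == "ped") 0 else 1e-8
  out <- compute_egv(fit$residuals, R, fit$sigma_g2, fit$sigma_e2, ridge = ridge)
  out$source <- src
  if (pev) out$E <- egv_error_variance(R, fit$sigma_g2, fit$sigma_e2, ridge = ridge)
  out
}

#' Per-replicate EGV pipeline
#'
#' For each phenotype replicate: fit the polygenic model on the supplied
#' covariates and relatedness matrix, residualise, and compute the EGV (and
#' its error-variance matrix) with that replicate's own variance-component
#' estimates. Replicates whose heritability estimate hits the zero boundary
#' are emitted as skip records (the EGV is undefined without additive
#' variance).
#'
#' @param pheno Long data frame with columns `id`, `replicate`, `y`.
#' @param covariates Data frame with `id`, `age`, `sex`, `PC1..PCk` (fixed
#'   across replicates).
#' @param relatedness A [relatedness] object; its `source` labels the output
#'   (EGV_ped / EGV_snp / EGV_seq).
#' @param pev Compute E per replicate (default `TRUE`).
#' @param method `"ML"` or `"REML"`.
#' @return List of class `"egv_set"`: `source`, `replicates` (list of
#'   `"egv"` objects or skip records `list(skipped = TRUE, reason = ...)`),
#'   `fits` (the polygenic fits), `ids`.
#' @export
egv_pipeline <- function(pheno, covariates, relatedness, pev = TRUE,
                         method = "ML") {
  stopifnot(all(c("id", "replicate", "y") %in% names(pheno)),
            inherits(relatedness, "relatedness"))
  ids <- covariates$id
  K <- relatedness$M[ids, ids]
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  pc_cols <- grep("^PC", names(covariates), value = TRUE)
  form <- stats::reformulate(c("age", "sex", pc_cols), response = "y")
  X <- stats::model.matrix(form[-2], covariates)
  reps <- sort(unique(pheno$replicate))
  out <- vector("list", length(reps))
  fits <- vector("list", length(reps))
  names(out) <- names(fits) <- as.character(reps)
  for (r in seq_along(reps)) {
    pr <- pheno[pheno$replicate == reps[r], ]
    yv <- pr$y[match(ids, pr$id)]
    fit <- polygenic_fit(yv, X, method = method, ids = ids, eig = eig)
    fits[[r]] <- fit
    if (fit$h2 <= 0) {
      out[[r]] <- list(skipped = TRUE,
                       reason = "h2 at zero boundary; EGV undefined")
      next
    }
    ridge <- if (relatedness$source == "ped") 0 else 1e-8
    e <- compute_egv(fit$residuals, K, fit$sigma_g2, fit$sigma_e2, ridge = ridge)
    e$source <- relatedness$source
    if (pev) e$E <- egv_error_variance(K, fit$sigma_g2, fit$sigma_e2, ridge = ridge)
    out[[r]] <- e
  }
  structure(list(source = relatedness$source, replicates = out, fits = fits,
                 ids = ids),
            class = "egv_set")
}

#' @export
print.egv_set <- function(x, ...) {
  skipped <- vapply(x$replicates, function(r) isTRUE(r$skipped), logical(1))
  cat("EGV set (source: ", x$source, "): ", length(x$replicates),
      " replicates (", sum(skipped), " skipped), n = ", length(x$ids),
      "\n", sep = "")
  invisible(x)
}
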