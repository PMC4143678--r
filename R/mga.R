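#' Null-model fit for measured-genotype association
#'
#' Fits the no-SNP polygenic null model under the family covariance
#' \deqn{\Omega = \sigma_p^2\,(2\Phi\,h^2 + I\,e^2 + E_n\,\varepsilon)}
#' with the variance shares (h^2, e^2, epsilon) on the unit simplex and E_n
#' the EGV error-variance matrix normalised to unit mean diagonal (so that
#' epsilon is a variance proportion comparable to h^2). With `E = NULL` the
#' model reduces exactly to the standard polygenic covariance. The expected
#' kinship matrix 2*Phi is diagonalised once; when E shares its eigenvectors
#' (as the pedigree-derived prediction-error variance does) the whole
#' optimisation stays in eigen space, otherwise a dense Cholesky path is
#' used.
#'
#' @param y Trait vector (raw phenotype or EGV).
#' @param X Fixed-effect design matrix (with intercept).
#' @param Phi2 Expected relatedness matrix 2*Phi (matrix or [relatedness]).
#' @param E Optional error-variance matrix (see [egv_error_variance]).
#' @return Object of class `"mga_null"` carrying the spectral prep, the
#'   fitted variance shares and the null log-likelihood.
#' @export
mga_null_fit <- function(y, X, Phi2, E = NULL) {
  if (inherits(Phi2, "relatedness")) Phi2 <- Phi2$M
  Phi2 <- as.matrix(Phi2)
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(Phi2) == n)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effect design")
  eig <- eigen((Phi2 + t(Phi2)) / 2, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  prep <- list(U = U, d = d, Xt = crossprod(U, X), yt = drop(crossprod(U, y)),
               y = y, X = X, Phi2 = Phi2, u = NULL, En = NULL, dense = FALSE)
  if (!is.null(E) && mean(diag(as.matrix(E))) <= 1e-12) E <- NULL  # no error
  if (!is.null(E)) {
    E <- as.matrix(E)
    En <- E / mean(diag(E))
    C <- crossprod(U, En %*% U)
    off <- max(abs(C - diag(diag(C))))
    if (off < 1e-6) {
      prep$u <- pmax(diag(C), 0)
    } else {
      prep$dense <- TRUE
      prep$En <- En
    }
  }
  null <- .mga_fit(prep, prep$yt, prep$Xt, prep$y, prep$X)
  structure(c(prep, list(null = null)), class = "mga_null")
}

# Maximise the ML profile likelihood over the variance shares.
# Fast path: weights w_i = h2*d_i + e2 + eps*u_i in eigen space.
# Dense path: Sigma = h2*Phi2 + e2*I + eps*En via Cholesky.
.mga_fit <- function(prep, yt, Xt, y = NULL, X = NULL) {
  if (!prep$dense) {
    ll1 <- function(h2) .vc_profile(yt, Xt, h2 * prep$d + (1 - h2), "ML")$loglik
    opt <- stats::optimize(ll1, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- rbind(c(0, 1, 0, ll1(0)), c(opt$maximum, 1 - opt$maximum, 0, opt$objective),
                  c(1, 0, 0, ll1(1)))
    if (!is.null(prep$u)) {
      obj <- function(par) {
        th <- exp(c(par, 0)); th <- th / sum(th)
        w <- th[1] * prep$d + th[2] + th[3] * prep$u
        -.vc_profile(yt, Xt, w, "ML")$loglik
      }
      for (start in list(c(0, 0), c(1.5, 1.5), c(-1, 1))) {
        o <- stats::optim(start, obj, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-10))
        th <- exp(c(o$par, 0)); th <- th / sum(th)
        cand <- rbind(cand, c(th[1], th[2], th[3], -o$value))
      }
    }
    best <- cand[which.max(cand[, 4]), ]
    th <- best[1:3]
    w <- th[1] * prep$d + th[2] + if (is.null(prep$u)) 0 else th[3] * prep$u
    pr <- .vc_profile(yt, Xt, w, "ML")
    list(theta = c(h2 = th[1], e2 = th[2], eps = th[3]),
         beta = pr$beta, sigma_p2 = pr$sigma_p2, loglik = best[4],
         vcov = pr$vcov, converged = TRUE)
  } else {
    n <- length(y)
    densell <- function(th) {
      Sigma <- th[1] * prep$Phi2 + diag(th[2], n) + th[3] * prep$En
      ch <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (is.null(ch)) return(list(loglik = -Inf))
      Ly <- backsolve(ch, y, transpose = TRUE)
      LX <- backsolve(ch, X, transpose = TRUE)
      qrX <- qr(LX)
      beta <- qr.coef(qrX, Ly)
      rss <- sum(qr.resid(qrX, Ly)^2)
      sigma_p2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi) + n * log(sigma_p2) +
                      2 * sum(log(diag(ch))) + n)
      list(loglik = ll, beta = beta, sigma_p2 = sigma_p2,
           vcov = sigma_p2 * chol2inv(qr.R(qrX)))
    }
    obj <- function(par) {
      th <- exp(c(par, 0)); th <- th / sum(th)
      -densell(th)$loglik
    }
    best <- NULL; bestll <- -Inf; conv <- TRUE
    for (start in list(c(0, 0), c(1.5, 1.5), c(-1, 1))) {
      o <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
      if (-o$value > bestll) {
        bestll <- -o$value
        th <- exp(c(o$par, 0)); best <- th / sum(th)
        conv <- o$convergence == 0
      }
    }
    fit <- densell(best)
    list(theta = c(h2 = best[1], e2 = best[2], eps = best[3]),
         beta = fit$beta, sigma_p2 = fit$sigma_p2, loglik = fit$loglik,
         vcov = fit$vcov, converged = conv)
  }
}

#' Measured-genotype association test for one SNP
#'
#' Likelihood-ratio test of an additive allelic fixed effect: the null model
#' (trait on covariates under the family covariance, see [mga_null_fit]) is
#' compared with the alternative adding the SNP dosage as one fixed effect,
#' with all variance parameters re-optimised in both. The statistic
#' 2(logLik_alt - logLik_null), clamped at zero, is referred to chi-squared
#' with 1 degree of freedom. Missing dosages are mean-imputed.
#'
#' @param null An `"mga_null"` fit (or `NULL`, in which case `y`, `X`,
#'   `Phi2`, `E` are used to fit one).
#' @param g Dosage vector for the SNP.
#' @param y,X,Phi2,E Passed to [mga_null_fit] when `null` is `NULL`.
#' @return List: `beta` (allelic effect), `se`, `lrt`, `p`, `converged`,
#'   `theta_alt`.
#' @export
mga_test <- function(g, null = NULL, y = NULL, X = NULL, Phi2 = NULL, E = NULL) {
  if (is.null(null)) null <- mga_null_fit(y, X, Phi2, E)
  stopifnot(inherits(null, "mga_null"))
  g <- as.numeric(g)
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (stats::var(g) == 0) stop("monomorphic SNP: no genotypic contrast")
  Xa <- cbind(null$X, snp = g)
  gt <- drop(crossprod(null$U, g))
  Xat <- cbind(null$Xt, snp = gt)
  alt <- .mga_fit(null[!names(null) %in% "null"], null$yt, Xat, null$y, Xa)
  lrt <- max(0, 2 * (alt$loglik - null$null$loglik))
  k <- length(alt$beta)
  list(beta = unname(alt$beta[k]), se = sqrt(alt$vcov[k, k]),
       lrt = lrt, p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       converged = alt$converged, theta_alt = alt$theta)
}

#' Genome scan by measured-genotype association
#'
#' Runs [mga_test] for every SNP in a genotype matrix against one trait. The
#' null model is fitted once and reused; per-SNP failures (monomorphic sites,
#' non-convergence) become flagged records and never abort the scan.
#'
#' @param y Trait vector aligned with `G`'s samples.
#' @param G A [genotypes] object.
#' @param X Fixed-effect design matrix.
#' @param Phi2 Expected relatedness 2*Phi (matrix or [relatedness]).
#' @param E Optional error-variance matrix (include for EGV traits).
#' @param threshold Genome-wide significance threshold (default 5e-8).
#' @param trait Label stored with the results (e.g. `"SBP"`, `"EGV_ped"`).
#' @return Data frame of class `"mga_scan"`: snp, chrom, pos, maf, beta, lrt,
#'   p, significant, note.
#' @export
mga_scan <- function(y, G, X, Phi2, E = NULL, threshold = 5e-8,
                     trait = "trait") {
  stopifnot(inherits(G, "genotypes"))
  null <- mga_null_fit(y, X, Phi2, E)
  m <- ncol(G$dosages)
  fr <- maf(G)
  res <- data.frame(snp = G$map$snp, chrom = G$map$chrom, pos = G$map$pos,
                    maf = unname(fr), beta = NA_real_, lrt = NA_real_,
                    p = NA_real_, significant = FALSE, note = "ok",
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    g <- G$dosages[, j]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (!is.finite(stats::var(g)) || stats::var(g) == 0) {
      res$note[j] <- "skipped: monomorphic"
      next
    }
    t <- mga_test(g, null = null)
    res$beta[j] <- t$beta; res$lrt[j] <- t$lrt; res$p[j] <- t$p
    if (!t$converged) res$note[j] <- "non-convergence flagged"
  }
  res$significant <- !is.na(res$p) & res$p < threshold
  attr(res, "trait") <- trait
  attr(res, "threshold") <- threshold
  attr(res, "null") <- null$null
  class(res) <- c("mga_scan", "data.frame")
  res
}

#' @export
print.mga_scan <- function(x, ...) {
  cat("MGA scan (", attr(x, "trait"), "): ", nrow(x), " SNPs, ",
      sum(x$significant), " significant at p < ",
      format(attr(x, "threshold")), "\n", sep = "")
  ok <- !is.na(x$p)
  if (any(ok))
    cat("  min p = ", format(min(x$p[ok]), digits = 3), " at ",
        x$snp[ok][which.min(x$p[ok])], "\n", sep = "")
  invisible(x)
}

#' Median-based inflation factor
#'
#' Lambda = median(LRT) / qchisq(0.5, 1), the genomic-control style check
#' that a set of null association statistics follows chi-squared(1).
#'
#' @param lrt Vector of likelihood-ratio statistics.
#' @return Scalar inflation factor.
#' @export
inflation_lambda <- function(lrt) {
  stats::median(lrt, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
}
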