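#' Fit a variance-component polygenic model
#'
#' Fits the mixed model y = X beta + g + e with g ~ N(0, sigma_g^2 R) and
#' e ~ N(0, sigma_e^2 I), where R = 2*Phi is a relatedness matrix, by maximum
#' likelihood (default) or REML. The covariance sigma_p^2 (h^2 R + (1-h^2) I)
#' is diagonalised once through the spectral decomposition of R; for each
#' candidate heritability h^2 the fixed effects and the total variance
#' sigma_p^2 are profiled out in closed form, leaving a one-dimensional
#' optimisation of h^2 on [0, 1]. Boundary optima are returned as exact 0 or
#' 1 with `boundary = TRUE`; a likelihood flat in h^2 (e.g. R = I, where
#' sigma_g^2 and sigma_e^2 are not separately identifiable) yields h^2 = 0
#' with a warning.
#'
#' @param formula Model formula for the fixed effects, e.g.
#'   `y ~ age + sex + PC1 + PC2 + PC3`.
#' @param data Data frame holding the variables plus an `id` column matching
#'   the relatedness ids (rownames are used if there is no `id` column).
#' @param relatedness A [relatedness] object (repair empirical matrices
#'   first, see [nearest_correlation]).
#' @param method `"ML"` (default) or `"REML"`.
#' @param tol Convergence tolerance for the h^2 optimisation (default 1e-8).
#' @return Object of class `"polygenic"` with elements `coefficients`, `h2`,
#'   `sigma_g2`, `sigma_e2`, `sigma_p2`, `loglik`, `boundary`, `residuals`
#'   (marginal, y - X beta-hat), `fitted`, `vcov`, `ids`, `n`, `method`.
#' @seealso [egv] for BLUP genetic values from a fit; [mga_scan] for
#'   association scans under the same covariance family.
#' @export
polygenic <- function(formula, data, relatedness, method = c("ML", "REML"),
                      tol = 1e-8) {
  method <- match.arg(method)
  stopifnot(inherits(relatedness, "relatedness"))
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  ids <- if ("id" %in% names(data)) as.character(data$id) else rownames(data)
  if (is.null(ids)) stop("data needs an `id` column (or rownames) matching relatedness ids")
  if (!all(ids %in% relatedness$ids))
    stop("individual(s) absent from relatedness matrix: ",
         paste(utils::head(setdiff(ids, relatedness$ids), 5L), collapse = ", "))
  K <- relatedness$M[ids, ids]
  fit <- polygenic_fit(y, X, K, method = method, tol = tol, ids = ids)
  fit$call <- match.call()
  fit
}

#' Low-level polygenic fit on prepared matrices
#'
#' Matrix-interface workhorse behind [polygenic]; useful when the design is
#' already assembled (as in simulation loops) or when one eigendecomposition
#' of R is to be reused across many phenotype replicates via `eig`.
#'
#' @param y Numeric response vector.
#' @param X Design matrix including the intercept column.
#' @param K Relatedness matrix (n x n, PSD), ignored when `eig` is given.
#' @param method `"ML"` or `"REML"`.
#' @param tol Optimisation tolerance.
#' @param ids Optional individual ids.
#' @param eig Optional precomputed `eigen(K, symmetric = TRUE)`.
#' @return A `"polygenic"` object (see [polygenic]).
#' @export
polygenic_fit <- function(y, X, K = NULL, method = c("ML", "REML"),
                          tol = 1e-8, ids = NULL, eig = NULL) {
  method <- match.arg(method)
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (!all(is.finite(y))) stop("non-finite phenotype values")
  if (nrow(X) != n) stop("dimension mismatch between y and X")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effect design")
  if (is.null(eig)) {
    K <- as.matrix(K)
    if (nrow(K) != n) stop("relatedness matrix does not match phenotype length")
    eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  }
  d <- eig$values
  if (min(d) < -1e-6)
    stop("relatedness matrix is not positive semidefinite; repair it first")
  d <- pmax(d, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  p <- ncol(X)

  prof <- function(h2) .vc_profile(yt, Xt, h2 * d + (1 - h2), method)
  ll <- function(h2) prof(h2)$loglik

  ll0 <- ll(0); ll1 <- ll(1)
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = tol)
  cands <- c(`0` = ll0, opt = opt$objective, `1` = ll1)
  flat <- (max(cands) - min(cands)) < 1e-8
  if (flat) {
    h2 <- 0
    boundary <- TRUE
    warning("likelihood is flat in h2 (variance components not identifiable); ",
            "returning the h2 = 0 boundary")
  } else if (ll0 >= opt$objective - 1e-10 && ll0 >= ll1) {
    h2 <- 0; boundary <- TRUE
  } else if (ll1 >= opt$objective - 1e-10 && ll1 > ll0) {
    h2 <- 1; boundary <- TRUE
  } else {
    h2 <- opt$maximum; boundary <- FALSE
  }
  best <- prof(h2)

  beta <- best$beta
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  if (!is.null(ids)) names(resid) <- names(fitted) <- ids
  structure(list(coefficients = beta, h2 = h2,
                 sigma_p2 = best$sigma_p2,
                 sigma_g2 = h2 * best$sigma_p2,
                 sigma_e2 = (1 - h2) * best$sigma_p2,
                 loglik = best$loglik, boundary = boundary, flat = flat,
                 residuals = resid, fitted = fitted,
                 vcov = best$vcov, method = method,
                 n = n, p = p, ids = ids, y = y, X = X,
                 eigen = eig, call = match.call()),
            class = "polygenic")
}

# Profile loglik at fixed weights w_i (eigen-space variances / sigma_p2).
# Returns GLS beta, profiled sigma_p2 and the ML or REML log-likelihood.
.vc_profile <- function(yt, Xt, w, method) {
  w <- pmax(w, 1e-12)
  sw <- sqrt(w)
  Xw <- Xt / sw
  yw <- yt / sw
  qrX <- qr(Xw)
  beta <- qr.coef(qrX, yw)
  rss <- sum(qr.resid(qrX, yw)^2)
  n <- length(yt); p <- ncol(Xt)
  if (method == "ML") {
    sigma_p2 <- rss / n
    loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma_p2) + sum(log(w)) + n)
  } else {
    sigma_p2 <- rss / (n - p)
    Rmat <- qr.R(qrX)
    logdetXWX <- 2 * sum(log(abs(diag(Rmat))))
    loglik <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma_p2) +
                        sum(log(w)) + logdetXWX + (n - p))
  }
  XtWX_inv <- chol2inv(qr.R(qrX))
  vcov <- sigma_p2 * XtWX_inv
  list(beta = beta, sigma_p2 = sigma_p2, loglik = loglik, vcov = vcov)
}

#' @export
print.polygenic <- function(x, digits = 4, ...) {
  cat("Polygenic model (", x$method, "), n = ", x$n, "\n", sep = "")
  cat("  h2 = ", format(x$h2, digits = digits),
      if (x$boundary) " (boundary)",
      "   sigma_g2 = ", format(x$sigma_g2, digits = digits),
      "   sigma_e2 = ", format(x$sigma_e2, digits = digits), "\n", sep = "")
  cat("  log-likelihood: ", format(x$loglik, digits = digits + 2), "\n", sep = "")
  cat("Fixed effects:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.polygenic <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, h2 = object$h2, sigma_g2 = object$sigma_g2,
              sigma_e2 = object$sigma_e2, sigma_p2 = object$sigma_p2,
              loglik = object$loglik, boundary = object$boundary,
              n = object$n, method = object$method, call = object$call)
  class(out) <- "summary.polygenic"
  out
}

#' @export
print.summary.polygenic <- function(x, digits = 4, ...) {
  cat("Polygenic model (", x$method, "), n = ", x$n, "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nVariance components:\n")
  cat("  sigma_g2 = ", format(x$sigma_g2, digits = digits),
      "   sigma_e2 = ", format(x$sigma_e2, digits = digits),
      "   sigma_p2 = ", format(x$sigma_p2, digits = digits), "\n", sep = "")
  cat("  h2 = ", format(x$h2, digits = digits),
      if (x$boundary) " (boundary estimate)", "\n", sep = "")
  cat("  log-likelihood: ", format(x$loglik, digits = digits + 2), "\n", sep = "")
  invisible(x)
}

#' @export
coef.polygenic <- function(object, ...) object$coefficients

#' @export
logLik.polygenic <- function(object, ...) {
  structure(object$loglik, df = object$p + 2, nobs = object$n,
            class = "logLik")
}

#' @export
vcov.polygenic <- function(object, ...) object$vcov

#' @export
fitted.polygenic <- function(object, ...) object$fitted

#' Residuals from a polygenic fit
#'
#' `type = "response"` (default) gives the marginal residuals y - X beta-hat
#' — the residualised phenotype the EGV equation consumes. `type = "genetic"`
#' subtracts the BLUP genetic value as well, leaving the estimated
#' environmental deviation.
#'
#' @param object A `"polygenic"` fit.
#' @param type `"response"` or `"genetic"`.
#' @param ... Unused.
#' @export
residuals.polygenic <- function(object, type = c("response", "genetic"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "genetic") {
    K <- object$eigen$vectors %*% (pmax(object$eigen$values, 0) *
                                     t(object$eigen$vectors))
    r <- r - compute_egv(r, K, object$sigma_g2, object$sigma_e2)$egv
  }
  r
}

#' Simulate phenotypes from a fitted polygenic model
#'
#' @param object A `"polygenic"` fit.
#' @param nsim Number of replicates.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Data frame of simulated phenotype vectors, one column per
#'   replicate.
#' @export
simulate.polygenic <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  U <- object$eigen$vectors
  d <- pmax(object$eigen$values, 0)
  n <- object$n
  out <- matrix(NA_real_, n, nsim)
  for (s in seq_len(nsim)) {
    g <- U %*% (sqrt(object$sigma_g2 * d) * stats::rnorm(n))
    out[, s] <- object$fitted + g + stats::rnorm(n, sd = sqrt(object$sigma_e2))
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
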