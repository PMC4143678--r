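# shared small study: 3 families, ~70 members, pedigree kinship
small_study <- local({
  cfg <- tiny_cfg(n_families = 3L, target_n = 70L)
  ped <- simulate_pedigree(cfg, seed = 12)
  K <- expected_relatedness(ped)$M
  set.seed(12)
  n <- nrow(ped)
  X <- cbind(1, age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5))
  list(ped = ped, K = K, X = X, n = n, C = chol(K + diag(1e-10, n)))
})

sim_y <- function(h2, sp2 = 100, beta = c(50, 0.5, -2)) {
  with(small_study, {
    g <- sqrt(h2 * sp2) * drop(t(C) %*% rnorm(n))
    drop(X %*% beta) + g + rnorm(n, sd = sqrt((1 - h2) * sp2))
  })
}

test_that("noiseless regression limit recovers coefficients exactly", {
  b <- c(10, 0.25, -3)
  y <- drop(small_study$X %*% b) + rnorm(small_study$n, sd = 1e-7)
  f <- polygenic_fit(y, small_study$X, small_study$K)
  expect_equal(unname(coef(f)), b, tolerance = 1e-6)
  expect_equal(unname(residuals(f)), drop(y - small_study$X %*% b),
               tolerance = 1e-6)
})

test_that("spectral profile likelihood equals dense MVN evaluation", {
  set.seed(13)
  y <- sim_y(0.5)
  f <- polygenic_fit(y, small_study$X, small_study$K)
  S <- f$sigma_g2 * small_study$K + f$sigma_e2 * diag(small_study$n)
  ll_dense <- dense_mvn_loglik(y, drop(small_study$X %*% coef(f)), S)
  expect_equal(f$loglik, ll_dense, tolerance = 1e-8)
  # and the optimum matches a dense grid-search ML fit
  dml <- dense_ml_fit(y, small_study$X, small_study$K)
  expect_lt(abs(f$h2 - dml$h2), 2e-3)
  expect_gte(f$loglik, dml$ll - 1e-6)
})

test_that("heritability recovery is unbiased across the design range", {
  set.seed(14)
  for (h2 in c(0.2, 0.8)) {
    est <- replicate(25, polygenic_fit(sim_y(h2), small_study$X,
                                       small_study$K)$h2)
    expect_lt(abs(mean(est) - h2), 0.12)  # small n fixture: generous bound
  }
})

test_that("h2 = 0 data yield near-zero estimates", {
  set.seed(15)
  est <- replicate(20, polygenic_fit(sim_y(0), small_study$X, small_study$K)$h2)
  expect_lt(mean(est), 0.06)
})

test_that("optimum log-likelihood dominates both h2 endpoints", {
  set.seed(16)
  y <- sim_y(0.5)
  f <- polygenic_fit(y, small_study$X, small_study$K)
  eig <- f$eigen
  yt <- drop(crossprod(eig$vectors, y))
  Xt <- crossprod(eig$vectors, small_study$X)
  ll_at <- function(h2)
    egvkit:::.vc_profile(yt, Xt, h2 * pmax(eig$values, 0) + (1 - h2), "ML")$loglik
  expect_gte(f$loglik, ll_at(0) - 1e-8)
  expect_gte(f$loglik, ll_at(1) - 1e-8)
})

test_that("identity kinship gives a flat likelihood and the h2=0 boundary", {
  set.seed(17)
  y <- rnorm(50, 10)
  X <- matrix(1, 50, 1)
  expect_warning(f <- polygenic_fit(y, X, diag(50)), "flat")
  expect_equal(f$h2, 0)
  expect_true(f$boundary)
})

test_that("h2 estimate is invariant to affine rescaling of the phenotype", {
  set.seed(18)
  y <- sim_y(0.5)
  f1 <- polygenic_fit(y, small_study$X, small_study$K)
  f2 <- polygenic_fit(7.3 * y - 150, small_study$X, small_study$K)
  expect_lt(abs(f1$h2 - f2$h2), 1e-6)
})

test_that("GLS residual structure: intercept-only mean and orthogonality", {
  set.seed(19)
  y <- sim_y(0.4)
  X1 <- matrix(1, small_study$n, 1)
  f <- polygenic_fit(y, X1, small_study$K)
  # ML mean equals the GLS mean under the fitted covariance
  S <- f$sigma_g2 * small_study$K + f$sigma_e2 * diag(small_study$n)
  Si <- solve(S)
  mu_gls <- drop(solve(t(X1) %*% Si %*% X1, t(X1) %*% Si %*% y))
  expect_equal(unname(coef(f)[1]), mu_gls, tolerance = 1e-6)
  # residuals orthogonal to X under the inverse-covariance metric
  f2 <- polygenic_fit(y, small_study$X, small_study$K)
  S2 <- f2$sigma_g2 * small_study$K + f2$sigma_e2 * diag(small_study$n)
  score <- t(small_study$X) %*% solve(S2, residuals(f2))
  expect_lt(max(abs(score)), 1e-6)
})

test_that("formula interface, methods and error paths behave", {
  set.seed(20)
  y <- sim_y(0.5)
  d <- data.frame(id = small_study$ped$id, y = y,
                  age = small_study$X[, "age"], sex = small_study$X[, "sex"])
  R <- expected_relatedness(small_study$ped)
  f <- polygenic(y ~ age + sex, d, R)
  expect_s3_class(f, "polygenic")
  expect_named(coef(f), c("(Intercept)", "age", "sex"))
  expect_equal(as.numeric(logLik(f)), f$loglik)
  s <- summary(f)
  expect_s3_class(s, "summary.polygenic")
  expect_equal(dim(s$coefficients), c(3L, 4L))
  expect_output(print(f), "Polygenic model")
  sim <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(small_study$n, 2L))
  # REML runs and gives a comparable estimate
  fr <- polygenic(y ~ age + sex, d, R, method = "REML")
  expect_lt(abs(fr$h2 - f$h2), 0.15)
  # error paths
  Xbad <- cbind(small_study$X, small_study$X[, 2])
  expect_error(polygenic_fit(y, Xbad, small_study$K), "rank")
  expect_error(polygenic_fit(c(y[-1], NA), small_study$X, small_study$K),
               "non-finite")
  Kbad <- small_study$K; Kbad[1, 2] <- Kbad[2, 1] <- 5
  expect_error(polygenic_fit(y, small_study$X, Kbad), "positive semidefinite")
})
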