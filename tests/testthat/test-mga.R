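mga_fixture <- local({
  cfg <- tiny_cfg(n_families = 4L, target_n = 100L, m_snps = 80L,
                  h2_polygenic = 0.3, n_replicates = 1L)
  st <- simulate_study(cfg, seed = 30)
  ids <- st$ped$id
  X <- model.matrix(~ age + sex, st$covariates)
  y <- st$pheno$y[match(ids, st$pheno$id)]
  list(st = st, ids = ids, X = X, y = y, Phi2 = st$R_ped$M, n = length(ids))
})

test_that("monomorphic SNPs are skipped, scans never abort", {
  with(mga_fixture, {
    expect_error(mga_test(rep(2, n), y = y, X = X, Phi2 = Phi2), "monomorphic")
    D <- st$G$dosages[, 1:5]
    D[, 3] <- 0
    map <- st$G$map[1:5, ]
    sc <- mga_scan(y, genotypes(D, map), X, Phi2)
    expect_equal(sc$note[3], "skipped: monomorphic")
    expect_true(all(is.finite(sc$p[-3]) | sc$note[-3] != "ok"))
  })
})

test_that("strong planted effect is recovered in the regression limit", {
  with(mga_fixture, {
    set.seed(31)
    g <- st$G$dosages[, which.max(maf(st$G))]
    ylim <- 5.0 * g + rnorm(n, sd = 0.001)
    t <- mga_test(g, y = ylim, X = X, Phi2 = Phi2)
    expect_lt(abs(t$beta - 5.0), 1e-3)
    expect_gt(t$lrt, 30)
  })
})

test_that("planted 5%-variance SNP is the scan minimum", {
  cfg <- tiny_cfg(n_families = 4L, target_n = 100L, m_snps = 60L,
                  h2_polygenic = 0.2, n_replicates = 1L, ld_rho = 0,
                  genes = data.frame(gene = "gA", chrom = 1L, n_snps = 1L,
                                     frac = 0.20, stringsAsFactors = FALSE),
                  causal_rare_n = 0L, causal_low_n = 0L)
  st <- simulate_study(cfg, seed = 32)
  ids <- st$ped$id
  y <- st$pheno$y[match(ids, st$pheno$id)]
  X <- model.matrix(~ age + sex, st$covariates)
  sc <- mga_scan(y, st$G, X, st$R_ped)
  causal <- st$arch$causal$snp[1]
  ok <- !is.na(sc$p)
  expect_identical(sc$snp[ok][which.min(sc$p[ok])], causal)
})

test_that("permuting SNP columns permutes scan results identically", {
  with(mga_fixture, {
    G10 <- subset_genotypes(st$G, snps = 1:10)
    sc1 <- mga_scan(y, G10, X, Phi2)
    perm <- c(4, 1, 9, 2, 10, 3, 7, 5, 8, 6)
    Dp <- G10$dosages[, perm]
    mapp <- data.frame(snp = colnames(Dp), chrom = 1L,
                       pos = seq_len(10L) * 100L)
    sc2 <- mga_scan(y, genotypes(Dp, mapp), X, Phi2)
    expect_equal(sc2$p, sc1$p[perm])
    expect_equal(sc2$beta, sc1$beta[perm])
  })
})

test_that("null model with E = 0-share reduces to the standard polygenic model", {
  with(mga_fixture, {
    f0 <- mga_null_fit(y, X, Phi2)
    # an E proportional to the identity is absorbed into the noise share:
    # the achievable covariance family is identical, so is the likelihood
    fE <- mga_null_fit(y, X, Phi2, E = diag(3.7, n))
    expect_equal(fE$null$loglik, f0$null$loglik, tolerance = 1e-5)
    # eps free but truth has none: likelihood cannot drop
    Epev <- egv_error_variance(Phi2, sigma_g2 = 50, sigma_e2 = 75)
    fP <- mga_null_fit(y, X, Phi2, E = Epev)
    expect_gte(fP$null$loglik, f0$null$loglik - 1e-6)
  })
})

test_that("pedigree-derived E shares eigenvectors: fast path equals dense path", {
  with(mga_fixture, {
    Epev <- egv_error_variance(Phi2, sigma_g2 = 50, sigma_e2 = 75)
    fFast <- mga_null_fit(y, X, Phi2, E = Epev)
    expect_false(fFast$dense)
    # force the dense route on the same inputs
    fDense <- fFast
    fDense$dense <- TRUE
    fDense$u <- NULL
    fDense$En <- Epev / mean(diag(Epev))
    dn <- egvkit:::.mga_fit(fDense[!names(fDense) %in% "null"],
                            fDense$yt, fDense$Xt, fDense$y, fDense$X)
    expect_equal(dn$loglik, fFast$null$loglik, tolerance = 1e-4)
    # a genuinely non-commuting E triggers the dense route and still works
    set.seed(33)
    Q <- crossprod(matrix(rnorm(n * n, sd = 0.3), n, n)) / n + diag(n)
    fNC <- mga_null_fit(y, X, Phi2, E = Q)
    expect_true(fNC$dense)
    expect_true(is.finite(fNC$null$loglik))
  })
})

test_that("LRT agrees with a dense-likelihood evaluation at the optimum", {
  with(mga_fixture, {
    g <- st$G$dosages[, which.max(maf(st$G))]
    null <- mga_null_fit(y, X, Phi2)
    t <- mga_test(g, null = null)
    # recompute alternative loglik densely at the fitted variance shares
    th <- t$theta_alt
    Xa <- cbind(X, snp = g)
    S <- th[1] * Phi2 + diag(th[2], n)
    Si <- solve(S)
    beta <- solve(t(Xa) %*% Si %*% Xa, t(Xa) %*% Si %*% y)
    r <- y - Xa %*% beta
    sp2 <- drop(t(r) %*% Si %*% r) / n
    ll_dense <- dense_mvn_loglik(y, drop(Xa %*% beta), sp2 * S)
    ll_alt <- null$null$loglik + t$lrt / 2
    expect_equal(ll_alt, ll_dense, tolerance = 1e-6)
  })
})

test_that("null statistics are calibrated: type-I error and inflation", {
  # independent SNPs (no LD) so the tests are effectively independent draws
  cfg <- tiny_cfg(n_families = 4L, target_n = 120L, m_snps = 250L,
                  n_chroms = 2L, ld_rho = 0, rare_frac = 0,
                  h2_polygenic = 0.3, n_replicates = 1L,
                  genes = data.frame(gene = "gA", chrom = 1L, n_snps = 2L,
                                     frac = 0, stringsAsFactors = FALSE),
                  causal_rare_n = 0L, causal_low_n = 1L)
  st <- simulate_study(cfg, seed = 34)
  ids <- st$ped$id
  y <- st$pheno$y[match(ids, st$pheno$id)]
  X <- model.matrix(~ age + sex, st$covariates)
  sc <- mga_scan(y, st$G, X, st$R_ped)
  ok <- !is.na(sc$p)
  m <- sum(ok)
  rate <- mean(sc$p[ok] < 0.05)
  ci <- qbinom(c(0.005, 0.995), m, 0.05) / m
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
  expect_gt(inflation_lambda(sc$lrt[ok]), 0.8)
  expect_lt(inflation_lambda(sc$lrt[ok]), 1.2)
})
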