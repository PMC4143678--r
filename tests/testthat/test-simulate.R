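test_that("pedigree generator hits the target size and is reproducible", {
  cfg <- sim_config(m_snps = 50L)
  ped <- simulate_pedigree(cfg, seed = 50)
  expect_equal(nrow(ped), 847L)
  expect_gte(nrow(ped), 762L); expect_lte(nrow(ped), 932L)
  expect_equal(length(unique(ped$fam)), 20L)
  ped2 <- simulate_pedigree(cfg, seed = 50)
  expect_identical(ped, ped2)
  expect_false(identical(ped, simulate_pedigree(cfg, seed = 51)))
  expect_error(sim_config(n_families = 0L), "infeasible")
})

test_that("founder haplotypes respect the causal MAF quota and marginals", {
  cfg <- tiny_cfg(n_families = 4L, target_n = 120L, m_snps = 400L)
  ped <- simulate_pedigree(cfg, seed = 52)
  fh <- simulate_founder_haplotypes(ped, cfg, seed = 52)
  expect_equal(sum(fh$causal$freq < 0.01), 1L)
  expect_equal(sum(fh$causal$freq >= 0.01 & fh$causal$freq < 0.05), 2L)
  # designed frequencies are the realised haplotype marginals (binomial SE)
  for (ch in 1:2) {
    p <- fh$freq[[ch]]
    common <- which(p > 0.1)
    emp <- colMeans(fh$haps[[ch]][, common, drop = FALSE])
    se <- sqrt(p[common] * (1 - p[common]) / nrow(fh$haps[[ch]]))
    expect_lt(mean(abs(emp - p[common]) / se), 2)  # avg within ~2 SE
  }
})

test_that("LD decays with rho and vanishes at rho = 0", {
  cfg0 <- tiny_cfg(n_families = 6L, target_n = 150L, m_snps = 500L,
                   n_chroms = 1L, ld_rho = 0, rare_frac = 0,
                   genes = data.frame(gene = "gA", chrom = 1L, n_snps = 3L,
                                      frac = 0.05),
                   causal_rare_n = 0L, causal_low_n = 1L)
  cfg9 <- tiny_cfg(n_families = 6L, target_n = 150L, m_snps = 500L,
                   n_chroms = 1L, ld_rho = 0.9, rare_frac = 0,
                   genes = data.frame(gene = "gA", chrom = 1L, n_snps = 3L,
                                      frac = 0.05),
                   causal_rare_n = 0L, causal_low_n = 1L)
  adj_r2 <- function(cfg, seed) {
    ped <- simulate_pedigree(cfg, seed)
    fh <- simulate_founder_haplotypes(ped, cfg, seed)
    H <- fh$haps[[1]]
    keep <- which(fh$freq[[1]] > 0.1)
    keep <- keep[keep + 1L %in% which(fh$freq[[1]] > 0.1)]
    list(r2 = mean(sapply(keep[1:min(300, length(keep))], function(k)
      suppressWarnings(cor(H[, k], H[, k + 1L]))^2), na.rm = TRUE),
      null = 1 / (nrow(H) - 1))
  }
  r2_0 <- adj_r2(cfg0, 53)
  r2_9 <- adj_r2(cfg9, 53)
  expect_lt(r2_0$r2, 2.5 * r2_0$null)  # independence at rho = 0
  expect_gt(r2_9$r2, 10 * r2_0$r2)     # strong adjacent LD at rho = 0.9
})

test_that("gene drop is Mendelian and no-recombination copies a haplotype", {
  cfg <- tiny_cfg(n_families = 3L, target_n = 60L, m_snps = 150L,
                  recomb_per_chrom = 0)
  st <- simulate_study(cfg, seed = 54)
  ped <- st$ped
  D <- st$G$dosages
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  for (i in which(!ped$founder)) {
    dk <- D[i, ]; df <- D[idx[ped$father[i]], ]; dm <- D[idx[ped$mother[i]], ]
    # impossible trios: child 0 with hom-alt parent, child 2 with hom-ref
    expect_equal(sum(dk == 0 & (df == 2 | dm == 2)), 0L)
    expect_equal(sum(dk == 2 & (df == 0 | dm == 0)), 0L)
  }
  # with recomb = 0 each transmitted chromosome matches one parental gamete:
  # child dosage minus one parental allele is a valid allele everywhere
  expect_true(all(D %in% 0:2))
})

test_that("realised relatedness of gene-dropped genomes matches expectation", {
  cfg <- tiny_cfg(n_families = 3L, target_n = 70L, m_snps = 2500L,
                  n_chroms = 2L, rare_frac = 0, ld_rho = 0)
  st <- simulate_study(cfg, seed = 55)
  Rk <- empirical_relatedness(st$G, "all", repair = FALSE)
  ped <- st$ped
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  po <- which(!ped$founder)
  expect_lt(abs(mean(Rk$M[cbind(idx[ped$father[po]], po)]) - 0.5), 0.02)
})

test_that("designed variance fractions are realised in the phenotype", {
  cfg <- tiny_cfg(n_families = 6L, target_n = 300L, m_snps = 150L,
                  n_replicates = 25L)
  st <- simulate_study(cfg, seed = 56)
  ids <- st$ped$id
  # direct construction check: the causal contribution has the designed variance
  for (g in c("gA", "gB")) {
    sel <- st$arch$causal$gene == g
    contrib <- drop(st$G$dosages[ids, st$arch$causal$snp[sel], drop = FALSE] %*%
                      st$arch$causal$effect[sel])
    expect_equal(var(contrib) / st$cfg$var_total,
                 st$cfg$genes$frac[st$cfg$genes$gene == g], tolerance = 1e-6)
  }
  # and the regression-based estimator recovers it from the phenotype
  sh <- gene_variance_share(st, "gA", replicates = 1:25)
  expect_lt(abs(sh$share - 0.08), 0.012)
  # total realised heritability close to design: causal + polygenic
  h2_design <- sum(st$cfg$genes$frac) + st$cfg$h2_polygenic
  vr <- sapply(1:25, function(r) {
    pr <- st$pheno[st$pheno$replicate == r, ]
    y <- pr$y[match(ids, pr$id)]
    var(st$g_true[ids, r]) / var(y)
  })
  expect_lt(abs(mean(vr) - h2_design), 0.03)
})

test_that("null architecture gives near-zero fitted heritability", {
  cfg <- tiny_cfg(n_families = 5L, target_n = 200L, m_snps = 80L,
                  h2_polygenic = 0, n_replicates = 5L,
                  genes = data.frame(gene = "gA", chrom = 1L, n_snps = 2L,
                                     frac = 0),
                  causal_rare_n = 0L, causal_low_n = 1L)
  st <- simulate_study(cfg, seed = 57)
  ids <- st$ped$id
  X <- model.matrix(~ age + sex, st$covariates)
  eig <- eigen(st$R_ped$M, symmetric = TRUE)
  h2 <- sapply(1:5, function(r) {
    pr <- st$pheno[st$pheno$replicate == r, ]
    polygenic_fit(pr$y[match(ids, pr$id)], X, eig = eig)$h2
  })
  expect_lt(mean(h2), 0.06)
})

test_that("the whole study is reproducible from the master seed", {
  cfg <- tiny_cfg()
  s1 <- simulate_study(cfg, seed = 58)
  s2 <- simulate_study(cfg, seed = 58)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$G$dosages, s2$G$dosages)
  expect_identical(s1$arch$causal, s2$arch$causal)
  # substreams: regenerating a single stage reproduces it in isolation
  fh <- simulate_founder_haplotypes(s1$ped, cfg, seed = 58)
  expect_identical(fh$haps, s1$fh$haps)
})
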