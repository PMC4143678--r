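# constructed-LD fixture: causal SNP plus proxies at controlled r2
ld_fixture <- local({
  set.seed(40)
  n <- 400L
  causal <- rbinom(n, 2, 0.4)
  mk_proxy <- function(target_r2) {
    # swap genotypes at random positions until the correlation decays
    g <- causal
    repeat {
      if (cor(g, causal)^2 <= target_r2) break
      i <- sample(n, 8)
      g[i] <- rbinom(8, 2, 0.4)
    }
    g
  }
  strong <- mk_proxy(0.40)   # lands just under 0.40, well above 0.2
  weak <- mk_proxy(0.08)     # well below 0.2
  other_chr <- rbinom(n, 2, 0.4)
  D <- cbind(causal = causal, strong = strong, weak = weak,
             far = rbinom(n, 2, 0.3), other = other_chr)
  rownames(D) <- paste0("i", 1:n)
  map <- data.frame(snp = colnames(D), chrom = c(1L, 1L, 1L, 1L, 2L),
                    pos = c(100L, 200L, 300L, 40000L, 100L))
  G <- genotypes(D, map)
  arch <- causal_architecture(
    genes = data.frame(gene = "gA", chrom = 1L, n_snps = 1L, frac = 0.05),
    causal = data.frame(snp = "causal", gene = "gA", chrom = 1L, pos = 100L,
                        freq = 0.4, effect = 1),
    h2_polygenic = 0.2)
  list(G = G, arch = arch)
})

test_that("pairwise r2: identical, complemented and degenerate columns", {
  g <- c(0, 1, 2, 1, 0, 2, 1)
  expect_equal(pairwise_r2(g, g), 1.0)
  expect_equal(pairwise_r2(g, 2 - g), 1.0)  # sign-invariance
  expect_error(pairwise_r2(g, rep(1, 7)), "zero genotypic variance")
})

test_that("independent SNPs have null-level mean r2", {
  set.seed(41)
  n <- 850L
  r2s <- replicate(1000, pairwise_r2(rbinom(n, 2, runif(1, 0.2, 0.5)),
                                     rbinom(n, 2, runif(1, 0.2, 0.5))))
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 3 * sd(r2s) / sqrt(1000) + 2e-4)
})

test_that("hits are adjudicated by the LD-block rule", {
  with(ld_fixture, {
    lab <- classify_hits(c("causal", "strong", "weak", "other"), arch, G)
    expect_equal(lab$label, c("TP", "TP", "FP", "FP"))
    expect_equal(lab$best_gene[1], "gA")
    expect_equal(lab$best_r2[1], 1.0)     # a causal SNP vouches for itself
    # different chromosome can never be a true positive
    expect_identical(lab$label[lab$snp == "other"], "FP")
    expect_error(classify_hits("nope", arch, G), "absent")
  })
})

test_that("raising the r2 threshold never increases the TP count", {
  with(ld_fixture, {
    hits <- c("causal", "strong", "weak", "far")
    tps <- sapply(c(0.05, 0.2, 0.5, 0.9), function(thr)
      sum(classify_hits(hits, arch, G, r2_block = thr)$label == "TP"))
    expect_true(all(diff(tps) <= 0))
    # conservation at every threshold
    for (thr in c(0.05, 0.2, 0.9)) {
      lab <- classify_hits(hits, arch, G, r2_block = thr)
      expect_equal(sum(lab$label == "TP") + sum(lab$label == "FP"),
                   length(hits))
    }
  })
})

test_that("FDR summary arithmetic is exact on planted counts", {
  # 12 TPs + 1 FP pooled for methodA; 3 TPs 0 FP for methodB
  hA <- data.frame(replicate = c(rep(1, 6), rep(2, 7)),
                   snp = paste0("s", 1:13),
                   label = c(rep("TP", 12), "FP"),
                   stringsAsFactors = FALSE)
  hB <- data.frame(replicate = c(1, 1, 2), snp = paste0("s", c(1, 2, 20)),
                   label = rep("TP", 3), stringsAsFactors = FALSE)
  mafs <- setNames(c(runif(13, 0.1, 0.4), 0.004), paste0("s", c(1:13, 20)))
  tab <- fdr_summary(list(ref = hA, alt = hB), mafs, n_replicates = 2,
                     reference = "ref")
  expect_equal(tab["FDR", "ref"], 100 * 1 / 13, tolerance = 1e-12)
  expect_equal(tab["Total significant SNPs", "ref"], 13)
  expect_equal(tab["FDR", "alt"], 0)
  expect_equal(tab["Mean sig SNPs per replicate", "ref"], 6.5)
  expect_equal(tab["Median sig SNPs per replicate", "ref"], 6.5)
  expect_equal(tab["Sig SNPs with MAF < 0.01", "alt"], 100 / 3,
               tolerance = 1e-12)
  # conditional FDR counts only the one hit unseen in the reference
  expect_equal(tab["FDR for SNPs not seen in reference", "alt"], 0)
  expect_equal(tab["Replicates with fewer SNPs than reference", "alt"], 2)
  # zero significant hits: FDR not applicable, reported as NA
  h0 <- hA[0, ]
  tab0 <- fdr_summary(list(ref = h0), mafs, n_replicates = 2)
  expect_true(is.na(tab0["FDR", "ref"]))
})

test_that("gene hit table counts replicates with at least one attributed hit", {
  arch <- causal_architecture(
    genes = data.frame(gene = c("big", "small"), chrom = c(1L, 2L),
                       n_snps = c(1L, 1L), frac = c(0.08, 0.01)),
    causal = data.frame(snp = c("a", "b"), gene = c("big", "small"),
                        chrom = c(1L, 2L), pos = c(1L, 1L), freq = 0.3,
                        effect = 1),
    h2_polygenic = 0.2)
  # method finds `big` in 7 of 10 replicates, `small` never
  h <- data.frame(replicate = rep(1:7, each = 2),
                  snp = rep(c("a", "x"), 7),
                  label = rep(c("TP", "FP"), 7),
                  genes = rep(c("big", NA), 7), stringsAsFactors = FALSE)
  tab <- gene_hit_table(list(m1 = h), arch)
  expect_equal(tab$m1[tab$gene == "big"], 7L)
  expect_equal(tab$m1[tab$gene == "small"], 0L)
  # saturation: found in every replicate
  hs <- data.frame(replicate = 1:10, snp = "a", label = "TP", genes = "big")
  expect_equal(gene_hit_table(list(m = hs), arch)$m[1], 10L)
  # multi-gene attribution counts for each gene it clears
  hm <- data.frame(replicate = 1, snp = "a", label = "TP",
                   genes = "big;small")
  tabm <- gene_hit_table(list(m = hm), arch)
  expect_equal(tabm$m, c(1L, 1L))
})

test_that("pure-noise scan yields only false positives", {
  with(ld_fixture, {
    # pretend two null SNPs reached significance
    lab <- classify_hits(c("far", "other"), arch, G, r2_block = 0.2)
    expect_true(all(lab$label == "FP"))
    h <- data.frame(replicate = 1, snp = lab$snp, label = lab$label)
    tab <- fdr_summary(list(m = h), setNames(c(0.3, 0.4), lab$snp), 1)
    expect_equal(tab["FDR", "m"], 100)
  })
})
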