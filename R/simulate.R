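#' Simulation configuration
#'
#' Study-design parameters for the synthetic pedigree/genotype/phenotype
#' generator. Defaults emulate a GAW-style family study: 20 extended families
#' totalling 847 individuals over 4 generations, replicate blood-pressure
#' phenotypes (mm Hg) over fixed genotypes and covariates, and a multi-gene
#' causal architecture in which the four causal genes carry 15, 14, 16 and 8
#' SNPs explaining 7.79%, 4.67%, 3.87% and 2.06% of total phenotypic
#' variance, with 10 of the 53 causal sites designed at MAF below 1% and a
#' further 18 between 1% and 5%.
#'
#' @param n_families Number of extended families (default 20).
#' @param target_n Total pedigree size (default 847); sibship draws are
#'   trimmed/extended at the youngest generation to hit it exactly.
#' @param generations Generations per family (default 4).
#' @param sibship_lambda Sibship sizes are 1 + Poisson(lambda) (default 1.8).
#' @param n_chroms Number of chromosomes (default 4).
#' @param m_snps SNPs per chromosome (default 500).
#' @param rare_frac Fraction of non-causal sites drawn from the rare
#'   frequency component U(0.001, 0.01) (default 0.2); the rest are common,
#'   U(0.05, 0.5).
#' @param ld_rho Latent AR(1) correlation generating monotone LD decay along
#'   each chromosome, in `[0, 1)` (default 0.7; 0 gives independent sites).
#' @param recomb_per_chrom Expected crossovers per meiosis per chromosome
#'   (default 1).
#' @param genes Data frame (`gene`, `chrom`, `n_snps`, `frac`) of causal
#'   genes and their designed variance fractions of total phenotypic
#'   variance.
#' @param causal_rare_n,causal_low_n Causal-site MAF quota: number designed
#'   below 1% and number between 1% and 5% (defaults 10 and 18 of 53).
#' @param h2_polygenic Background polygenic heritability (default 0.2).
#' @param covariate_frac Variance share of the age/sex covariate signal
#'   (default 0.1).
#' @param var_total Designed total phenotypic variance (default 400, i.e.
#'   sd 20 mm Hg).
#' @param mu Phenotype mean (default 120 mm Hg).
#' @param n_replicates Phenotype replicates over fixed genotypes/covariates
#'   (default 100).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_families = 20L, target_n = 847L, generations = 4L,
                       sibship_lambda = 1.8, n_chroms = 4L, m_snps = 500L,
                       rare_frac = 0.2, ld_rho = 0.7, recomb_per_chrom = 1,
                       genes = data.frame(
                         gene = c("geneA", "geneB", "geneC", "geneD"),
                         chrom = c(3L, 2L, 4L, 1L),
                         n_snps = c(15L, 14L, 16L, 8L),
                         frac = c(0.0779, 0.0467, 0.0387, 0.0206),
                         stringsAsFactors = FALSE),
                       causal_rare_n = 10L, causal_low_n = 18L,
                       h2_polygenic = 0.2, covariate_frac = 0.1,
                       var_total = 400, mu = 120, n_replicates = 100L) {
  cfg <- list(n_families = n_families, target_n = target_n,
              generations = generations, sibship_lambda = sibship_lambda,
              n_chroms = n_chroms, m_snps = m_snps, rare_frac = rare_frac,
              ld_rho = ld_rho, recomb_per_chrom = recomb_per_chrom,
              genes = genes, causal_rare_n = causal_rare_n,
              causal_low_n = causal_low_n, h2_polygenic = h2_polygenic,
              covariate_frac = covariate_frac, var_total = var_total,
              mu = mu, n_replicates = n_replicates)
  if (n_families < 1L) stop("infeasible config: need at least 1 family")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (sum(genes$frac) + h2_polygenic + covariate_frac >= 1)
    stop("infeasible variance budget: fractions sum to >= 1")
  if (any(genes$chrom > n_chroms)) stop("causal gene placed beyond n_chroms")
  if (any(genes$n_snps >= m_snps)) stop("gene larger than its chromosome")
  if (n_replicates < 1L) stop("need at least one replicate")
  class(cfg) <- "sim_config"
  cfg
}

# Named RNG substream seed derived from the master seed; keeps every stage
# independently re-runnable. Result is a valid 32-bit seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Simulate extended-family pedigrees
#'
#' Builds `n_families` families: a founder couple, sibships of size
#' 1 + Poisson(lambda) per couple, with each child of a non-final generation
#' marrying in a new founder spouse (sexes alternate within sibships). After
#' the random draw, youngest-generation leaves are added or removed
#' deterministically so the total equals `target_n`.
#'
#' @param cfg A [sim_config].
#' @param seed Integer seed.
#' @return A [pedigree] with an extra `generation` column.
#' @export
simulate_pedigree <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(seed, "pedigree"))
  rows <- list()
  add <- function(fam, id, fa, mo, sex, gen) {
    rows[[length(rows) + 1L]] <<- data.frame(
      fam = fam, id = id, father = fa, mother = mo, sex = sex,
      generation = gen, stringsAsFactors = FALSE)
  }
  final_couples <- list()  # parents able to take extra youngest-gen children
  for (f in seq_len(cfg$n_families)) {
    fam <- sprintf("F%02d", f)
    nid <- 0L
    newid <- function() { nid <<- nid + 1L; sprintf("%s_I%03d", fam, nid) }
    dad <- newid(); mom <- newid()
    add(fam, dad, "0", "0", 1L, 1L)
    add(fam, mom, "0", "0", 2L, 1L)
    couples <- list(c(dad, mom))
    for (g in 2:cfg$generations) {
      nxt <- list()
      for (cp in couples) {
        s <- 1L + stats::rpois(1L, cfg$sibship_lambda)
        for (j in seq_len(s)) {
          sex <- if (j %% 2L == 1L) 1L else 2L
          child <- newid()
          add(fam, child, cp[1], cp[2], sex, g)
          if (g < cfg$generations) {
            spouse <- newid()
            add(fam, spouse, "0", "0", if (sex == 1L) 2L else 1L, g)
            nxt[[length(nxt) + 1L]] <- if (sex == 1L) c(child, spouse) else c(spouse, child)
          }
        }
        if (g == cfg$generations)
          final_couples[[length(final_couples) + 1L]] <-
            list(fam = fam, couple = cp, gen = g)
      }
      couples <- nxt
    }
  }
  df <- do.call(rbind, rows)
  # deterministic size adjustment at the youngest generation
  excess <- nrow(df) - cfg$target_n
  if (excess > 0L) {
    leaves <- which(df$generation == cfg$generations)
    drop <- leaves[seq(length(leaves), length.out = excess, by = -1L)]
    df <- df[-drop, , drop = FALSE]
  } else if (excess < 0L) {
    need <- -excess
    extra <- list()
    ci <- 0L
    counters <- stats::setNames(rep(0L, cfg$n_families),
                                sprintf("F%02d", seq_len(cfg$n_families)))
    for (k in seq_len(need)) {
      ci <- ci %% length(final_couples) + 1L
      fc <- final_couples[[ci]]
      counters[fc$fam] <- counters[fc$fam] + 1L
      extra[[k]] <- data.frame(
        fam = fc$fam, id = sprintf("%s_X%03d", fc$fam, counters[fc$fam]),
        father = fc$couple[1], mother = fc$couple[2],
        sex = if (k %% 2L == 1L) 1L else 2L,
        generation = cfg$generations, stringsAsFactors = FALSE)
    }
    df <- rbind(df, do.call(rbind, extra))
  }
  ped <- pedigree(df$fam, df$id, df$father, df$mother, df$sex)
  gen <- stats::setNames(df$generation, df$id)
  ped$generation <- unname(gen[ped$id])
  ped
}

#' Simulate founder haplotypes with LD structure
#'
#' Draws per-site allele frequencies from a two-component spectrum (common
#' U(0.05, 0.5); rare U(0.001, 0.01)) and generates founder haplotypes from a
#' latent Gaussian AR(1) process thresholded at the frequency quantile:
#' marginal frequencies are exact (so the causal-site MAF quota holds) and
#' adjacent-site LD decays monotonically with distance, vanishing at
#' `ld_rho = 0`. Causal genes occupy contiguous blocks centred on their
#' chromosomes; causal-site frequencies follow the configured rare/low/common
#' quota (allocation over sites is a seeded permutation).
#'
#' @param ped A [pedigree] (its founders receive haplotypes).
#' @param cfg A [sim_config].
#' @param seed Integer seed.
#' @return List: `haps` (per chromosome, a 2*n_founders x m 0/1 matrix),
#'   `freq` (per chromosome), `map` (snp, chrom, pos), `causal` (snp, gene,
#'   chrom, pos, freq, index), `founder_ids`.
#' @export
simulate_founder_haplotypes <- function(ped, cfg, seed) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  set.seed(substream_seed(seed, "haplotypes"))
  founders <- ped$id[ped$founder]
  n_hap <- 2L * length(founders)
  m <- cfg$m_snps
  # causal slots and their frequency categories
  genes <- cfg$genes
  slots <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    start <- (m - genes$n_snps[i]) %/% 2L
    data.frame(gene = genes$gene[i], chrom = genes$chrom[i],
               index = start + seq_len(genes$n_snps[i]),
               stringsAsFactors = FALSE)
  }))
  ncausal <- nrow(slots)
  if (cfg$causal_rare_n + cfg$causal_low_n > ncausal)
    stop("causal MAF quota exceeds number of causal sites")
  cats <- c(rep("rare", cfg$causal_rare_n), rep("low", cfg$causal_low_n),
            rep("common", ncausal - cfg$causal_rare_n - cfg$causal_low_n))
  slots$cat <- sample(cats)
  slots$freq <- ifelse(slots$cat == "rare", stats::runif(ncausal, 0.001, 0.01),
                ifelse(slots$cat == "low", stats::runif(ncausal, 0.01, 0.05),
                       stats::runif(ncausal, 0.05, 0.5)))
  haps <- freq <- vector("list", cfg$n_chroms)
  maps <- vector("list", cfg$n_chroms)
  for (ch in seq_len(cfg$n_chroms)) {
    p <- ifelse(stats::runif(m) < cfg$rare_frac,
                stats::runif(m, 0.001, 0.01), stats::runif(m, 0.05, 0.5))
    sl <- slots[slots$chrom == ch, , drop = FALSE]
    p[sl$index] <- sl$freq
    Z <- matrix(NA_real_, n_hap, m)
    Z[, 1] <- stats::rnorm(n_hap)
    if (m > 1L) {
      rho <- cfg$ld_rho
      sdres <- sqrt(1 - rho^2)
      for (k in 2:m) Z[, k] <- rho * Z[, k - 1] + sdres * stats::rnorm(n_hap)
    }
    A <- matrix(0L, n_hap, m)
    A[Z < rep(stats::qnorm(p), each = n_hap)] <- 1L
    haps[[ch]] <- A
    freq[[ch]] <- p
    maps[[ch]] <- data.frame(snp = sprintf("c%d_s%04d", ch, seq_len(m)),
                             chrom = ch, pos = seq_len(m) * 1000L,
                             stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, maps)
  slots$snp <- sprintf("c%d_s%04d", slots$chrom, slots$index)
  slots$pos <- slots$index * 1000L
  list(haps = haps, freq = freq, map = map,
       causal = slots[, c("snp", "gene", "chrom", "pos", "freq", "index", "cat")],
       founder_ids = founders)
}

#' Gene-drop Mendelian transmission through a pedigree
#'
#' Each meiosis transmits a recombined parental haplotype: crossover count
#' Poisson(`recomb_per_chrom`), breakpoints uniform along the chromosome,
#' starting haplotype fair-coin. Dosage is the sum of the two inherited
#' alleles.
#'
#' @param ped A [pedigree].
#' @param fh Founder haplotypes from [simulate_founder_haplotypes].
#' @param cfg A [sim_config].
#' @param seed Integer seed.
#' @return A [genotypes] object for every pedigree member.
#' @export
gene_drop <- function(ped, fh, cfg, seed) {
  stopifnot(inherits(ped, "pedigree"))
  set.seed(substream_seed(seed, "genedrop"))
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  founder_row <- match(ped$id, fh$founder_ids)  # NA for non-founders
  blocks <- vector("list", cfg$n_chroms)
  meiosis <- function(h1, h2, m) {
    k <- stats::rpois(1L, cfg$recomb_per_chrom)
    src <- stats::rbinom(1L, 1L, 0.5)
    if (k == 0L) return(if (src == 0L) h1 else h2)
    bp <- sort(unique(ceiling(stats::runif(k) * (m - 1L))))
    out <- h1
    use2 <- src == 1L
    prev <- 1L
    for (b in c(bp, m)) {
      if (use2) out[prev:b] <- h2[prev:b]
      use2 <- !use2
      prev <- b + 1L
    }
    out
  }
  for (ch in seq_len(cfg$n_chroms)) {
    m <- ncol(fh$haps[[ch]])
    H <- matrix(0L, 2L * n, m)
    for (i in seq_len(n)) {
      if (ped$founder[i]) {
        fr <- founder_row[i]
        H[2L * i - 1L, ] <- fh$haps[[ch]][2L * fr - 1L, ]
        H[2L * i, ] <- fh$haps[[ch]][2L * fr, ]
      } else {
        fa <- idx[ped$father[i]]; mo <- idx[ped$mother[i]]
        H[2L * i - 1L, ] <- meiosis(H[2L * fa - 1L, ], H[2L * fa, ], m)
        H[2L * i, ] <- meiosis(H[2L * mo - 1L, ], H[2L * mo, ], m)
      }
    }
    blocks[[ch]] <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  }
  D <- do.call(cbind, blocks)
  rownames(D) <- ped$id
  colnames(D) <- fh$map$snp
  genotypes(D, fh$map)
}

#' Simulate replicate phenotypes with a known causal architecture
#'
#' Builds y = mu + covariates + causal-gene effects + polygenic + noise.
#' Per-SNP causal effects within a gene are drawn once (standard-normal
#' weights scaled by 1/sqrt(2p(1-p))) and then rescaled so the gene's
#' realised in-sample variance contribution equals its designed fraction of
#' `var_total` — calibration against the realised dosage covariance keeps the
#' designed fractions exact under LD among a gene's SNPs. Covariate effects
#' are similarly scaled to `covariate_frac`. The polygenic deviate is drawn
#' per replicate from N(0, h2_polygenic * var_total * 2*Phi), the noise
#' independently; genotypes, covariates and effect sizes stay fixed across
#' replicates.
#'
#' @param ped A [pedigree] with a `generation` column (see
#'   [simulate_pedigree]).
#' @param G A [genotypes] object from [gene_drop].
#' @param fh Founder-haplotype stage output (supplies the causal map).
#' @param cfg A [sim_config].
#' @param seed Integer seed.
#' @param R_ped Optional precomputed expected [relatedness]; computed from
#'   `ped` when missing.
#' @return List: `pheno` (long data frame id/replicate/y), `covariates`
#'   (id, age, sex), `arch` (a [causal_architecture] with fitted effects),
#'   `g_true` (n x n_replicates matrix of true genetic values = causal +
#'   polygenic), `components` (named variance shares used).
#' @export
simulate_phenotypes <- function(ped, G, fh, cfg, seed, R_ped = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(G, "genotypes"))
  set.seed(substream_seed(seed, "phenotypes"))
  n <- nrow(ped)
  ids <- ped$id
  # covariates: age uniform within generation bands (oldest generation first)
  breaks <- seq(80, 20, length.out = cfg$generations + 1L)
  gen <- ped$generation
  age <- stats::runif(n, breaks[gen + 1L], breaks[gen])
  sex <- as.integer(ped$sex == 2L)
  base_cov <- 0.3 * (age - mean(age)) - 1 * (sex - mean(sex))
  vb <- stats::var(base_cov)
  cov_scale <- if (vb > 0) sqrt(cfg$covariate_frac * cfg$var_total / vb) else 0
  cov_sig <- cov_scale * base_cov
  # causal effects calibrated to realised dosage covariance
  causal <- fh$causal
  causal$effect <- NA_real_
  contrib <- numeric(n)
  for (i in seq_len(nrow(cfg$genes))) {
    gname <- cfg$genes$gene[i]
    frac <- cfg$genes$frac[i]
    snps <- causal$snp[causal$gene == gname]
    Gc <- G$dosages[ids, snps, drop = FALSE]
    p <- causal$freq[causal$gene == gname]
    a0 <- stats::rnorm(length(snps)) / sqrt(2 * p * (1 - p))
    raw <- drop(Gc %*% a0)
    v0 <- stats::var(raw)
    if (frac > 0 && v0 <= 0)
      stop("infeasible variance budget: gene ", gname,
           " has no realised genotypic variance")
    sc <- if (frac > 0) sqrt(frac * cfg$var_total / v0) else 0
    causal$effect[causal$gene == gname] <- a0 * sc
    contrib <- contrib + raw * sc
  }
  contrib <- contrib - mean(contrib)
  sigma_poly2 <- cfg$h2_polygenic * cfg$var_total
  sigma_e2 <- cfg$var_total *
    (1 - sum(cfg$genes$frac) - cfg$h2_polygenic - cfg$covariate_frac)
  if (sigma_e2 <= 0) stop("infeasible variance budget: no residual variance left")
  if (is.null(R_ped)) R_ped <- expected_relatedness(ped)
  C <- chol(R_ped$M[ids, ids] + diag(1e-10, n))
  reps <- cfg$n_replicates
  Y <- matrix(NA_real_, n, reps)
  g_true <- matrix(NA_real_, n, reps, dimnames = list(ids, NULL))
  for (r in seq_len(reps)) {
    set.seed(substream_seed(seed, paste0("replicate", r)))
    gp <- sqrt(sigma_poly2) * drop(t(C) %*% stats::rnorm(n))
    e <- stats::rnorm(n, sd = sqrt(sigma_e2))
    g_true[, r] <- contrib + gp
    Y[, r] <- cfg$mu + cov_sig + contrib + gp + e
  }
  pheno <- data.frame(id = rep(ids, reps),
                      replicate = rep(seq_len(reps), each = n),
                      y = as.vector(Y), stringsAsFactors = FALSE)
  covariates <- data.frame(id = ids, age = age, sex = sex,
                           stringsAsFactors = FALSE)
  arch <- causal_architecture(cfg$genes,
                              causal[, c("snp", "gene", "chrom", "pos",
                                         "freq", "effect")],
                              cfg$h2_polygenic)
  list(pheno = pheno, covariates = covariates, arch = arch, g_true = g_true,
       components = c(causal = sum(cfg$genes$frac),
                      polygenic = cfg$h2_polygenic,
                      covariates = cfg$covariate_frac,
                      noise = sigma_e2 / cfg$var_total))
}

#' Simulate a complete family study
#'
#' Chains [simulate_pedigree], [simulate_founder_haplotypes], [gene_drop] and
#' [simulate_phenotypes] under named substreams of one master seed, so each
#' stage is independently reproducible.
#'
#' @param cfg A [sim_config].
#' @param seed Master integer seed.
#' @return List of class `"egv_study"`: `ped`, `G`, `fh`, `pheno`,
#'   `covariates`, `arch`, `g_true`, `R_ped`, `components`, `cfg`, `seed`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1L) {
  ped <- simulate_pedigree(cfg, seed)
  fh <- simulate_founder_haplotypes(ped, cfg, seed)
  G <- gene_drop(ped, fh, cfg, seed)
  R_ped <- expected_relatedness(ped)
  ph <- simulate_phenotypes(ped, G, fh, cfg, seed, R_ped = R_ped)
  structure(list(ped = ped, G = G, fh = fh, pheno = ph$pheno,
                 covariates = ph$covariates, arch = ph$arch,
                 g_true = ph$g_true, R_ped = R_ped,
                 components = ph$components, cfg = cfg, seed = seed),
            class = "egv_study")
}

#' @export
print.egv_study <- function(x, ...) {
  cat("Synthetic family study: ", nrow(x$ped), " individuals / ",
      length(unique(x$ped$fam)), " families; ", ncol(x$G$dosages),
      " SNPs on ", x$cfg$n_chroms, " chromosomes; ",
      x$cfg$n_replicates, " phenotype replicates (seed ", x$seed, ")\n",
      sep = "")
  print(x$arch)
  invisible(x)
}
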