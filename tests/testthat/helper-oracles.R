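# Fixtures and independent oracles shared across the suite.

# --- small pedigrees ------------------------------------------------------

ped_trio <- function() {
  pedigree(fam = rep("F1", 3), id = c("dad", "mom", "kid"),
           father = c("0", "0", "dad"), mother = c("0", "0", "mom"),
           sex = c(1, 2, 1))
}

ped_sibs <- function() {
  pedigree(fam = rep("F1", 4), id = c("dad", "mom", "s1", "s2"),
           father = c("0", "0", "dad", "dad"),
           mother = c("0", "0", "mom", "mom"), sex = c(1, 2, 1, 2))
}

ped_halfsibs <- function() {
  pedigree(fam = rep("F1", 5), id = c("dad", "m1", "m2", "h1", "h2"),
           father = c("0", "0", "0", "dad", "dad"),
           mother = c("0", "0", "0", "m1", "m2"), sex = c(1, 2, 2, 1, 2))
}

# offspring of a full-sib mating: F = 1/4
ped_inbred <- function() {
  pedigree(fam = rep("F1", 5), id = c("gp1", "gp2", "s1", "s2", "kid"),
           father = c("0", "0", "gp1", "gp1", "s1"),
           mother = c("0", "0", "gp2", "gp2", "s2"), sex = c(1, 2, 1, 2, 1))
}

# four generations, 12 members, includes an inbred loop via first cousins
ped_4gen <- function() {
  pedigree(
    fam = rep("F1", 12),
    id = c("a1", "a2", "b1", "b2", "b3", "b4", "c1", "c2", "c3", "c4", "d1", "d2"),
    father = c("0", "0", "a1", "0", "a1", "0", "b1", "b3", "b1", "b3", "c1", "c3"),
    mother = c("0", "0", "a2", "0", "a2", "0", "b2", "b4", "b2", "b4", "c2", "c4"),
    sex = c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 1, 2))
}

# --- gene-drop single-locus kinship oracle --------------------------------

# Monte-Carlo IBD: drop uniquely labelled founder alleles through the
# pedigree `ndrops` times; phi-hat(i,j) = mean over drops and the four
# allele pairings of the IBD indicator.
genedrop_kinship_mc <- function(ped, ndrops = 200000L, seed = 42L) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  A1 <- matrix(0L, n, ndrops)
  A2 <- matrix(0L, n, ndrops)
  lab <- 0L
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      A1[i, ] <- lab + 1L
      A2[i, ] <- lab + 2L
      lab <- lab + 2L
    } else {
      fa <- idx[ped$father[i]]; mo <- idx[ped$mother[i]]
      pick <- stats::runif(ndrops) < 0.5
      A1[i, ] <- ifelse(pick, A1[fa, ], A2[fa, ])
      pick <- stats::runif(ndrops) < 0.5
      A2[i, ] <- ifelse(pick, A1[mo, ], A2[mo, ])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
        (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])
      phi[i, j] <- phi[j, i] <- mean(ibd) / 4
    }
  }
  phi
}

# --- dense likelihood and BLUP oracles ------------------------------------

# Direct dense multivariate-normal log-density for y ~ N(X beta, Sigma),
# independent of the spectral-trick code path.
dense_mvn_loglik <- function(y, mean, Sigma) {
  n <- length(y)
  ch <- chol(Sigma)
  z <- backsolve(ch, y - mean, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# ML fit by brute force: profile beta/sigma_p2 on a fine h2 grid with dense
# covariance algebra only.
dense_ml_fit <- function(y, X, K, grid = seq(0, 1, by = 0.001)) {
  n <- length(y)
  best <- list(ll = -Inf)
  for (h2 in grid) {
    S <- h2 * K + (1 - h2) * diag(n)
    Si <- solve(S)
    XtSiX <- t(X) %*% Si %*% X
    beta <- solve(XtSiX, t(X) %*% Si %*% y)
    r <- y - X %*% beta
    sp2 <- drop(t(r) %*% Si %*% r) / n
    ll <- dense_mvn_loglik(y, drop(X %*% beta), sp2 * S)
    if (ll > best$ll) best <- list(ll = ll, h2 = h2, beta = drop(beta), sp2 = sp2)
  }
  best
}

# Henderson mixed-model equations for the no-fixed-effect model: the
# random-effect solution solves (I + lambda R^-1) g = y, and the
# prediction-error variance is sigma_e2 (I + lambda R^-1)^-1. Solved with
# explicit inverses, unlike the package's factorised path.
mme_blup_oracle <- function(resid, R, sigma_g2, sigma_e2) {
  lambda <- sigma_e2 / sigma_g2
  Cinv <- unname(solve(diag(nrow(R)) + lambda * solve(R)))
  list(g = unname(drop(Cinv %*% resid)), pev = sigma_e2 * Cinv)
}

# --- nearest-correlation brute-force oracle -------------------------------

# Any 3x3 correlation matrix is LL' with unit-norm lower-triangular L
# parameterised by three angles; minimise the Frobenius distance directly.
nearcor3_bruteforce <- function(A) {
  obj <- function(th) {
    L <- rbind(c(1, 0, 0),
               c(cos(th[1]), sin(th[1]), 0),
               c(cos(th[2]), sin(th[2]) * cos(th[3]), sin(th[2]) * sin(th[3])))
    sum((L %*% t(L) - A)^2)
  }
  best <- list(value = Inf)
  for (s in list(c(0.5, 0.5, 0.5), c(1, 2, 1), c(2, 1, 2), c(0.1, 0.1, 3))) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    if (o$value < best$value) best <- o
  }
  th <- best$par
  L <- rbind(c(1, 0, 0),
             c(cos(th[1]), sin(th[1]), 0),
             c(cos(th[2]), sin(th[2]) * cos(th[3]), sin(th[2]) * sin(th[3])))
  L %*% t(L)
}

# --- small synthetic-study shortcut ---------------------------------------

tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_families = 2L, target_n = 40L, generations = 3L,
                   m_snps = 60L, n_chroms = 2L, n_replicates = 3L,
                   genes = data.frame(gene = c("gA", "gB"), chrom = c(1L, 2L),
                                      n_snps = c(4L, 3L),
                                      frac = c(0.08, 0.02),
                                      stringsAsFactors = FALSE),
                   causal_rare_n = 1L, causal_low_n = 2L)
  defaults[names(args)] <- args  # plain replacement; never merge data frames
  do.call(sim_config, defaults)
}
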