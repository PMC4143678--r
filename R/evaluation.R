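#' Pairwise r-squared between two SNPs
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' observations — the composite-LD measure used for true/false-positive
#' adjudication.
#'
#' @param g_a,g_b Dosage vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
pairwise_r2 <- function(g_a, g_b) {
  ok <- !is.na(g_a) & !is.na(g_b)
  a <- g_a[ok]; b <- g_b[ok]
  if (length(a) < 2L || stats::var(a) == 0 || stats::var(b) == 0)
    stop("r-squared undefined: zero genotypic variance")
  stats::cor(a, b)^2
}

#' Causal architecture container
#'
#' Ground truth for power/FDR evaluation: the causal genes, their SNPs and
#' designed variance fractions.
#'
#' @param genes Data frame with columns `gene`, `chrom`, `n_snps`, `frac`
#'   (designed fraction of total phenotypic variance).
#' @param causal Data frame with columns `snp`, `gene`, `chrom`, `pos`,
#'   `freq` (designed allele frequency), `effect`.
#' @param h2_polygenic Designed background polygenic heritability.
#' @return Object of class `"causal_architecture"`.
#' @export
causal_architecture <- function(genes, causal, h2_polygenic) {
  stopifnot(all(c("gene", "chrom", "n_snps", "frac") %in% names(genes)),
            all(c("snp", "gene", "chrom") %in% names(causal)))
  if (any(genes$frac < 0)) stop("variance fractions must be non-negative")
  structure(list(genes = genes, causal = causal,
                 h2_polygenic = h2_polygenic),
            class = "causal_architecture")
}

#' @export
print.causal_architecture <- function(x, ...) {
  cat("Causal architecture: ", nrow(x$genes), " genes, ",
      nrow(x$causal), " causal SNPs; polygenic h2 = ",
      x$h2_polygenic, "\n", sep = "")
  print(x$genes, row.names = FALSE)
  invisible(x)
}

#' Classify significant SNPs as true or false positives
#'
#' A significant SNP is a true positive if its r-squared with any causal SNP
#' of some gene on the same chromosome reaches `r2_block` (the LD-block
#' criterion); otherwise it is a false positive. All genes clearing the
#' threshold are recorded (a hit in a region of extended LD can vouch for
#' more than one gene); the single best gene (max r-squared, ties broken by
#' genomic distance then name) labels the hit. Hits whose r-squared cannot be
#' computed (monomorphic) are unclassifiable and counted as false positives.
#'
#' @param sig_snps Character vector of significant SNP ids (present in `G`).
#' @param arch A [causal_architecture].
#' @param G The [genotypes] object containing both hit and causal SNPs.
#' @param r2_block LD-block threshold (default 0.2).
#' @return Data frame: snp, chrom, pos, label (`"TP"`/`"FP"`), best_gene,
#'   best_r2, genes (all attributed genes, ";"-separated).
#' @export
classify_hits <- function(sig_snps, arch, G, r2_block = 0.2) {
  stopifnot(inherits(arch, "causal_architecture"), inherits(G, "genotypes"))
  sig_snps <- as.character(sig_snps)
  if (!all(sig_snps %in% G$map$snp))
    stop("significant SNP(s) absent from genotypes: ",
         paste(utils::head(setdiff(sig_snps, G$map$snp), 5L), collapse = ", "))
  causal <- arch$causal[arch$causal$snp %in% G$map$snp, , drop = FALSE]
  out <- data.frame(snp = sig_snps, chrom = NA, pos = NA_real_,
                    label = "FP", best_gene = NA_character_,
                    best_r2 = NA_real_, genes = NA_character_,
                    stringsAsFactors = FALSE)
  midx <- match(sig_snps, G$map$snp)
  out$chrom <- G$map$chrom[midx]
  out$pos <- G$map$pos[midx]
  for (i in seq_along(sig_snps)) {
    hit <- sig_snps[i]
    cc <- causal[causal$chrom == out$chrom[i], , drop = FALSE]
    if (!nrow(cc)) next
    gh <- G$dosages[, hit]
    if (is.na(stats::var(gh, na.rm = TRUE)) || stats::var(gh, na.rm = TRUE) == 0) {
      out$label[i] <- "FP"  # unclassifiable, counted as false positive
      out$genes[i] <- "unclassifiable"
      next
    }
    r2 <- vapply(cc$snp, function(s) {
      gc <- G$dosages[, s]
      if (stats::var(gc, na.rm = TRUE) == 0) return(0)
      pairwise_r2(gh, gc)
    }, numeric(1))
    per_gene <- tapply(r2, cc$gene, max)
    hitters <- names(per_gene)[per_gene >= r2_block]
    if (length(hitters)) {
      out$label[i] <- "TP"
      out$genes[i] <- paste(sort(hitters), collapse = ";")
      best <- max(per_gene)
      tied <- names(per_gene)[per_gene >= best - 1e-12]
      if (length(tied) > 1L && "pos" %in% names(cc)) {
        dist <- vapply(tied, function(g)
          min(abs(cc$pos[cc$gene == g] - out$pos[i])), numeric(1))
        tied <- tied[order(dist, tied)]
      } else tied <- sort(tied)
      out$best_gene[i] <- tied[1]
      out$best_r2[i] <- best
    } else {
      out$best_r2[i] <- max(r2)
    }
  }
  out
}

#' Cross-replicate FDR and hit-count summary
#'
#' Builds the per-method summary table: total significant SNPs pooled over
#' replicates, MAF breakdown, mean/median/stdev of per-replicate counts,
#' pooled FDR (false positives / total significant), conditional FDR among
#' hits not significant for the reference method (raw phenotype), and
#' per-replicate count comparisons against the reference.
#'
#' @param hits Named list (one element per method) of data frames with
#'   columns `replicate`, `snp`, `label` (from [classify_hits], plus the
#'   replicate index).
#' @param maf_table Named numeric vector: MAF per SNP id.
#' @param n_replicates Total number of replicates scanned.
#' @param reference Method name the conditional rows compare against
#'   (default first element).
#' @return Data frame of class `"fdr_summary"`, one column per method, rows
#'   mirroring the standard report layout.
#' @export
fdr_summary <- function(hits, maf_table, n_replicates,
                        reference = names(hits)[1]) {
  stopifnot(is.list(hits), reference %in% names(hits))
  methods <- names(hits)
  rows <- c("Total significant SNPs", "Sig SNPs with MAF < 0.05",
            "Sig SNPs with MAF < 0.01", "Mean sig SNPs per replicate",
            "Median sig SNPs per replicate", "Stdev sig SNPs per replicate",
            "FDR", "FDR for SNPs not seen in reference",
            "Replicates with more SNPs than reference",
            "Replicates with fewer SNPs than reference",
            "Replicates with same number as reference")
  out <- matrix(NA_real_, length(rows), length(methods),
                dimnames = list(rows, methods))
  ref_keys <- with(hits[[reference]], paste(replicate, snp))
  for (m in methods) {
    h <- hits[[m]]
    tot <- nrow(h)
    out["Total significant SNPs", m] <- tot
    counts <- tabulate(factor(h$replicate, levels = seq_len(n_replicates)),
                       nbins = n_replicates)
    out["Mean sig SNPs per replicate", m] <- mean(counts)
    out["Median sig SNPs per replicate", m] <- stats::median(counts)
    out["Stdev sig SNPs per replicate", m] <- stats::sd(counts)
    if (tot > 0) {
      mafs <- maf_table[h$snp]
      out["Sig SNPs with MAF < 0.05", m] <- 100 * mean(mafs < 0.05, na.rm = TRUE)
      out["Sig SNPs with MAF < 0.01", m] <- 100 * mean(mafs < 0.01, na.rm = TRUE)
      out["FDR", m] <- 100 * sum(h$label == "FP") / tot
    }
    if (m != reference) {
      new <- !(paste(h$replicate, h$snp) %in% ref_keys)
      if (any(new))
        out["FDR for SNPs not seen in reference", m] <-
          100 * sum(h$label[new] == "FP") / sum(new)
      rc <- tabulate(factor(hits[[reference]]$replicate,
                            levels = seq_len(n_replicates)), n_replicates)
      out["Replicates with more SNPs than reference", m] <- sum(counts > rc)
      out["Replicates with fewer SNPs than reference", m] <- sum(counts < rc)
      out["Replicates with same number as reference", m] <- sum(counts == rc)
    }
  }
  out <- as.data.frame(out)
  attr(out, "reference") <- reference
  class(out) <- c("fdr_summary", "data.frame")
  out
}

#' Per-gene hit counts across replicates
#'
#' For each causal gene and method, the number of replicates with at least
#' one significant SNP attributed to that gene (a hit counts for every gene
#' whose LD-block criterion it clears). Genes never hit are still listed with
#' zero counts.
#'
#' @param hits Named list per method of labelled hit data frames (columns
#'   `replicate`, `genes`).
#' @param arch A [causal_architecture].
#' @return Data frame: gene, chrom, then one count column per method.
#' @export
gene_hit_table <- function(hits, arch) {
  stopifnot(inherits(arch, "causal_architecture"))
  genes <- arch$genes$gene
  out <- data.frame(gene = genes, chrom = arch$genes$chrom,
                    stringsAsFactors = FALSE)
  for (m in names(hits)) {
    h <- hits[[m]]
    cnt <- integer(length(genes))
    if (nrow(h)) {
      tp <- h[h$label == "TP" & !is.na(h$genes), , drop = FALSE]
      for (gi in seq_along(genes)) {
        g <- genes[gi]
        has <- vapply(strsplit(tp$genes, ";", fixed = TRUE),
                      function(v) g %in% v, logical(1))
        cnt[gi] <- length(unique(tp$replicate[has]))
      }
    }
    out[[m]] <- cnt
  }
  out
}
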