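#' Write a pedigree as a FAM-style file
#'
#' Five whitespace-separated columns: family id, individual id, father,
#' mother, sex (1/2); missing parents written as `0`. Round-trips through
#' [read_pedigree].
#'
#' @param ped A [pedigree].
#' @param path Output path.
#' @export
write_fam <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  df <- data.frame(ped$fam, ped$id,
                   ifelse(is.na(ped$father), "0", ped$father),
                   ifelse(is.na(ped$mother), "0", ped$mother),
                   ped$sex)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write / read a relatedness matrix as text
#'
#' `format = "square"` writes the full matrix with a header row of ids;
#' `format = "long"` writes the three columns id1, id2, value (upper triangle
#' including the diagonal). Values keep full double precision.
#'
#' @param R A [relatedness] object.
#' @param path File path.
#' @param format `"square"` or `"long"`.
#' @export
write_relatedness <- function(R, path, format = c("square", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(R, "relatedness"))
  if (format == "square") {
    utils::write.table(format(R$M, digits = 17, trim = TRUE, scientific = TRUE),
                       path, quote = FALSE, row.names = TRUE, col.names = NA,
                       sep = "\t")
  } else {
    ut <- which(upper.tri(R$M, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id1 = R$ids[ut[, 1]], id2 = R$ids[ut[, 2]],
                     value = format(R$M[ut], digits = 17, trim = TRUE,
                                    scientific = TRUE))
    utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  }
  invisible(path)
}

#' @rdname write_relatedness
#' @param source Provenance tag for the matrix being read.
#' @export
read_relatedness <- function(path, format = c("square", "long"),
                             source = "ped") {
  format <- match.arg(format)
  if (format == "square") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE)
    M <- as.matrix(df)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "character", "numeric"))
    ids <- unique(c(df$id1, df$id2))
    M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    M[cbind(df$id1, df$id2)] <- df$value
    M[cbind(df$id2, df$id1)] <- df$value
  }
  relatedness(M, source = source)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT fields built from dosages (`0/0`, `0/1`,
#' `1/1`, `./.` for missing). Phase is not represented.
#'
#' @param G A [genotypes] object.
#' @param path Output path (plain text).
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotypes"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$sample_ids), collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  D <- G$dosages
  for (j in seq_len(ncol(D))) {
    gt <- gt_code[as.character(D[, j])]
    gt[is.na(gt)] <- "./."
    ref <- if ("ref" %in% names(G$map)) G$map$ref[j] else "A"
    alt <- if ("alt" %in% names(G$map)) G$map$alt[j] else "G"
    writeLines(paste(c(G$map$chrom[j], G$map$pos[j], G$map$snp[j], ref, alt,
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Dosages are taken from the GT field (count of alternate alleles; missing
#' GT yields `NA`, never 0). Requires the vcfR package.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [genotypes] object.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_dosages needs the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    parts <- strsplit(x[ok], "[/|]")
    out[ok] <- vapply(parts, function(p) sum(as.numeric(p)), numeric(1))
    out
  }
  D <- apply(gt, 2, count_alt)
  if (is.null(dim(D))) D <- matrix(D, nrow = nrow(gt),
                                   dimnames = dimnames(gt))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  map <- data.frame(snp = fix$ID, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  genotypes(t(D), map)
}

#' Write / read a phenotype table
#'
#' Long CSV with columns id, replicate, y. Reading validates ids against a
#' pedigree when one is supplied.
#'
#' @param pheno Data frame (id, replicate, y).
#' @param path CSV path.
#' @export
write_phenotypes <- function(pheno, path) {
  stopifnot(all(c("id", "replicate", "y") %in% names(pheno)))
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @param ped Optional [pedigree] for id validation.
#' @export
read_phenotypes <- function(path, ped = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "replicate", "y") %in% names(df)))
    stop("phenotype file must have columns id, replicate, y")
  if (!is.null(ped)) {
    unknown <- setdiff(unique(df$id), ped$id)
    if (length(unknown))
      stop("phenotype id(s) not in pedigree: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  df
}

#' Run the full simulation-to-evaluation pipeline
#'
#' Desk-scale end-to-end driver: simulate a study; compute pedigree,
#' SNP-based (common variants) and sequence-based (all variants) relatedness;
#' derive PCA covariates on the unrelated subset with parental-mean
#' projection; fit per-replicate polygenic models and EGVs for each
#' relatedness flavour; scan the raw phenotype and the three EGV traits by
#' measured-genotype association; and adjudicate significant SNPs against the
#' known causal architecture. Two thresholds are carried: `sig_threshold`
#' (genome-wide significance, default 5e-8) drives the summary tables, and
#' `eval_threshold` (default 5e-7) bounds which SNPs are LD-classified at
#' all.
#'
#' @param cfg A [sim_config] (use small settings for smoke runs).
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, FAM/VCF/CSV outputs and the
#'   summary tables are written there and checksummed in the manifest.
#' @param sig_threshold Genome-wide significance threshold (default 5e-8).
#' @param eval_threshold Evaluation inclusion threshold (default 5e-7).
#' @param n_pcs Principal components used as covariates (default 3).
#' @return List of class `"run_manifest"`: `summary` (an [fdr_summary]
#'   table), `gene_table`, `hits`, `scans`, `study`, `config`, `seed`,
#'   `outputs` (paths + md5 checksums when written).
#' @export
run_pipeline <- function(cfg = sim_config(), seed = 1L, out_dir = NULL,
                         sig_threshold = 5e-8, eval_threshold = 5e-7,
                         n_pcs = 3L) {
  study <- simulate_study(cfg, seed)
  ped <- study$ped; G <- study$G
  R_ped <- study$R_ped
  R_snp <- empirical_relatedness(G, "common")
  R_seq <- empirical_relatedness(G, "all")
  unrel <- select_unrelated(ped, R_ped)
  pruned <- tryCatch(ld_prune(G), error = function(e) G$map$snp)
  Gp <- subset_genotypes(G, snps = pruned)
  pca <- pca_unrelated(Gp, unrel, k = n_pcs)
  fscores <- pc_scores(pca, Gp, ids = ped$id[ped$founder])
  scores <- project_scores(ped, fscores)
  covars <- make_covariates(ped,
                            stats::setNames(study$covariates$age,
                                            study$covariates$id),
                            scores)
  pc_cols <- grep("^PC", names(covars), value = TRUE)
  X <- stats::model.matrix(stats::reformulate(c("age", "sex", pc_cols)), covars)
  sources <- list(ped = R_ped, snp = R_snp, seq = R_seq)
  egvs <- lapply(sources, function(R)
    egv_pipeline(study$pheno, covars, R))
  reps <- seq_len(cfg$n_replicates)
  traits <- c("SBP", "EGV_ped", "EGV_snp", "EGV_seq")
  hits <- stats::setNames(vector("list", length(traits)), traits)
  scans <- list()
  for (tr in traits) hits[[tr]] <- data.frame(replicate = integer(0),
                                              snp = character(0),
                                              label = character(0),
                                              genes = character(0),
                                              stringsAsFactors = FALSE)
  fr <- maf(G)
  for (r in reps) {
    pr <- study$pheno[study$pheno$replicate == r, ]
    yr <- pr$y[match(covars$id, pr$id)]
    trait_vals <- list(SBP = yr)
    trait_E <- list(SBP = NULL)
    for (s in names(sources)) {
      er <- egvs[[s]]$replicates[[as.character(r)]]
      nm <- paste0("EGV_", s)
      if (isTRUE(er$skipped)) {
        trait_vals[nm] <- list(NULL)
      } else {
        trait_vals[[nm]] <- er$egv
        trait_E[[nm]] <- er$E
      }
    }
    for (tr in traits) {
      yv <- trait_vals[[tr]]
      if (is.null(yv)) next
      sc <- mga_scan(yv, G, X, R_ped, E = trait_E[[tr]],
                     threshold = sig_threshold, trait = tr)
      scans[[paste(tr, r, sep = "_rep")]] <- sc
      cand <- sc$snp[!is.na(sc$p) & sc$p < eval_threshold]
      if (length(cand)) {
        lab <- classify_hits(cand, study$arch, G)
        lab$replicate <- r
        lab$p <- sc$p[match(lab$snp, sc$snp)]
        lab <- lab[lab$p < sig_threshold, , drop = FALSE]
        if (nrow(lab))
          hits[[tr]] <- rbind(hits[[tr]],
                              lab[, c("replicate", "snp", "label", "genes")])
      }
    }
  }
  summary_tab <- fdr_summary(hits, fr, cfg$n_replicates, reference = "SBP")
  gene_tab <- gene_hit_table(hits, study$arch)
  outputs <- data.frame(path = character(0), md5 = character(0),
                        stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      write_fam(ped, file.path(out_dir, "pedigree.fam")),
      write_vcf(G, file.path(out_dir, "genotypes.vcf")),
      write_phenotypes(study$pheno, file.path(out_dir, "phenotypes.csv")),
      { utils::write.csv(covars, file.path(out_dir, "covariates.csv"),
                         row.names = FALSE); file.path(out_dir, "covariates.csv") },
      write_relatedness(R_ped, file.path(out_dir, "relatedness_ped.txt")),
      { utils::write.csv(cbind(row = rownames(summary_tab), summary_tab),
                         file.path(out_dir, "summary_table.csv"),
                         row.names = FALSE); file.path(out_dir, "summary_table.csv") },
      { utils::write.csv(gene_tab, file.path(out_dir, "gene_table.csv"),
                         row.names = FALSE); file.path(out_dir, "gene_table.csv") },
      { jsonlite::write_json(list(genes = study$arch$genes,
                                  causal = study$arch$causal,
                                  h2_polygenic = study$arch$h2_polygenic),
                             file.path(out_dir, "architecture.json"),
                             auto_unbox = TRUE, digits = NA)
        file.path(out_dir, "architecture.json") })
    outputs <- data.frame(path = paths, md5 = unname(tools::md5sum(paths)),
                          stringsAsFactors = FALSE)
  }
  structure(list(summary = summary_tab, gene_table = gene_tab, hits = hits,
                 scans = scans, egvs = egvs, study = study, config = cfg,
                 seed = seed, sig_threshold = sig_threshold,
                 eval_threshold = eval_threshold, outputs = outputs,
                 r_version = R.version.string),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, "): ", nrow(x$study$ped),
      " individuals, ", x$config$n_replicates, " replicates\n", sep = "")
  cat("\nSummary table:\n")
  print(round(as.matrix(x$summary), 2))
  invisible(x)
}
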