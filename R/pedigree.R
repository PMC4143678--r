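#' Read a pedigree from a FAM-style text file
#'
#' Parses a PLINK FAM dialect pedigree: whitespace- or comma-delimited text
#' with at least five columns (family id, individual id, father id, mother id,
#' sex), any further columns ignored. `0` or `NA` denotes a missing parent.
#'
#' @param path Path to the pedigree file.
#' @return A [pedigree] object, sorted so that parents precede offspring.
#' @export
#' @examples
#' fam <- tempfile(fileext = ".fam")
#' writeLines(c("F1 dad 0 0 1", "F1 mom 0 0 2", "F1 kid dad mom 1"), fam)
#' ped <- read_pedigree(fam)
#' ped
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          colClasses = "character", strip.white = TRUE,
                          blank.lines.skip = TRUE)
  if (ncol(df) < 5L)
    stop("pedigree file must have at least 5 columns (FAM, ID, FATHER, MOTHER, SEX)")
  pedigree(fam = df[[1]], id = df[[2]], father = df[[3]],
           mother = df[[4]], sex = df[[5]])
}

#' Construct and validate a pedigree
#'
#' Builds a `pedigree` object from per-individual records. Validation
#' enforces: unique ids, both parents present or both absent (half-specified
#' parentage is an error), parent ids that exist in the pedigree, and
#' acyclicity (no individual is its own ancestor). Individuals are reordered
#' topologically so every parent precedes its offspring; this generation order
#' is what the recursive kinship algorithm and parental-mean projection rely
#' on.
#'
#' @param fam Family ids (character).
#' @param id Individual ids (character, unique).
#' @param father,mother Parent ids; `0`, `""` or `NA` mean missing.
#' @param sex Sex codes: `1`/`M`/`male` and `2`/`F`/`female`.
#' @return A data frame of class `"pedigree"` with columns `fam`, `id`,
#'   `father`, `mother` (`NA` for founders), `sex` (`1` male / `2` female) and
#'   `founder` (logical), rows in generation order.
#' @export
pedigree <- function(fam, id, father, mother, sex) {
  id <- as.character(id); fam <- as.character(fam)
  father <- as.character(father); mother <- as.character(mother)
  miss <- function(x) is.na(x) | x %in% c("0", "", "NA")
  father[miss(father)] <- NA_character_
  mother[miss(mother)] <- NA_character_
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  half <- xor(is.na(father), is.na(mother))
  if (any(half))
    stop("one-parent-only records (both parents must be present or absent): ",
         paste(id[half], collapse = ", "))
  sex <- as.character(sex)
  sex_code <- ifelse(sex %in% c("1", "M", "m", "male"), 1L,
                     ifelse(sex %in% c("2", "F", "f", "female"), 2L, NA_integer_))
  if (anyNA(sex_code))
    stop("unrecognised sex code(s): ", paste(unique(sex[is.na(sex_code)]), collapse = ", "))
  known <- c(father, mother)
  known <- known[!is.na(known)]
  unknown <- setdiff(known, id)
  if (length(unknown))
    stop("parent id(s) not present in pedigree: ", paste(unknown, collapse = ", "))

  df <- data.frame(fam = fam, id = id, father = father, mother = mother,
                   sex = sex_code, founder = is.na(father),
                   stringsAsFactors = FALSE)
  ord <- ped_topo_order(df)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

# Kahn's algorithm over the parent -> child DAG; leftover nodes imply a cycle.
ped_topo_order <- function(df) {
  n <- nrow(df)
  idx <- seq_len(n)
  names(idx) <- df$id
  fa <- idx[df$father]; mo <- idx[df$mother]
  indeg <- ifelse(is.na(fa), 0L, 1L) + ifelse(is.na(mo), 0L, 1L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    queue <- sort(queue)
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n)
    stop("cycle detected in pedigree involving: ",
         paste(df$id[setdiff(seq_len(n), out)], collapse = ", "))
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree: ", nrow(x), " individuals in ", length(unique(x$fam)),
      " families (", sum(x$founder), " founders)\n", sep = "")
  utils::print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Expected relatedness 2*Phi from a pedigree
#'
#' Computes the expected relatedness matrix R = 2*Phi, twice the kinship
#' coefficient, by the recursive (tabular) method in generation order:
#' phi(i,i) = (1 + phi(father_i, mother_i)) / 2 and, for j already processed,
#' phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2; founders have
#' self-kinship 1/2 and kinship 0 with everyone processed before them. The
#' diagonal of R is 1 + F with F the inbreeding coefficient.
#'
#' @param ped A [pedigree].
#' @return A [relatedness] object with `source = "ped"`.
#' @export
#' @examples
#' fam <- tempfile(fileext = ".fam")
#' writeLines(c("F1 dad 0 0 1", "F1 mom 0 0 2", "F1 kid dad mom 1"), fam)
#' R <- expected_relatedness(read_pedigree(fam))
#' R$M["dad", "kid"]  # parent-offspring: 0.5
expected_relatedness <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  idx <- seq_len(n); names(idx) <- ped$id
  fa <- idx[ped$father]; mo <- idx[ped$mother]
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      phi[i, i] <- 0.5
    } else {
      f <- fa[i]; m <- mo[i]
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        v <- 0.5 * (phi[f, prev] + phi[m, prev])
        phi[i, prev] <- v
        phi[prev, i] <- v
      }
      phi[i, i] <- 0.5 * (1 + phi[f, m])
    }
  }
  relatedness(2 * phi, ids = ped$id, source = "ped")
}

#' Relatedness matrix container
#'
#' A symmetric n x n relatedness matrix R = 2*Phi together with the
#' individual ids it is indexed by and its provenance: `"ped"` (expected,
#' pedigree-based), `"snp"` (empirical, common variants) or `"seq"`
#' (empirical, all variants).
#'
#' @param M Symmetric numeric matrix.
#' @param ids Individual ids (defaults to `rownames(M)`).
#' @param source One of `"ped"`, `"snp"`, `"seq"`.
#' @return An object of class `"relatedness"`: list with elements `ids`, `M`,
#'   `source`.
#' @export
relatedness <- function(M, ids = rownames(M), source = c("ped", "snp", "seq")) {
  source <- match.arg(source)
  M <- as.matrix(M)
  if (is.null(ids)) stop("relatedness matrix needs individual ids")
  if (nrow(M) != ncol(M)) stop("relatedness matrix must be square")
  if (length(ids) != nrow(M)) stop("ids length does not match matrix")
  if (max(abs(M - t(M))) > 1e-8) stop("relatedness matrix must be symmetric")
  M <- (M + t(M)) / 2
  dimnames(M) <- list(ids, ids)
  structure(list(ids = as.character(ids), M = M, source = source),
            class = "relatedness")
}

#' @export
print.relatedness <- function(x, ...) {
  off <- x$M[upper.tri(x$M)]
  cat("Relatedness matrix (", x$source, "): ", length(x$ids), " individuals\n",
      "  off-diagonal range [", format(min(off), digits = 4), ", ",
      format(max(off), digits = 4), "], mean diagonal ",
      format(mean(diag(x$M)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Greedy selection of a mutually unrelated subset
#'
#' Scans ids in sorted order and keeps an id when its relatedness with every
#' id already kept is below `max_relatedness`, yielding a maximal (not
#' maximum) pairwise-unrelated set. Deterministic given the ids.
#'
#' @param ped A [pedigree].
#' @param R A [relatedness] covering all pedigree ids.
#' @param max_relatedness Exclusive upper bound on pairwise R entries
#'   (default 0.05).
#' @return Character vector of selected ids.
#' @export
select_unrelated <- function(ped, R, max_relatedness = 0.05) {
  stopifnot(inherits(ped, "pedigree"), inherits(R, "relatedness"))
  if (nrow(ped) == 0L) stop("empty pedigree")
  if (!all(ped$id %in% R$ids)) stop("relatedness matrix does not cover all pedigree ids")
  ids <- sort(ped$id)
  keep <- character(0)
  for (i in ids) {
    if (!length(keep) || all(R$M[i, keep] < max_relatedness)) keep <- c(keep, i)
  }
  keep
}
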