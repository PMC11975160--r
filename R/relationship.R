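## Normalise a pedigree argument: accepts a data.frame with columns
## id/sire/dam (ids arbitrary, 0 or NA = unknown) or a list(sire, dam) of
## positional indices. Returns list(sire, dam, ids) with positional parent
## indices (0 = unknown), parents strictly before offspring.
normalize_pedigree <- function(pedigree) {
  if (is.data.frame(pedigree)) {
    ids <- pedigree$id
    if (anyDuplicated(ids)) stop("pedigree ids must be unique")
    sire <- match(pedigree$sire, ids, nomatch = 0L)
    dam <- match(pedigree$dam, ids, nomatch = 0L)
    known_s <- !(is.na(pedigree$sire) | pedigree$sire == 0)
    known_d <- !(is.na(pedigree$dam) | pedigree$dam == 0)
    if (any(known_s & sire == 0L) || any(known_d & dam == 0L))
      stop("pedigree refers to parents that are not recorded")
  } else {
    sire <- as.integer(pedigree$sire)
    dam <- as.integer(pedigree$dam)
    ids <- seq_along(sire)
  }
  n <- length(sire)
  pos <- seq_len(n)
  if (any(sire >= pos) || any(dam >= pos))
    stop("pedigree not sorted parents-before-offspring (or cyclic)")
  list(sire = sire, dam = dam, ids = ids, n = n)
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the pedigree-based additive relationship matrix A by the tabular
#' method. Unknown parents are treated as unrelated, non-inbred founders.
#'
#' @param pedigree Either a data.frame with columns `id`, `sire`, `dam`
#'   (0 or NA marks an unknown parent; parents must be recorded before their
#'   offspring) or a list with positional `sire`/`dam` index vectors.
#' @return A dense n x n matrix, rows/columns in pedigree order.
#' @export
build_A <- function(pedigree) {
  p <- normalize_pedigree(pedigree)
  n <- p$n; sire <- p$sire; dam <- p$dam
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      ai <- numeric(i - 1L)
      if (s > 0L) ai <- ai + 0.5 * A[s, prev]
      if (d > 0L) ai <- ai + 0.5 * A[d, prev]
      A[i, prev] <- ai
      A[prev, i] <- ai
    }
    A[i, i] <- 1 + (if (s > 0L && d > 0L) 0.5 * A[s, d] else 0)
  }
  dimnames(A) <- list(p$ids, p$ids)
  A
}

#' Pedigree inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes inbreeding coefficients for every animal by the Meuwissen & Luo
#' (1992) algorithm, tracing, per animal, the contribution vector over its
#' ancestor closure. Animals with at least one unknown parent have F = 0.
#'
#' @inheritParams build_A
#' @return Numeric vector of inbreeding coefficients in pedigree order.
#' @export
meuwissen_luo_inbreeding <- function(pedigree) {
  p <- normalize_pedigree(pedigree)
  n <- p$n; sire <- p$sire; dam <- p$dam
  FF <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (s == 0L || d == 0L) next
    # ancestor closure of i (including i)
    anc <- logical(i)
    anc[i] <- TRUE
    for (j in i:1) {
      if (!anc[j]) next
      if (sire[j] > 0L) anc[sire[j]] <- TRUE
      if (dam[j] > 0L) anc[dam[j]] <- TRUE
    }
    idx <- which(anc)
    L <- numeric(i)
    L[i] <- 1
    Fi <- -1
    for (j in rev(idx)) {
      lj <- L[j]
      if (lj == 0) next
      s2 <- sire[j]; d2 <- dam[j]
      Dj <- if (s2 > 0L && d2 > 0L) 0.5 - 0.25 * (FF[s2] + FF[d2])
            else if (s2 > 0L) 0.75 - 0.25 * FF[s2]
            else if (d2 > 0L) 0.75 - 0.25 * FF[d2]
            else 1
      Fi <- Fi + lj * lj * Dj
      if (s2 > 0L) L[s2] <- L[s2] + lj / 2
      if (d2 > 0L) L[d2] <- L[d2] + lj / 2
    }
    FF[i] <- Fi
  }
  FF
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Direct construction of A-inverse by Henderson's rules, accounting for
#' inbreeding through the Mendelian-sampling variances
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (with the usual conventions for unknown
#' parents). Inbreeding coefficients are computed with
#' [meuwissen_luo_inbreeding()] unless supplied.
#'
#' @inheritParams build_A
#' @param inbreeding Optional precomputed inbreeding coefficients in pedigree
#'   order (for example `diag(build_A(ped)) - 1`).
#' @return A sparse symmetric `Matrix::dgCMatrix`.
#' @export
build_A_inverse <- function(pedigree, inbreeding = NULL) {
  p <- normalize_pedigree(pedigree)
  n <- p$n; sire <- p$sire; dam <- p$dam
  FF <- if (is.null(inbreeding)) meuwissen_luo_inbreeding(p) else inbreeding
  Fs <- ifelse(sire > 0L, FF[pmax(sire, 1L)], 0)
  Fd <- ifelse(dam > 0L, FF[pmax(dam, 1L)], 0)
  d <- ifelse(sire > 0L & dam > 0L, 0.5 - 0.25 * (Fs + Fd),
       ifelse(sire > 0L, 0.75 - 0.25 * Fs,
       ifelse(dam > 0L, 0.75 - 0.25 * Fd, 1)))
  b <- 1 / d
  pos <- seq_len(n)
  ii <- pos; jj <- pos; xx <- b
  hs <- sire > 0L; hd <- dam > 0L
  add <- function(i2, j2, x2) {
    ii <<- c(ii, i2); jj <<- c(jj, j2); xx <<- c(xx, x2)
  }
  if (any(hs)) {
    add(pos[hs], sire[hs], -b[hs] / 2); add(sire[hs], pos[hs], -b[hs] / 2)
    add(sire[hs], sire[hs], b[hs] / 4)
  }
  if (any(hd)) {
    add(pos[hd], dam[hd], -b[hd] / 2); add(dam[hd], pos[hd], -b[hd] / 2)
    add(dam[hd], dam[hd], b[hd] / 4)
  }
  both <- hs & hd
  if (any(both)) {
    add(sire[both], dam[both], b[both] / 4)
    add(dam[both], sire[both], b[both] / 4)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 * sum(p_k (1 - p_k)))` with `Z` the allele-count matrix
#' centred by twice the allele frequencies. By default the frequencies are
#' the observed frequencies among the genotyped animals supplied. To keep the
#' matrix invertible alongside the pedigree block, G is blended with the
#' pedigree relationships of the genotyped animals:
#' `G_blended = blend * G + (1 - blend) * A22`.
#'
#' @param M Genotype dosage matrix, animals in rows, markers in columns
#'   (entries 0/1/2).
#' @param A22 Pedigree relationship matrix among the genotyped animals (same
#'   order as rows of `M`); required when `blend < 1`.
#' @param freq Optional allele frequencies used for centring; defaults to the
#'   observed frequencies `colMeans(M) / 2`.
#' @param blend Weight on the genomic component (default 0.95).
#' @return The (blended) genomic relationship matrix.
#' @export
build_G <- function(M, A22 = NULL, freq = NULL, blend = 0.95) {
  if (nrow(M) < 2L) stop("need at least two genotyped individuals")
  p <- if (is.null(freq)) colMeans(M) / 2 else freq
  den <- 2 * sum(p * (1 - p))
  if (den <= 0)
    stop("all markers monomorphic among genotyped animals; G undefined")
  Z <- sweep(M, 2L, 2 * p)
  G <- tcrossprod(Z) / den
  if (blend < 1) {
    if (is.null(A22))
      stop("A22 required for blending")
    G <- blend * G + (1 - blend) * A22
  }
  G
}

#' Inverse of the single-step H matrix
#'
#' The single-step relationship matrix H combines pedigree and genomic
#' information; its inverse is the pedigree A-inverse plus a correction on
#' the genotyped block: `H^-1 = A^-1 + [0 0; 0 G_b^-1 - A22^-1]`.
#'
#' @param A_inv Sparse inverse of the full pedigree relationship matrix.
#' @param A22 Pedigree relationships among genotyped animals.
#' @param G_blended Blended genomic relationship matrix ([build_G()]).
#' @param geno_idx Positions of the genotyped animals within the pedigree
#'   ordering of `A_inv`.
#' @param parts If TRUE, return `list(A_inv, correction, geno_idx)` without
#'   forming the sum explicitly (the iterative solver exploits the
#'   sparse-plus-dense structure).
#' @return A sparse matrix, or the parts list.
#' @export
build_H_inverse <- function(A_inv, A22, G_blended, geno_idx,
                            parts = FALSE) {
  if (length(geno_idx) == 0L) {
    if (parts) return(list(A_inv = A_inv, correction = NULL,
                           geno_idx = integer(0)))
    return(A_inv)
  }
  Gi <- tryCatch(chol2inv(chol(G_blended)), error = function(e)
    stop("blended G is singular: ", conditionMessage(e)))
  A22i <- chol2inv(chol(A22))
  corr <- Gi - A22i
  if (parts)
    return(list(A_inv = A_inv, correction = corr, geno_idx = geno_idx))
  n <- nrow(A_inv)
  C <- Matrix::sparseMatrix(
    i = rep(geno_idx, times = length(geno_idx)),
    j = rep(geno_idx, each = length(geno_idx)),
    x = as.numeric(t(corr)), dims = c(n, n))
  A_inv + C
}

#' Mean pedigree kinship of a cohort
#'
#' Mean of the pairwise kinship coefficients `A_ij / 2` over unordered
#' distinct pairs of cohort members (self-pairs excluded), with A built on
#' the recorded pedigree.
#'
#' @param cohort Ids of the cohort members (at least two).
#' @param pedigree A pedigree data.frame (`id`, `sire`, `dam`) covering the
#'   cohort and its ancestors, or a precomputed relationship matrix with
#'   dimnames matching the ids.
#' @return Mean kinship coefficient.
#' @export
mean_pedigree_kinship <- function(cohort, pedigree) {
  if (length(cohort) < 2L) stop("singleton cohort: no pairs to average")
  A <- if (is.matrix(pedigree)) pedigree else build_A(pedigree)
  idx <- match(as.character(cohort), rownames(A))
  if (anyNA(idx)) stop("cohort ids missing from the pedigree")
  Ac <- A[idx, idx]
  k <- length(idx)
  (sum(Ac) - sum(diag(Ac))) / (k * (k - 1L)) / 2
}

## Mean off-diagonal A/2 from the flock's incrementally maintained kinship
## block (base population = founder breeding cohort).
flock_ram_kinship <- function(fl) {
  idx <- match(fl$rams, fl$kin$ids)
  Ac <- fl$kin$A[idx, idx]
  k <- length(idx)
  (sum(Ac) - sum(diag(Ac))) / (k * (k - 1L)) / 2
}
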