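## Genetic evaluation of the current population state.
##
## Builds the evaluation window (data from the last `window_cycles` breeding
## cycles, pedigree extended a further `ped_depth` cycles back), assembles the
## relationship structure (pedigree A-inverse for PBLUP; single-step
## H-inverse for ssGBLUP) and solves the two-trait mixed-model equations.
## EBVs are written back into the flock (`fl$ebv`).

#' Evaluate a flock (PBLUP or single-step GBLUP)
#'
#' @param fl A `flock` with trait architecture and phenotypes.
#' @param method `"PBLUP"` or `"ssGBLUP"`.
#' @param candidate_ids Ids of the current selection candidates (always part
#'   of the evaluation, without own phenotypes).
#' @param extra_geno_ids Ids whose genotypes are used in this evaluation in
#'   addition to the permanent reference population (the candidates genotyped
#'   this cycle); ignored under PBLUP.
#' @param window_cycles Data window: phenotypes of animals born within this
#'   many cycles are used (default 10).
#' @param ped_depth Additional pedigree depth beyond the data window
#'   (default 7); older ancestors are treated as unknown.
#' @param blend Genomic blending weight passed to [build_G()].
#' @param tol,maxit Solver controls, see [solve_mme()].
#' @param window_cache Optional precomputed window from
#'   `build_eval_window()`; the two evaluations of a two-stage cycle share
#'   the same window, pedigree and relationship structure.
#' @return The flock with updated `ebv` and evaluation diagnostics in
#'   `fl$last_eval` (window size, number of genotyped animals, iterations).
#' @export
evaluate_flock <- function(fl, method = c("PBLUP", "ssGBLUP"),
                           candidate_ids = integer(0),
                           extra_geno_ids = integer(0),
                           window_cycles = 10L, ped_depth = 7L,
                           blend = 0.95, tol = 1e-8, maxit = 5000L,
                           window_cache = NULL) {
  method <- match.arg(method)
  geno_ids <- if (method == "ssGBLUP")
    unique(c(fl$refgeno$ids, extra_geno_ids)) else integer(0)
  w <- if (is.null(window_cache))
    build_eval_window(fl, candidate_ids,
                      if (method == "ssGBLUP") fl$refgeno$ids else integer(0),
                      window_cycles, ped_depth)
    else window_cache
  if (length(geno_ids) && !all(w$loc[geno_ids] > 0L))
    stop("window cache does not cover all genotyped animals")
  ids <- w$ids; n <- length(ids); loc <- w$loc
  A <- w$A; Ainv <- w$Ainv; phen_use <- w$phen_use
  corr <- NULL; gpos <- integer(0)
  if (method == "ssGBLUP" && length(geno_ids) >= 2L) {
    gpos <- loc[geno_ids]
    stopifnot(all(gpos > 0L))
    M <- flock_dosages(fl, geno_ids)          # animals x markers
    A22 <- A[gpos, gpos]
    Gb <- build_G(M, A22 = A22, blend = blend)
    H <- build_H_inverse(Ainv, A22, Gb, gpos, parts = TRUE)
    corr <- H$correction
  }
  y <- matrix(NA_real_, n, 2L)
  y[loc[phen_use], ] <- fl$phen[phen_use, , drop = FALSE]
  G0 <- fl$arch$target_var *
    matrix(c(1, fl$arch$r_g, fl$arch$r_g, 1), 2L, 2L)
  R0 <- diag(fl$arch$residual_var)
  fit <- solve_mme(y, Ainv, G0, R0, correction = corr, geno_idx = gpos,
                   tol = tol, maxit = maxit)
  fl$ebv[ids, ] <- fit$u
  fl$n_evals <- fl$n_evals + 1L
  fl$last_eval <- list(method = method, n_window = n,
                       n_genotyped = length(geno_ids),
                       iterations = fit$iterations, beta = fit$beta)
  fl
}

## Construct the evaluation window: candidates, animals in service,
## phenotyped animals born within the data window (plus the permanent
## genotyped reference population - no sliding base), and their ancestors up
## to ped_depth cycles before the data window. Builds the local sorted
## pedigree, the dense tabular A (source of inbreeding coefficients and of
## A22) and the sparse A-inverse.
build_eval_window <- function(fl, candidate_ids, ref_ids, window_cycles,
                              ped_depth) {
  t_now <- fl$cycle
  min_birth_data <- t_now - window_cycles
  min_birth_ped <- min_birth_data - ped_depth
  phen_ids <- which(!is.na(fl$phen[, 1L]))
  phen_use <- phen_ids[fl$birth[phen_ids] > min_birth_data]
  phen_use <- unique(c(phen_use, intersect(phen_ids, ref_ids)))
  core <- unique(c(candidate_ids, fl$rams, fl$ewes, phen_use, ref_ids))
  ids <- core
  frontier <- core
  repeat {
    par <- unique(c(fl$sire[frontier], fl$dam[frontier]))
    par <- par[par > 0L]
    par <- par[fl$birth[par] > min_birth_ped]
    new <- setdiff(par, ids)
    if (length(new) == 0L) break
    ids <- c(ids, new)
    frontier <- new
  }
  ids <- ids[order(fl$birth[ids], ids)]
  n <- length(ids)
  loc <- integer(fl$n)
  loc[ids] <- seq_len(n)
  sire <- ifelse(fl$sire[ids] > 0L, loc[pmax(fl$sire[ids], 1L)], 0L)
  dam <- ifelse(fl$dam[ids] > 0L, loc[pmax(fl$dam[ids], 1L)], 0L)
  ped <- list(sire = as.integer(sire), dam = as.integer(dam))
  A <- build_A(ped)
  Ainv <- build_A_inverse(ped, inbreeding = diag(A) - 1)
  list(ids = ids, loc = loc, ped = ped, A = A, Ainv = Ainv,
       phen_use = phen_use)
}

## Genotype dosage matrix (animals x markers) for the given ids, combining
## the cached reference-population dosages with haplotypes of current
## candidates.
flock_dosages <- function(fl, ids) {
  m <- fl$map$n_markers
  M <- matrix(NA_real_, length(ids), m)
  ref_pos <- match(ids, fl$refgeno$ids)
  cached <- !is.na(ref_pos)
  if (any(cached))
    M[cached, ] <- t(fl$refgeno$M[, ref_pos[cached], drop = FALSE])
  todo <- which(!cached)
  for (k in todo) {
    h <- fl$hap[[ids[k]]]
    if (is.null(h)) stop("no stored genotype or haplotypes for id ", ids[k])
    M[k, ] <- h[, 1L] + h[, 2L]
  }
  M
}

## Add animals to the permanent reference genotype store.
flock_add_ref_genotypes <- function(fl, ids) {
  ids <- setdiff(ids, fl$refgeno$ids)
  if (length(ids) == 0L) return(fl)
  add <- vapply(ids, function(i) {
    h <- fl$hap[[i]]
    h[, 1L] + h[, 2L]
  }, numeric(fl$map$n_markers))
  if (length(ids) == 1L) add <- matrix(add, ncol = 1L)
  fl$refgeno$M <- if (is.null(fl$refgeno$M)) add else cbind(fl$refgeno$M, add)
  fl$refgeno$ids <- c(fl$refgeno$ids, ids)
  fl$genotyped[ids] <- TRUE
  fl
}
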