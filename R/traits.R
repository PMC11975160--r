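#' Sample the two-trait additive architecture
#'
#' Draws one shared set of QTL marker indices (uniformly, without
#' replacement) used by both traits, and per-QTL additive effect pairs from a
#' bivariate normal whose effect-level correlation is calibrated so that the
#' realised correlation of true breeding values (TBVs) in the founder
#' population equals the target genetic correlation. Each trait is then
#' affinely rescaled so the founder-cohort TBV mean and variance equal the
#' configured targets exactly.
#'
#' @param map A [genome_map()].
#' @param founders A `flock` from [build_founder_population()]; the breeding
#'   rams and ewes anchor the scaling.
#' @param n_qtl Number of QTL (shared by both traits; default 1000).
#' @param target_mean,target_var Founder TBV mean and variance per trait
#'   (defaults 100 and 10).
#' @param h2 Length-2 heritabilities, `c(health, production)`; defaults
#'   `c(0.1, 0.3)`.
#' @param r_g Target genetic correlation between traits (default -0.1).
#' @param seed Optional integer seed.
#' @return A `trait_architecture`: QTL indices, effect matrix (QTL x 2),
#'   per-trait intercept/slope, heritabilities, residual variances
#'   `target_var * (1 - h2) / h2`, and the calibrated effect correlation.
#' @export
sample_architecture <- function(map, founders, n_qtl = 1000L,
                                target_mean = 100, target_var = 10,
                                h2 = c(0.1, 0.3), r_g = -0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- map$n_markers
  n_qtl <- as.integer(n_qtl)
  if (n_qtl > m) stop("n_qtl exceeds the number of markers")
  stopifnot(length(h2) == 2L, all(h2 > 0), all(h2 < 1), abs(r_g) < 1)
  qtl <- sort(sample.int(m, n_qtl))
  ids <- c(founders$rams, founders$ewes)
  if (length(ids) < 3L) stop("founder cohort too small to anchor scaling")
  # founder QTL allele counts: n_qtl x n matrix
  C <- vapply(ids, function(i) {
    h <- founders$hap[[i]]
    h[qtl, 1L] + h[qtl, 2L]
  }, integer(n_qtl))
  z1 <- stats::rnorm(n_qtl)
  z2 <- stats::rnorm(n_qtl)
  a1 <- drop(crossprod(C, z1))
  a2 <- drop(crossprod(C, z2))
  if (stats::var(a1) == 0 || stats::var(a2) == 0)
    stop("degenerate architecture: founder TBV variance is zero")
  # realised founder TBV correlation as a function of the effect-level rho
  realised <- function(rho) {
    t2 <- rho * a1 + sqrt(1 - rho^2) * a2
    stats::cor(a1, t2)
  }
  f <- function(rho) realised(rho) - r_g
  rho_e <- tryCatch(
    stats::uniroot(f, c(-0.999, 0.999), tol = 1e-10)$root,
    error = function(e) r_g)
  effects <- cbind(z1, rho_e * z1 + sqrt(1 - rho_e^2) * z2,
                   deparse.level = 0L)
  raw <- cbind(a1, rho_e * a1 + sqrt(1 - rho_e^2) * a2)
  slope <- sqrt(target_var / apply(raw, 2L, stats::var))
  intercept <- target_mean - slope * colMeans(raw)
  structure(
    list(qtl = qtl, effects = effects, intercept = intercept, slope = slope,
         n_qtl = n_qtl, target_mean = target_mean, target_var = target_var,
         h2 = h2, r_g = r_g, rho_effects = rho_e,
         residual_var = target_var * (1 - h2) / h2),
    class = "trait_architecture")
}

## TBVs from a QTL allele-count matrix (n_qtl x n): returns n x 2.
tbv_from_counts <- function(C, arch) {
  raw <- crossprod(C, arch$effects)            # n x 2
  sweep(sweep(raw, 2L, arch$slope, `*`), 2L, arch$intercept, `+`)
}

#' True breeding values
#'
#' The TBV of an individual is the affinely scaled sum over QTL of allele
#' count times additive effect, per trait; a pure function of the genotype.
#'
#' @param ind A `flock`, or a single individual-like list with a
#'   `haplotypes` matrix.
#' @param arch A `trait_architecture` from [sample_architecture()].
#' @param ids When `ind` is a flock: individual ids to evaluate.
#' @return An n x 2 matrix of TBVs (one row for a single individual).
#' @export
true_bv <- function(ind, arch, ids = NULL) {
  if (inherits(ind, "flock")) {
    if (is.null(ids)) ids <- which(!vapply(ind$hap, is.null, logical(1L)))
    C <- vapply(ids, function(i) {
      h <- ind$hap[[i]]
      h[arch$qtl, 1L] + h[arch$qtl, 2L]
    }, integer(arch$n_qtl))
    if (length(ids) == 1L) C <- matrix(C, arch$n_qtl, 1L)
    out <- tbv_from_counts(C, arch)
    rownames(out) <- ids
    return(out)
  }
  h <- if (is.list(ind)) ind$haplotypes else ind
  C <- matrix(h[arch$qtl, 1L] + h[arch$qtl, 2L], arch$n_qtl, 1L)
  tbv_from_counts(C, arch)
}

## Store TBVs for the given ids inside the flock.
flock_set_tbv <- function(fl, ids) {
  fl$tbv[ids, ] <- true_bv(fl, fl$arch, ids)
  fl
}

#' Draw phenotypes (own performance records)
#'
#' Adds independent normal residuals to the TBVs: `y_t = tbv_t + e_t` with
#' `e_t ~ N(0, target_var * (1 - h2_t) / h2_t)`; residuals are uncorrelated
#' across traits and individuals, and there is no sex effect. Phenotyping an
#' individual twice is an error (each animal contributes one own-performance
#' record per trait).
#'
#' @param fl A `flock` with a trait architecture attached (`fl$arch`).
#' @param ids Individual ids to phenotype.
#' @param seed Optional integer seed.
#' @return The updated flock.
#' @export
draw_phenotype <- function(fl, ids, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arch <- fl$arch
  if (is.null(arch)) stop("no trait architecture attached to the flock")
  if (length(ids) == 0L) return(fl)
  if (any(!is.na(fl$phen[ids, 1L])))
    stop("attempt to phenotype an already phenotyped individual")
  k <- length(ids)
  e <- cbind(stats::rnorm(k, 0, sqrt(arch$residual_var[1L])),
             stats::rnorm(k, 0, sqrt(arch$residual_var[2L])))
  fl$phen[ids, ] <- fl$tbv[ids, , drop = FALSE] + e
  fl
}
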