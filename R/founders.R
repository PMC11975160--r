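#' Ancestral haplotype panel
#'
#' Draws a panel of ancestral haplotypes with per-marker allele frequencies
#' from a symmetric Beta(shape, shape) spectrum (shape = 0.5 gives the
#' U-shaped minor-allele-frequency distribution typical of SNP data before
#' array ascertainment). Alleles are drawn independently per marker, so the
#' panel itself carries no linkage disequilibrium; LD is created afterwards by
#' [mosaic_copy()]. Markers that come out monomorphic are redrawn so the
#' marker index set stays stable for later QTL assignment.
#'
#' @param map A [genome_map()].
#' @param n_ancestral Number of haplotypes in the panel (at least 2).
#' @param freq_shape Positive shape parameter of the symmetric Beta frequency
#'   spectrum.
#' @param seed Optional integer seed.
#' @return A `haplotype_panel`: list with `alleles` (marker x haplotype 0/1
#'   integer matrix) and `n_haplotypes`.
#' @export
generate_ancestral_panel <- function(map, n_ancestral = 100L,
                                     freq_shape = 0.5, seed = NULL) {
  if (!inherits(map, "genome_map")) stop("configuration error: invalid map")
  if (n_ancestral < 2L) stop("n_ancestral must be at least 2")
  if (!is.numeric(freq_shape) || freq_shape <= 0)
    stop("freq_shape must be positive")
  if (!is.null(seed)) set.seed(seed)
  m <- map$n_markers
  draw <- function(k) {
    p <- stats::rbeta(k, freq_shape, freq_shape)
    matrix(stats::rbinom(k * n_ancestral, 1L, p), k, n_ancestral)
  }
  alleles <- draw(m)
  repeat {
    rs <- rowSums(alleles)
    mono <- which(rs == 0L | rs == n_ancestral)
    if (length(mono) == 0L) break
    alleles[mono, ] <- draw(length(mono))
  }
  storage.mode(alleles) <- "integer"
  structure(list(alleles = alleles, n_haplotypes = n_ancestral,
                 n_markers = m),
            class = "haplotype_panel")
}

#' Mosaic copying of a haplotype panel
#'
#' Builds an output panel whose haplotypes are mosaics of the input panel:
#' along each chromosome the current template haplotype is replaced by a
#' uniformly drawn one at the points of a Poisson process with the given rate
#' per Morgan (a fresh template is drawn at every chromosome start). Lower
#' switch rates give longer shared segments and therefore stronger, longer
#' range linkage disequilibrium in the output. This stands in for a real
#' genotype panel when one is not available.
#'
#' @param panel A `haplotype_panel` from [generate_ancestral_panel()].
#' @param map The [genome_map()] the panel was drawn on.
#' @param n_out Number of output haplotypes (default 1570, i.e. the diploid
#'   equivalent of 785 genotyped donor animals).
#' @param switch_rate Template switch rate per Morgan (> 0).
#' @param mutation_rate Per-marker allele flip probability applied to the
#'   output (default 0).
#' @param seed Optional integer seed.
#' @return A `haplotype_panel` with `n_out` haplotypes.
#' @export
mosaic_copy <- function(panel, map, n_out = 1570L, switch_rate = 1.0,
                        mutation_rate = 0, seed = NULL) {
  if (!inherits(panel, "haplotype_panel") || panel$n_haplotypes == 0L)
    stop("empty input panel")
  if (switch_rate <= 0) stop("switch_rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  m <- map$n_markers
  n_anc <- panel$n_haplotypes
  # per-interval probability that at least one template switch occurs;
  # forced re-draw (prob 1) across chromosome boundaries
  q <- ifelse(is.na(map$d_adj), 1, 1 - exp(-switch_rate * map$d_adj))
  out <- matrix(0L, m, n_out)
  for (j in seq_len(n_out)) {
    cuts <- which(stats::runif(m - 1L) < q)
    nseg <- length(cuts) + 1L
    tmpl <- sample.int(n_anc, nseg, replace = TRUE)
    t_idx <- rep.int(tmpl, diff(c(0L, cuts, m)))
    out[, j] <- panel$alleles[cbind(seq_len(m), t_idx)]
  }
  if (mutation_rate > 0) {
    flip <- matrix(stats::runif(m * n_out) < mutation_rate, m, n_out)
    out[flip] <- 1L - out[flip]
  }
  storage.mode(out) <- "integer"
  structure(list(alleles = out, n_haplotypes = n_out, n_markers = m),
            class = "haplotype_panel")
}

## Stationary age distribution of a breeding cohort under the culling model:
## each cycle exactly n_replace animals are removed, sampled with weight
## age^exponent, and replaced by age-1 entrants.  Iterated deterministically
## (expected flows) to its fixed point; used to initialise founder ages so
## the demography is stable from the first cycle.
stationary_age_distribution <- function(n_breeding, n_replace,
                                        exponent = 2, max_age = 15L) {
  stopifnot(n_replace >= 1, n_replace <= n_breeding)
  n <- c(n_breeding, rep(0, max_age - 1L))
  for (it in seq_len(400L)) {
    w <- n * (seq_len(max_age))^exponent
    culls <- if (sum(w) > 0) n_replace * w / sum(w) else rep(0, max_age)
    culls <- pmin(culls, n)
    surv <- n - culls
    n_new <- c(n_replace, surv[-max_age])
    n_new[max_age] <- n_new[max_age] + surv[max_age]  # cap: oldest class pools
    if (max(abs(n_new - n)) < 1e-10) { n <- n_new; break }
    n <- n_new
  }
  n / sum(n)
}

## Create an empty flock container. Individuals are stored column-wise in
## growing parallel vectors indexed by integer id (1..n).
new_flock <- function(map, params = list()) {
  structure(
    list(map = map, arch = NULL, params = params,
         n = 0L,
         sire = integer(0), dam = integer(0), sex = integer(0),  # 1=M,2=F
         birth = integer(0), alive = logical(0), age = integer(0),
         hap = list(),
         tbv = matrix(numeric(0), 0L, 2L),
         phen = matrix(numeric(0), 0L, 2L),
         genotyped = logical(0),
         ebv = matrix(numeric(0), 0L, 2L),
         rams = integer(0), ewes = integer(0),
         refgeno = list(ids = integer(0), M = NULL),
         kin = list(ids = integer(0), A = matrix(numeric(0), 0L, 0L)),
         cycle = NA_integer_, n_evals = 0L, last_eval = NULL),
    class = "flock")
}

#' @export
print.flock <- function(x, ...) {
  cat("flock:", x$n, "individuals recorded;",
      length(x$rams), "breeding rams,", length(x$ewes), "breeding ewes;",
      "cycle", x$cycle, "\n")
  invisible(x)
}

## Append individuals; hap_list may be NULL (no stored haplotypes).
## Returns list(flock, ids).
flock_add <- function(fl, sire, dam, sex, birth, hap_list = NULL,
                      alive = TRUE, age = 0L) {
  k <- length(sex)
  ids <- fl$n + seq_len(k)
  fl$sire <- c(fl$sire, as.integer(rep_len(sire, k)))
  fl$dam <- c(fl$dam, as.integer(rep_len(dam, k)))
  fl$sex <- c(fl$sex, as.integer(sex))
  fl$birth <- c(fl$birth, as.integer(rep_len(birth, k)))
  fl$alive <- c(fl$alive, rep_len(alive, k))
  fl$age <- c(fl$age, as.integer(rep_len(age, k)))
  fl$genotyped <- c(fl$genotyped, rep_len(FALSE, k))
  fl$tbv <- rbind(fl$tbv, matrix(NA_real_, k, 2L))
  fl$phen <- rbind(fl$phen, matrix(NA_real_, k, 2L))
  fl$ebv <- rbind(fl$ebv, matrix(NA_real_, k, 2L))
  if (is.null(hap_list)) hap_list <- vector("list", k)
  fl$hap[ids] <- hap_list
  fl$n <- fl$n + k
  list(flock = fl, ids = ids)
}

#' Assemble the founder herdbook population
#'
#' Forms initial diploids by pairing haplotypes drawn from the panel, then
#' simulates the requested number of discrete random-mating generations
#' (recording pedigree links), and declares the final generation the founder
#' breeding population with the configured number of breeding rams and ewes.
#' Founder ages are sampled from the stationary age distribution of the
#' culling model so that the demography is in steady state when breeding
#' cycles start.
#'
#' @param panel A `haplotype_panel` (typically from [mosaic_copy()]).
#' @param map The [genome_map()].
#' @param n_rams,n_ewes Breeding cohort sizes (469 and 7185 at full scale).
#' @param n_random_mating_generations Number of discrete random-mating
#'   generations (default 5).
#' @param spec A [cohort_spec()] supplying replacement numbers and the
#'   culling-weight exponent used for founder age initialisation. Defaults to
#'   `cohort_spec()` scaled so breeding cohort sizes match `n_rams`/`n_ewes`.
#' @param replace Sample panel haplotypes with replacement (default TRUE).
#'   With `replace = FALSE` the panel must contain at least
#'   `2 * (n_rams + n_ewes)` haplotypes.
#' @param start_cycle Breeding cycle at which the programme starts (default
#'   -10, i.e. ten burn-in cycles before cycle 0); founders are recorded as
#'   born one cycle earlier, random-mating generations before that.
#' @param seed Optional integer seed.
#' @return A `flock` whose `rams`/`ewes` hold the founder breeding cohorts.
#' @export
build_founder_population <- function(panel, map, n_rams = 469L,
                                     n_ewes = 7185L,
                                     n_random_mating_generations = 5L,
                                     spec = NULL, replace = TRUE,
                                     start_cycle = -10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_rams <- as.integer(n_rams); n_ewes <- as.integer(n_ewes)
  N <- n_rams + n_ewes
  if (!replace && panel$n_haplotypes < 2L * N)
    stop("panel smaller than 2 * (n_rams + n_ewes) with replacement disabled")
  if (is.null(spec))
    spec <- cohort_spec(n_breeding_rams = n_rams, n_breeding_ewes = n_ewes)
  fl <- new_flock(map)
  g <- as.integer(n_random_mating_generations)
  birth0 <- as.integer(start_cycle) - 1L - g
  # generation 0: direct panel diploids
  hidx <- sample.int(panel$n_haplotypes, 2L * N, replace = replace)
  haps <- lapply(seq_len(N), function(i) {
    panel$alleles[, c(hidx[2L * i - 1L], hidx[2L * i]), drop = FALSE]
  })
  sexes <- sample(rep.int(c(1L, 2L), c(n_rams, n_ewes)))
  res <- flock_add(fl, 0L, 0L, sexes, birth0, haps, alive = FALSE)
  fl <- res$flock; cur <- res$ids
  for (gen in seq_len(g)) {
    males <- cur[fl$sex[cur] == 1L]
    females <- cur[fl$sex[cur] == 2L]
    sires <- sample(males, N, replace = TRUE)
    dams <- sample(females, N, replace = TRUE)
    gam_s <- make_gametes(fl$hap, sires, map)
    gam_d <- make_gametes(fl$hap, dams, map)
    haps <- lapply(seq_len(N), function(i) {
      cbind(gam_s[, i], gam_d[, i], deparse.level = 0L)
    })
    sexes <- sample(rep.int(c(1L, 2L), c(n_rams, n_ewes)))
    res <- flock_add(fl, sires, dams, sexes, birth0 + gen, haps,
                     alive = FALSE)
    fl$hap[cur] <- list(NULL)  # ancestors' haplotypes no longer needed
    fl <- res$flock; cur <- res$ids
  }
  fl$alive[cur] <- TRUE
  fl$rams <- cur[fl$sex[cur] == 1L]
  fl$ewes <- cur[fl$sex[cur] == 2L]
  # steady-state ages per sex
  pr_r <- stationary_age_distribution(spec$n_breeding_rams, spec$n_new_rams,
                                      spec$culling_exponent)
  pr_e <- stationary_age_distribution(spec$n_breeding_ewes, spec$n_new_ewes,
                                      spec$culling_exponent)
  fl$age[fl$rams] <- sample(seq_along(pr_r), length(fl$rams), TRUE, prob = pr_r)
  fl$age[fl$ewes] <- sample(seq_along(pr_e), length(fl$ewes), TRUE, prob = pr_e)
  # kinship bookkeeping starts at the founder cohort (treated as base)
  act <- c(fl$rams, fl$ewes)
  fl$kin <- list(ids = act, A = diag(length(act)))
  fl$cycle <- as.integer(start_cycle)
  fl
}
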