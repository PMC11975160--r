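#' Genome map
#'
#' Defines the marker layout of the simulated genome: a set of autosomes of
#' given genetic length with markers at evenly spaced genetic positions.
#' Adjacent-marker recombination fractions are precomputed with the Haldane
#' map function (no crossover interference, sex-averaged map); markers on
#' different chromosomes segregate independently.
#'
#' @param n_chromosomes Number of autosomes (26 for the sheep karyotype).
#' @param n_markers Total number of biallelic markers across the genome.
#' @param chromosome_length Genetic length of each chromosome in Morgan.
#' @return An object of class `genome_map`: a list with the per-marker
#'   chromosome assignment (`marker_chr`), genetic position in Morgan within
#'   chromosome (`marker_pos`), and the adjacent-interval recombination
#'   fractions `r_adj` (0.5 across chromosome boundaries).
#' @examples
#' map <- genome_map(n_chromosomes = 2, n_markers = 100)
#' @export
genome_map <- function(n_chromosomes = 26L, n_markers = 50000L,
                       chromosome_length = 1.0) {
  n_chromosomes <- as.integer(n_chromosomes)
  n_markers <- as.integer(n_markers)
  if (n_chromosomes < 1L) stop("need at least one chromosome")
  if (n_markers < n_chromosomes)
    stop("configuration error: fewer markers than chromosomes ",
         "(an empty chromosome is not allowed)")
  if (chromosome_length <= 0) stop("chromosome_length must be positive")
  # distribute markers as evenly as possible
  per_chr <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0L) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  marker_chr <- rep.int(seq_len(n_chromosomes), per_chr)
  marker_pos <- unlist(lapply(per_chr, function(k) {
    (seq_len(k) - 0.5) / k * chromosome_length
  }), use.names = FALSE)
  # adjacent recombination fractions (Haldane); 0.5 across chromosome breaks
  d <- diff(marker_pos)
  same <- marker_chr[-1L] == marker_chr[-n_markers]
  r_adj <- ifelse(same, 0.5 * (1 - exp(-2 * d)), 0.5)
  d_adj <- ifelse(same, d, NA_real_)
  structure(
    list(n_chromosomes = n_chromosomes, n_markers = n_markers,
         chromosome_length = chromosome_length, markers_per_chr = per_chr,
         marker_chr = marker_chr, marker_pos = marker_pos,
         r_adj = r_adj, d_adj = d_adj),
    class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", x$n_markers, "markers on", x$n_chromosomes,
      "chromosomes of", x$chromosome_length, "Morgan\n")
  invisible(x)
}

## Parental-origin templates for a batch of gametes.
##
## Under the Haldane model the parental origin of successive markers along a
## chromosome is a two-state Markov chain with switch probability equal to
## the adjacent-marker recombination fraction; the chain starts from a random
## haplotype on each chromosome.  Returns an m x n 0/1 matrix (0 = first
## parental haplotype).
sample_origin_templates <- function(map, n) {
  m <- map$n_markers
  if (n == 0L) return(matrix(integer(0), m, 0L))
  sw <- matrix(stats::runif((m - 1L) * n) < map$r_adj, m - 1L, n)
  start <- sample(c(0L, 1L), n, replace = TRUE)
  tpl <- rbind(start, sw)
  tpl <- apply(tpl, 2L, cumsum) %% 2L
  dimnames(tpl) <- NULL
  tpl
}

## Vectorised meiosis for a batch of parents. `hap` is the per-individual
## haplotype list; `parent_ids` may contain repeats. Returns m x n integer
## matrix of gametes.
make_gametes <- function(hap, parent_ids, map) {
  m <- map$n_markers
  n <- length(parent_ids)
  H1 <- vapply(parent_ids, function(i) hap[[i]][, 1L], integer(m))
  H2 <- vapply(parent_ids, function(i) hap[[i]][, 2L], integer(m))
  if (n == 1L) { H1 <- matrix(H1, m, 1L); H2 <- matrix(H2, m, 1L) }
  tpl <- sample_origin_templates(map, n)
  G <- H1
  pick2 <- tpl == 1L
  G[pick2] <- H2[pick2]
  storage.mode(G) <- "integer"
  G
}

#' Simulate one meiosis
#'
#' Draws a single gamete from a diploid parent. Crossovers follow a Poisson
#' process along genetic distance (Haldane map function, no interference) at
#' marker resolution, with an independent random starting haplotype per
#' chromosome.
#'
#' @param parent Either a two-column 0/1 matrix of parental haplotypes
#'   (markers in rows) or a list with an element `haplotypes` of that form.
#' @param map A [genome_map()].
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of length `map$n_markers`: the gamete.
#' @export
meiosis <- function(parent, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- if (is.list(parent) && !is.null(parent$haplotypes)) parent$haplotypes
       else parent
  if (!is.matrix(h) || ncol(h) != 2L || nrow(h) != map$n_markers)
    stop("parent must carry two haplotypes over the genome map")
  drop(make_gametes(list(h), 1L, map))
}

#' Mate two individuals
#'
#' Produces one offspring from a sire and a dam: one meiosis per parent,
#' parent identifiers recorded, no phenotype and no genotyping flag set.
#'
#' @param sire,dam Individual-like lists with elements `id`, `sex`
#'   (`"male"`/`"female"`) and `haplotypes` (marker x 2 matrix).
#' @param sex Sex of the offspring, `"male"` or `"female"`.
#' @param birth_cycle Integer birth cycle recorded for the offspring.
#' @param map A [genome_map()].
#' @param seed Optional integer seed.
#' @return An individual-like list with the offspring's haplotypes and
#'   pedigree links.
#' @export
mate <- function(sire, dam, sex = c("male", "female"), birth_cycle = 0L,
                 map, seed = NULL) {
  sex <- match.arg(sex)
  if (!is.null(seed)) set.seed(seed)
  if (!identical(sire$sex, "male") || !identical(dam$sex, "female"))
    stop("parent sex mismatch: sire must be male and dam female")
  g_s <- meiosis(sire, map)
  g_d <- meiosis(dam, map)
  list(id = NA_integer_, sex = sex, birth_cycle = as.integer(birth_cycle),
       sire_id = sire$id, dam_id = dam$id,
       haplotypes = cbind(g_s, g_d, deparse.level = 0L),
       genotyped = FALSE, phenotypes = c(NA_real_, NA_real_))
}

#' Observed marker heterozygosity of a cohort
#'
#' Mean, over individuals, of the fraction of markers at which the two
#' haplotypes carry different alleles.
#'
#' @param cohort Either a `flock` (see [build_founder_population()]) together
#'   with `ids`, or a list of individuals with `haplotypes` matrices.
#' @param ids Individual identifiers within the flock (required when `cohort`
#'   is a flock).
#' @return A value in `[0, 1]`.
#' @export
observed_heterozygosity <- function(cohort, ids = NULL) {
  haps <- if (inherits(cohort, "flock")) {
    if (is.null(ids) || length(ids) == 0L) stop("empty cohort")
    lapply(ids, function(i) cohort$hap[[i]])
  } else {
    if (length(cohort) == 0L) stop("empty cohort")
    lapply(cohort, function(x) if (is.list(x)) x$haplotypes else x)
  }
  if (any(vapply(haps, is.null, logical(1L))))
    stop("haplotypes unavailable for some cohort members")
  mean(vapply(haps, function(h) mean(h[, 1L] != h[, 2L]), numeric(1L)))
}
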