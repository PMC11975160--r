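#' Load a run configuration from a YAML file
#'
#' Reads a YAML configuration and merges it over the full-scale defaults of
#' [default_config()]; an empty file yields the defaults. Fields are
#' validated (unknown fields, unknown scenario names, non-positive counts or
#' rates are errors naming the offending field).
#'
#' @param path Path to a YAML file.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- default_config()
  bad <- setdiff(names(raw), names(cfg))
  if (length(bad))
    stop("unknown configuration fields: ", paste(bad, collapse = ", "))
  cfg[names(raw)] <- raw
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("scale", "n_chromosomes", "n_markers", "chromosome_length",
           "n_ancestral", "freq_shape", "switch_rate", "n_mosaic",
           "n_qtl", "target_var", "burn_in", "n_cycles", "window_cycles",
           "ped_depth", "tol", "maxit", "n_runs", "n_runs_diversity")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] <= 0))
      stop("configuration field must be positive: ", f)
  if (cfg$mutation_rate < 0 || cfg$mutation_rate >= 1)
    stop("configuration field out of range: mutation_rate")
  if (length(cfg$h2) != 2L || any(cfg$h2 <= 0) || any(cfg$h2 >= 1))
    stop("configuration field out of range: h2")
  if (abs(cfg$r_g) >= 1)
    stop("configuration field out of range: r_g")
  if (cfg$blend <= 0 || cfg$blend > 1)
    stop("configuration field out of range: blend")
  bad <- setdiff(cfg$scenarios, scenario_table()$name)
  if (length(bad))
    stop("unknown scenario name: ", paste(bad, collapse = ", "))
  # derived cohort counts must be constructible
  cohort_spec(scale = cfg$scale)
  invisible(cfg)
}

#' Write genotypes in PLINK .ped/.map text format
#'
#' One row per individual in the `.ped` file (family id, individual id,
#' sire, dam, sex, phenotype placeholder, then two allele columns per marker
#' coded 1/2); the `.map` file lists chromosome, marker name, genetic
#' position in centiMorgan and a bp-position placeholder.
#'
#' @param fl A `flock`.
#' @param ids Individuals to export (must have stored haplotypes).
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(fl, ids, prefix) {
  map <- fl$map
  alle <- vapply(ids, function(i) {
    h <- fl$hap[[i]]
    if (is.null(h)) stop("no haplotypes stored for id ", i)
    as.integer(t(h)) + 1L   # interleave the two alleles per marker, 1/2
  }, integer(2L * map$n_markers))
  ped <- cbind(1L, ids, fl$sire[ids], fl$dam[ids], fl$sex[ids], 0L,
               t(alle))
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  mp <- data.frame(chr = map$marker_chr,
                   id = paste0("m", seq_len(map$n_markers)),
                   cm = round(100 * map$marker_pos, 4),
                   bp = seq_len(map$n_markers))
  utils::write.table(mp, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Write a pedigree text file
#'
#' Plain whitespace-separated columns id, sire, dam, sex (1 = male,
#' 2 = female), birth cycle; 0 marks an unknown parent.
#'
#' @param fl A `flock`.
#' @param path Output file path.
#' @param ids Individuals to export (default: all recorded).
#' @return Invisibly, `path`.
#' @export
write_pedigree_file <- function(fl, path, ids = seq_len(fl$n)) {
  d <- data.frame(id = ids, sire = fl$sire[ids], dam = fl$dam[ids],
                  sex = fl$sex[ids], birth = fl$birth[ids])
  utils::write.table(d, path, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Deterministic miniature population for examples and tests
#'
#' Builds a small, fully deterministic flock (default: 50 founder breeders,
#' 200 markers on 2 chromosomes, 40 QTL) with trait architecture attached
#' and founders phenotyped — a convenient fixture generated in code rather
#' than stored on disk.
#'
#' @param n_rams,n_ewes Founder cohort sizes.
#' @param n_markers,n_chromosomes Genome size.
#' @param n_qtl Number of QTL.
#' @param seed Integer seed (default 1).
#' @return A list with `flock`, `spec` and `map`.
#' @export
make_test_population <- function(n_rams = 10L, n_ewes = 40L,
                                 n_markers = 200L, n_chromosomes = 2L,
                                 n_qtl = 40L, seed = 1L) {
  set.seed(seed)
  map <- genome_map(n_chromosomes, n_markers)
  panel <- generate_ancestral_panel(map, n_ancestral = 20L)
  donors <- mosaic_copy(panel, map, n_out = 120L)
  spec <- cohort_spec(scale = 1,
                      n_breeding_rams = n_rams, n_breeding_ewes = n_ewes,
                      n_male_lambs = 10L * n_rams,
                      n_female_lambs = 4L * n_ewes)
  fl <- build_founder_population(donors, map, n_rams = n_rams,
                                 n_ewes = n_ewes,
                                 n_random_mating_generations = 2L,
                                 spec = spec)
  fl$arch <- sample_architecture(map, fl, n_qtl = n_qtl)
  founders <- c(fl$rams, fl$ewes)
  fl <- flock_set_tbv(fl, founders)
  fl <- draw_phenotype(fl, founders)
  list(flock = fl, spec = spec, map = map)
}
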