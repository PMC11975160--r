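#' Default simulation configuration
#'
#' Full-scale study conditions: 26 autosomes of 1 Morgan carrying 50,000
#' markers, founder LD from mosaic copying of 100 ancestral haplotypes
#' (switch rate 1/Morgan, 1570 donor haplotypes), five random-mating founder
#' generations, 1000 shared QTL with founder TBV mean 100 / variance 10,
#' heritabilities 0.1 (health) and 0.3 (production), genetic correlation
#' -0.1, 10 burn-in plus 10 evaluated breeding cycles, 10-cycle data window
#' with 7 further cycles of pedigree, genomic blending 0.95, and 100
#' replicate runs (diversity metrics on 20). Any element can be overridden,
#' e.g. `default_config(scale = 0.2, n_markers = 5000)` for desk-scale runs.
#'
#' @param ... Named overrides of configuration elements.
#' @return A named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    scale = 1,
    n_chromosomes = 26L, n_markers = 50000L, chromosome_length = 1.0,
    n_ancestral = 100L, freq_shape = 0.5, switch_rate = 1.0,
    mutation_rate = 0, n_mosaic = 1570L,
    n_random_mating_generations = 5L,
    n_qtl = 1000L, target_mean = 100, target_var = 10,
    h2 = c(0.1, 0.3), r_g = -0.1,
    burn_in = 10L, n_cycles = 10L,
    window_cycles = 10L, ped_depth = 7L, blend = 0.95,
    tol = 1e-8, maxit = 5000L,
    n_runs = 100L, n_runs_diversity = 20L,
    scenarios = scenario_table()$name)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown configuration fields: ",
                          paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  cfg
}

## Found, burn in and return the cycle-0 state of one replicate.
simulate_base_population <- function(config, seed) {
  set.seed(seed)
  spec <- cohort_spec(scale = config$scale,
                      culling_exponent = 2)
  map <- genome_map(config$n_chromosomes, config$n_markers,
                    config$chromosome_length)
  panel <- generate_ancestral_panel(map, config$n_ancestral,
                                    config$freq_shape)
  donors <- mosaic_copy(panel, map, n_out = config$n_mosaic,
                        switch_rate = config$switch_rate,
                        mutation_rate = config$mutation_rate)
  fl <- build_founder_population(
    donors, map, n_rams = spec$n_breeding_rams,
    n_ewes = spec$n_breeding_ewes,
    n_random_mating_generations = config$n_random_mating_generations,
    spec = spec, start_cycle = -as.integer(config$burn_in))
  fl$arch <- sample_architecture(map, fl, n_qtl = config$n_qtl,
                                 target_mean = config$target_mean,
                                 target_var = config$target_var,
                                 h2 = config$h2, r_g = config$r_g)
  founders <- c(fl$rams, fl$ewes)
  fl <- flock_set_tbv(fl, founders)
  fl <- draw_phenotype(fl, founders)
  ped_cfg <- scenario_config("Ped")
  for (b in seq_len(config$burn_in)) {
    step <- run_cycle(fl, ped_cfg, spec,
                      window_cycles = config$window_cycles,
                      ped_depth = config$ped_depth, blend = config$blend,
                      tol = config$tol, maxit = config$maxit)
    fl <- step$flock
  }
  list(flock = fl, spec = spec)
}

#' Run the scenario-comparison experiment
#'
#' For each replicate run, one founder population is generated and burnt in
#' for ten pedigree-BLUP cycles; every scenario then continues from an
#' identical copy of that cycle-0 state with identical downstream random
#' streams (common random numbers), which makes the runs paired across
#' scenarios. Genetic gain is reported in genetic standard deviations,
#' zeroed at cycle 0 per cohort. Ram-cohort pedigree kinship and marker
#' heterozygosity are recorded for the first `n_runs_diversity` runs.
#'
#' @param scenarios Character vector of scenario names (see
#'   [scenario_table()]).
#' @param n_runs Number of replicate runs (at least 2).
#' @param base_seed Integer seed from which all per-run seeds derive.
#' @param config Configuration list from [default_config()].
#' @param progress Print per-run progress lines.
#' @return A `herd_trace`: list with `cohorts` (run, scenario, cycle, cohort,
#'   trait, mean_tbv, gain, accuracy) and `diversity` (run, scenario, cycle,
#'   kinship, heterozygosity, reference-population size).
#' @export
run_experiment <- function(scenarios = scenario_table()$name,
                           n_runs = 2L, base_seed = 1L,
                           config = default_config(), progress = FALSE) {
  if (length(scenarios) == 0L) stop("scenario list is empty")
  bad <- setdiff(scenarios, scenario_table()$name)
  if (length(bad)) stop("unknown scenarios: ", paste(bad, collapse = ", "))
  if (n_runs < 2L) stop("n_runs must be at least 2")
  gsd <- sqrt(config$target_var)
  coh_rows <- list(); div_rows <- list()
  for (r in seq_len(n_runs)) {
    seed_r <- as.integer((as.numeric(base_seed) + 104729 * r) %% 2147483629)
    base <- simulate_base_population(config, seed_r)
    fl0 <- base$flock; spec <- base$spec
    baseline <- snapshot_metrics(fl0)
    keep_div <- r <= config$n_runs_diversity
    for (sc_name in scenarios) {
      sc <- scenario_config(sc_name)
      fl <- fl0
      if (sc$method == "ssGBLUP")
        fl <- flock_add_ref_genotypes(fl, fl$rams)
      set.seed(as.integer((seed_r + 499979) %% 2147483629))
      coh <- list(cbind(run = r, scenario = sc_name, baseline$cohorts))
      div <- list(cbind(run = r, scenario = sc_name,
                        baseline$diversity[, c("cycle", "kinship",
                                               "heterozygosity")],
                        n_genotyped_ref = length(fl$refgeno$ids)))
      for (cy in seq_len(config$n_cycles)) {
        step <- run_cycle(fl, sc, spec,
                          window_cycles = config$window_cycles,
                          ped_depth = config$ped_depth,
                          blend = config$blend,
                          tol = config$tol, maxit = config$maxit)
        fl <- step$flock
        coh[[length(coh) + 1L]] <-
          cbind(run = r, scenario = sc_name, step$metrics$cohorts)
        if (keep_div)
          div[[length(div) + 1L]] <-
            cbind(run = r, scenario = sc_name,
                  step$metrics$diversity[, c("cycle", "kinship",
                                             "heterozygosity",
                                             "n_genotyped_ref")])
      }
      coh <- do.call(rbind, coh)
      # gain in genetic standard deviations, zeroed at cycle 0 per cohort
      base_tbv <- baseline$cohorts$mean_tbv[
        match(paste(coh$cohort, coh$trait),
              paste(baseline$cohorts$cohort, baseline$cohorts$trait))]
      coh$gain <- (coh$mean_tbv - base_tbv) / gsd
      coh$gain[!coh$cohort %in% c("breeding_rams", "breeding_ewes")] <-
        NA_real_
      coh_rows[[length(coh_rows) + 1L]] <- coh
      if (keep_div) div_rows[[length(div_rows) + 1L]] <- do.call(rbind, div)
      if (progress)
        message(sprintf("run %d / %d: %s done (final eval window %d)",
                        r, n_runs, sc_name, fl$last_eval$n_window))
    }
  }
  structure(list(cohorts = do.call(rbind, coh_rows),
                 diversity = do.call(rbind, div_rows),
                 scenarios = scenarios, n_runs = n_runs,
                 config = config),
            class = "herd_trace")
}

#' @export
print.herd_trace <- function(x, ...) {
  cat("herd_trace:", x$n_runs, "runs x", length(x$scenarios),
      "scenarios, cycles 0-", max(x$cohorts$cycle), "\n", sep = " ")
  invisible(x)
}

## Wide run x scenario matrix of one metric at one cycle/cohort/trait.
trace_matrix <- function(trace, metric = "gain", cycle = 10L,
                         cohort = "breeding_rams", trait = "health") {
  d <- trace$cohorts
  d <- d[d$cycle == cycle & d$cohort == cohort & d$trait == trait, ]
  runs <- sort(unique(d$run))
  out <- sapply(trace$scenarios, function(s) {
    v <- d[d$scenario == s, ]
    v[[metric]][match(runs, v$run)]
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = length(runs))
  rownames(out) <- runs
  colnames(out) <- trace$scenarios
  out
}

#' Pairwise paired t-tests with significance letter groups
#'
#' All pairwise paired two-sample Student's t-tests between scenarios on the
#' per-run values of a metric (runs are paired by common random numbers).
#' Letter groups are assigned by a greedy clique cover of the
#' non-significance graph: two scenarios share a letter if and only if their
#' difference is not significant at `alpha`. Degenerate cases are handled
#' explicitly: identical per-run values give p = 1; zero-variance non-zero
#' differences give p = 0.
#'
#' @param trace A `herd_trace` from [run_experiment()].
#' @param metric `"gain"` or `"accuracy"`.
#' @param cycle,cohort,trait Which slice of the trace to test.
#' @param alpha Significance level (default 0.05, no multiplicity
#'   correction).
#' @return List with the p-value matrix `p`, the letter assignment
#'   `letters`, and the scenario means.
#' @export
paired_tests <- function(trace, metric = "gain", cycle = 10L,
                         cohort = "breeding_rams", trait = "health",
                         alpha = 0.05) {
  X <- trace_matrix(trace, metric, cycle, cohort, trait)
  if (anyNA(X)) stop("unpaired traces: missing runs for some scenario")
  k <- ncol(X)
  if (nrow(X) < 2L) stop("paired tests require at least two runs")
  P <- matrix(1, k, k, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- X[, i] - X[, j]
    p <- if (all(d == 0)) 1
         else if (stats::sd(d) == 0) 0
         else stats::t.test(X[, i], X[, j], paired = TRUE)$p.value
    P[i, j] <- P[j, i] <- p
  }
  list(p = P, letters = cld_letters(P, alpha), means = colMeans(X))
}

## Greedy compact-letter display: cliques of the non-significance graph.
cld_letters <- function(P, alpha = 0.05) {
  k <- nrow(P)
  ns <- P >= alpha
  diag(ns) <- TRUE
  cliques <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (c_ in seq_along(cliques)) {
      if (all(ns[i, cliques[[c_]]])) {
        cliques[[c_]] <- c(cliques[[c_]], i)
        placed <- TRUE
      }
    }
    if (!placed) cliques[[length(cliques) + 1L]] <- i
  }
  # ensure every non-significant pair shares a clique
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (!ns[i, j]) next
    shared <- any(vapply(cliques, function(c_) all(c(i, j) %in% c_),
                         logical(1L)))
    if (!shared) {
      cl <- c(i, j)
      for (o in setdiff(seq_len(k), cl))
        if (all(ns[o, cl])) cl <- c(cl, o)
      cliques[[length(cliques) + 1L]] <- sort(cl)
    }
  }
  lab <- rep("", k)
  for (c_ in seq_along(cliques)) {
    lt <- letters[(c_ - 1L) %% 26L + 1L]
    for (i in cliques[[c_]]) lab[i] <- paste0(lab[i], lt)
  }
  names(lab) <- rownames(P)
  lab
}

#' Genetic-gain comparison table
#'
#' Cycle-10 mean true-breeding-value gain (in genetic standard deviations,
#' zeroed at cycle 0) per scenario, cohort and trait, with the SD across
#' runs and paired-test significance letters; scenarios sharing a letter do
#' not differ significantly.
#'
#' @param trace A `herd_trace`.
#' @param cycle Reporting cycle (default 10).
#' @param alpha Significance level for the letter groups.
#' @return A data.frame with columns scenario, cohort, trait, mean, sd,
#'   letters.
#' @export
gain_table <- function(trace, cycle = 10L, alpha = 0.05) {
  single <- trace$n_runs < 2L
  out <- list()
  for (cohort in c("breeding_rams", "breeding_ewes"))
    for (trait in c("health", "production")) {
      X <- trace_matrix(trace, "gain", cycle, cohort, trait)
      lt <- if (single) rep(NA_character_, ncol(X))
            else paired_tests(trace, "gain", cycle, cohort, trait,
                              alpha)$letters
      out[[length(out) + 1L]] <- data.frame(
        scenario = colnames(X), cohort = cohort, trait = trait,
        mean = colMeans(X),
        sd = if (single) NA_real_ else apply(X, 2L, stats::sd),
        letters = lt, row.names = NULL, stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}

#' EBV-accuracy comparison table
#'
#' Cycle-10 mean correlation between true and estimated breeding values per
#' scenario, cohort and trait, with across-run SDs and significance letters.
#'
#' @inheritParams gain_table
#' @return A data.frame with columns scenario, cohort, trait, mean, sd,
#'   letters.
#' @export
accuracy_table <- function(trace, cycle = 10L, alpha = 0.05) {
  out <- list()
  for (cohort in c("male_lambs", "breeding_rams", "female_lambs",
                   "breeding_ewes"))
    for (trait in c("health", "production")) {
      X <- trace_matrix(trace, "accuracy", cycle, cohort, trait)
      lt <- paired_tests(trace, "accuracy", cycle, cohort, trait,
                         alpha)$letters
      out[[length(out) + 1L]] <- data.frame(
        scenario = colnames(X), cohort = cohort, trait = trait,
        mean = colMeans(X), sd = apply(X, 2L, stats::sd),
        letters = lt, row.names = NULL, stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}

#' Relative increase in genetic gain
#'
#' Percent difference of mean cycle-10 gain between a scenario and a
#' reference scenario:
#' `100 * (gain_scenario - gain_reference) / gain_reference`.
#'
#' @param trace A `herd_trace` containing both scenarios.
#' @param scenario,reference Scenario names.
#' @param cohort,trait,cycle Which slice to compare.
#' @return Percent increase (a single number).
#' @export
relative_gain <- function(trace, scenario, reference = "Ped",
                          cohort = "breeding_rams", trait = "health",
                          cycle = 10L) {
  for (s in c(scenario, reference))
    if (!s %in% trace$scenarios) stop("scenario not in trace: ", s)
  g <- function(s) mean(trace_matrix(trace, "gain", cycle, cohort,
                                     trait)[, s])
  gr <- g(reference)
  if (!is.finite(gr) || gr <= 0)
    stop("reference mean gain is not positive; relative gain undefined")
  100 * (g(scenario) - gr) / gr
}
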