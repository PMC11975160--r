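#' Cohort specification of the breeding programme
#'
#' Cohort sizes and demographic rates of the simulated herdbook nucleus.
#' Defaults reproduce the full-scale programme: 469 breeding rams, 7185
#' breeding ewes, 6450 male and 6465 female lambs per cycle, of which the
#' best 2% of males (129) and 20% of females (1293) are selected as new
#' breeders. A single global scale factor multiplies all cohort sizes
#' (counts rounded to the nearest integer) while selection proportions are
#' held fixed, which allows desk-scale runs that preserve selection
#' intensity.
#'
#' @param scale Global population scale factor (default 1).
#' @param n_breeding_rams,n_breeding_ewes Breeding cohort sizes at scale 1.
#' @param n_male_lambs,n_female_lambs Lamb cohort sizes at scale 1.
#' @param male_selected_prop,female_selected_prop Selected proportions
#'   (0.02 and 0.20); the new-breeder counts are derived from these.
#' @param lambs_per_ewe Mean litter size at birth (1.8).
#' @param litter_probs Probabilities of litter sizes 1, 2, 3; must average
#'   `lambs_per_ewe`.
#' @param lamb_loss Lamb mortality before the selection stage (0.1).
#' @param culling_exponent Age-weight exponent for culling (weight
#'   `age^exponent`; default 2, preferring older animals).
#' @return A `cohort_spec` list of validated counts and rates.
#' @export
cohort_spec <- function(scale = 1,
                        n_breeding_rams = 469L, n_breeding_ewes = 7185L,
                        n_male_lambs = 6450L, n_female_lambs = 6465L,
                        male_selected_prop = 0.02,
                        female_selected_prop = 0.20,
                        lambs_per_ewe = 1.8,
                        litter_probs = c(0.3, 0.6, 0.1),
                        lamb_loss = 0.1,
                        culling_exponent = 2) {
  stopifnot(scale > 0, lamb_loss >= 0, lamb_loss < 1,
            male_selected_prop > 0, male_selected_prop <= 1,
            female_selected_prop > 0, female_selected_prop <= 1,
            length(litter_probs) == 3L, abs(sum(litter_probs) - 1) < 1e-8)
  if (abs(sum(litter_probs * (1:3)) - lambs_per_ewe) > 1e-8)
    stop("litter_probs inconsistent with lambs_per_ewe")
  sc <- function(x) max(1L, as.integer(round(x * scale)))
  n_ml <- sc(n_male_lambs); n_fl <- sc(n_female_lambs)
  spec <- list(
    scale = scale,
    n_breeding_rams = max(2L, sc(n_breeding_rams)),
    n_breeding_ewes = max(2L, sc(n_breeding_ewes)),
    n_male_lambs = n_ml, n_female_lambs = n_fl,
    male_selected_prop = male_selected_prop,
    female_selected_prop = female_selected_prop,
    n_new_rams = max(1L, as.integer(round(male_selected_prop * n_ml))),
    n_new_ewes = max(1L, as.integer(round(female_selected_prop * n_fl))),
    lambs_per_ewe = lambs_per_ewe, litter_probs = litter_probs,
    lamb_loss = lamb_loss, culling_exponent = culling_exponent)
  if (spec$n_new_rams > spec$n_breeding_rams ||
      spec$n_new_ewes > spec$n_breeding_ewes)
    stop("replacement counts exceed breeding cohort sizes")
  class(spec) <- "cohort_spec"
  spec
}

#' Genotyping-strategy scenarios
#'
#' The seven compared strategies: the pedigree-BLUP reference (`Ped`, nothing
#' genotyped) and six single-step GBLUP scenarios that differ in the
#' proportion of male and female lambs genotyped. Proportions below 1 imply
#' two-stage selection: lambs are preselected on parent-information EBVs,
#' only the preselected share is genotyped, and final selection uses a second
#' evaluation that includes those genotypes.
#'
#' @param name One of `"Ped"`, `"GSTop25"`, `"GSTop50"`, `"GS100"`,
#'   `"GS100+Top25"`, `"GS100+Top50"`, `"GS100+100"`.
#' @return A `scenario_config` with the evaluation `method` and the male and
#'   female genotyping proportions.
#' @export
scenario_config <- function(name) {
  tab <- scenario_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown scenario name: ", name)
  structure(list(name = tab$name[i], method = tab$method[i],
                 male_genotyping_prop = tab$male_genotyping_prop[i],
                 female_genotyping_prop = tab$female_genotyping_prop[i]),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @export
scenario_table <- function() {
  data.frame(
    name = c("Ped", "GSTop25", "GSTop50", "GS100",
             "GS100+Top25", "GS100+Top50", "GS100+100"),
    method = c("PBLUP", rep("ssGBLUP", 6L)),
    male_genotyping_prop = c(0, 0.25, 0.5, 1, 1, 1, 1),
    female_genotyping_prop = c(0, 0, 0, 0, 0.25, 0.5, 1),
    stringsAsFactors = FALSE)
}

#' Produce the lamb cohorts of one breeding cycle
#'
#' Every breeding ewe is assigned one breeding ram uniformly at random (ram
#' reuse allowed; no artificial insemination). Litter sizes are drawn from
#' \{1, 2, 3\} with the configured probabilities (mean 1.8 lambs born per
#' ewe), each lamb survives to the selection stage with probability
#' `1 - lamb_loss`, and sex is assigned 50/50. Surviving lambs are then
#' truncated (or topped up by additional litters) to exactly the configured
#' male and female lamb cohort sizes, which keeps the derived new-breeder
#' counts exact.
#'
#' @param fl A `flock`.
#' @param spec A [cohort_spec()].
#' @return `list(flock, males, females)` with the new lamb ids.
#' @export
produce_lambs <- function(fl, spec) {
  if (length(fl$rams) == 0L || length(fl$ewes) == 0L)
    stop("empty breeding cohorts")
  ram_of <- sample(fl$rams, length(fl$ewes), replace = TRUE)
  need_m <- spec$n_male_lambs; need_f <- spec$n_female_lambs
  sm <- im <- sf <- if_ <- integer(0)
  guard <- 0L
  while (length(sm) < need_m || length(sf) < need_f) {
    guard <- guard + 1L
    if (guard > 50L) stop("lamb production failed to reach cohort sizes")
    litter <- sample(1:3, length(fl$ewes), replace = TRUE,
                     prob = spec$litter_probs)
    dams <- rep.int(fl$ewes, litter)
    sires <- rep.int(ram_of, litter)
    k <- length(dams)
    surv <- stats::runif(k) < 1 - spec$lamb_loss
    male <- stats::runif(k) < 0.5
    sm <- c(sm, sires[surv & male]); im <- c(im, dams[surv & male])
    sf <- c(sf, sires[surv & !male]); if_ <- c(if_, dams[surv & !male])
  }
  pick_m <- sample(length(sm))[seq_len(need_m)]
  pick_f <- sample(length(sf))[seq_len(need_f)]
  sires_all <- c(sm[pick_m], sf[pick_f])
  dams_all <- c(im[pick_m], if_[pick_f])
  sexes <- rep.int(c(1L, 2L), c(need_m, need_f))
  gam_s <- make_gametes(fl$hap, sires_all, fl$map)
  gam_d <- make_gametes(fl$hap, dams_all, fl$map)
  nl <- need_m + need_f
  haps <- lapply(seq_len(nl), function(i) {
    cbind(gam_s[, i], gam_d[, i], deparse.level = 0L)
  })
  res <- flock_add(fl, sires_all, dams_all, sexes, fl$cycle, haps,
                   alive = TRUE, age = 0L)
  fl <- res$flock
  # TBVs directly from the gametes at the QTL
  if (!is.null(fl$arch)) {
    qtl <- fl$arch$qtl
    C <- gam_s[qtl, , drop = FALSE] + gam_d[qtl, , drop = FALSE]
    fl$tbv[res$ids, ] <- tbv_from_counts(C, fl$arch)
  }
  list(flock = fl, males = res$ids[seq_len(need_m)],
       females = res$ids[need_m + seq_len(need_f)])
}

#' Preselect lambs for genotyping
#'
#' First-stage truncation selection: the top `ceiling(proportion * n)` of the
#' cohort by total merit index, computed from an evaluation that did not use
#' the candidates' own genotypes or phenotypes. Ties are broken by id order,
#' so the step is deterministic given the index values.
#'
#' @param ids Candidate ids.
#' @param index Total merit index values aligned with `ids`.
#' @param proportion Proportion to retain, in (0, 1].
#' @return The preselected ids.
#' @export
preselect <- function(ids, index, proportion) {
  if (!is.numeric(proportion) || proportion <= 0 || proportion > 1)
    stop("proportion must lie in (0, 1]")
  k <- as.integer(ceiling(proportion * length(ids)))
  ids[order(-index, ids)][seq_len(k)]
}

#' Select new breeding animals
#'
#' Second-stage truncation selection: the best `n_select` of the (possibly
#' preselected) cohort by total merit index. The selected animals are the
#' cycle's new breeding rams or ewes; they are phenotyped afterwards and,
#' under genotyping scenarios, join the reference population.
#'
#' @param ids Candidate ids (the preselected cohort).
#' @param index Total merit index values aligned with `ids`.
#' @param n_select Number to select.
#' @return The selected ids.
#' @export
select_new_breeders <- function(ids, index, n_select) {
  if (n_select > length(ids))
    stop("n_select exceeds the size of the preselected cohort")
  ids[order(-index, ids)][seq_len(n_select)]
}

#' Cull old breeders and install the replacements
#'
#' Exactly as many old breeding animals are removed per sex as new breeders
#' enter, sampled without replacement with age-dependent weights
#' `age^culling_exponent` (older animals culled preferentially). Survivors
#' and new breeders form the next cycle's breeding cohorts at constant size;
#' ages are incremented.
#'
#' @param fl A `flock`.
#' @param spec A [cohort_spec()].
#' @param new_rams,new_ewes Ids of the selected new breeders.
#' @return The updated flock.
#' @export
cull_and_replace <- function(fl, spec, new_rams, new_ewes) {
  cull1 <- function(ids, n_cull, expo) {
    if (n_cull == 0L) return(integer(0))
    w <- as.numeric(fl$age[ids])^expo
    if (all(w == 0)) w <- rep(1, length(ids))
    sample(ids, n_cull, prob = w)
  }
  out_r <- cull1(fl$rams, length(new_rams), spec$culling_exponent)
  out_e <- cull1(fl$ewes, length(new_ewes), spec$culling_exponent)
  # kinship bookkeeping: add new breeders (their parents are still present),
  # then drop the culled
  fl <- kin_add(fl, c(new_rams, new_ewes))
  fl <- kin_drop(fl, c(out_r, out_e))
  fl$alive[c(out_r, out_e)] <- FALSE
  fl$hap[c(out_r, out_e)] <- list(NULL)
  fl$rams <- c(setdiff(fl$rams, out_r), new_rams)
  fl$ewes <- c(setdiff(fl$ewes, out_e), new_ewes)
  keep <- c(fl$rams, fl$ewes)
  fl$age[keep] <- fl$age[keep] + 1L
  fl
}

## Incremental pedigree-relationship bookkeeping over the active breeding
## population (base = founder cohort). New animals' rows follow from their
## parents' rows; exact because parents are active when offspring are added.
kin_add <- function(fl, ids) {
  if (length(ids) == 0L) return(fl)
  K <- fl$kin$A; kid <- fl$kin$ids
  sp <- match(fl$sire[ids], kid)
  dp <- match(fl$dam[ids], kid)
  if (anyNA(sp) || anyNA(dp))
    stop("kinship update: parents not in the active set")
  R <- 0.5 * (K[sp, , drop = FALSE] + K[dp, , drop = FALSE])
  NN <- 0.25 * (K[sp, sp, drop = FALSE] + K[sp, dp, drop = FALSE] +
                K[dp, sp, drop = FALSE] + K[dp, dp, drop = FALSE])
  diag(NN) <- 1 + 0.5 * K[cbind(sp, dp)]
  fl$kin$A <- rbind(cbind(K, t(R)), cbind(R, NN))
  fl$kin$ids <- c(kid, ids)
  fl
}

kin_drop <- function(fl, ids) {
  if (length(ids) == 0L) return(fl)
  keep <- !(fl$kin$ids %in% ids)
  fl$kin$A <- fl$kin$A[keep, keep, drop = FALSE]
  fl$kin$ids <- fl$kin$ids[keep]
  fl
}

## Selection index over a candidate cohort. "sd_scaled" standardizes each
## trait's EBV to unit spread within the cohort before the equal-weight sum,
## so both traits receive equal realized emphasis regardless of how much EBV
## variance the evaluation produces per trait; "raw" is the plain sum.
selection_index <- function(ebv, scaling = c("sd_scaled", "raw")) {
  scaling <- match.arg(scaling)
  if (scaling == "raw") return(rowSums(ebv))
  s <- apply(ebv, 2L, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  rowSums(sweep(ebv, 2L, s, `/`))
}

#' Run one breeding cycle
#'
#' One cycle of the programme: reproduction, genetic evaluation(s),
#' preselection and genotyping as configured by the scenario, final
#' truncation selection of new breeding rams and ewes, phenotyping of the
#' new breeders, reference-population update, and age-based culling with
#' replacement. Scenarios without a preselection stage (Ped, GS100,
#' GS100+100) perform a single evaluation per cycle; two-stage scenarios
#' perform two (the first without the candidates' own genotypes).
#'
#' Selection at every stage ranks candidates on the total merit index. With
#' `index_scaling = "sd_scaled"` (the default) each trait's EBV is
#' standardized to unit spread within the candidate cohort before the
#' equal-weight sum, giving both traits equal realized emphasis; `"raw"`
#' sums the EBVs unscaled.
#'
#' @param fl A `flock`.
#' @param scenario A [scenario_config()].
#' @param spec A [cohort_spec()].
#' @param window_cycles,ped_depth,blend,tol,maxit Evaluation controls, see
#'   [evaluate_flock()].
#' @param index_scaling `"sd_scaled"` or `"raw"`, see Details.
#' @return `list(flock, metrics)` where `metrics` is the per-cycle snapshot
#'   (cohort means, accuracies, kinship, heterozygosity). Accuracies for the
#'   breeding cohorts refer to the cohorts in service at the cycle's
#'   evaluation; mean TBVs refer to the post-replacement cohorts.
#' @export
run_cycle <- function(fl, scenario, spec, window_cycles = 10L,
                      ped_depth = 7L, blend = 0.95, tol = 1e-8,
                      maxit = 5000L, index_scaling = "sd_scaled") {
  fl$cycle <- fl$cycle + 1L
  L <- produce_lambs(fl, spec)
  fl <- L$flock
  pm <- scenario$male_genotyping_prop
  pf <- scenario$female_genotyping_prop
  two_stage <- (pm > 0 && pm < 1) || (pf > 0 && pf < 1)
  cand <- c(L$males, L$females)
  wcache <- build_eval_window(
    fl, cand, if (scenario$method == "ssGBLUP") fl$refgeno$ids
              else integer(0),
    window_cycles, ped_depth)
  ev <- function(f, extra) evaluate_flock(
    f, scenario$method, candidate_ids = cand, extra_geno_ids = extra,
    window_cycles = window_cycles, ped_depth = ped_depth, blend = blend,
    tol = tol, maxit = maxit, window_cache = wcache)
  idx <- function(ids) selection_index(fl$ebv[ids, , drop = FALSE],
                                       index_scaling)
  if (two_stage) {
    fl <- ev(fl, integer(0))
    presel_m <- if (pm > 0 && pm < 1) preselect(L$males, idx(L$males), pm)
      else L$males
    presel_f <- if (pf > 0 && pf < 1) preselect(L$females, idx(L$females), pf)
      else L$females
  } else {
    presel_m <- L$males
    presel_f <- L$females
  }
  geno_now <- c(if (pm > 0) presel_m else integer(0),
                if (pf > 0) presel_f else integer(0))
  fl <- ev(fl, geno_now)
  new_rams <- select_new_breeders(presel_m, idx(presel_m), spec$n_new_rams)
  new_ewes <- select_new_breeders(presel_f, idx(presel_f), spec$n_new_ewes)
  fl <- draw_phenotype(fl, c(new_rams, new_ewes))
  fl <- flock_add_ref_genotypes(fl, intersect(c(new_rams, new_ewes),
                                              geno_now))
  service_rams <- fl$rams; service_ewes <- fl$ewes
  fl <- cull_and_replace(fl, spec, new_rams, new_ewes)
  # discard haplotypes of lambs that left the programme
  gone <- setdiff(cand, c(new_rams, new_ewes))
  fl$alive[gone] <- FALSE
  fl$hap[gone] <- list(NULL)
  metrics <- snapshot_metrics(fl, males = L$males, females = L$females,
                              n_genotyped_now = length(geno_now),
                              service_rams = service_rams,
                              service_ewes = service_ewes)
  list(flock = fl, metrics = metrics)
}

## Per-cycle metrics: cohort mean TBVs and EBV accuracies from the cycle's
## final evaluation, plus ram-cohort pedigree kinship and marker
## heterozygosity. Accuracy for the breeding cohorts is computed on the
## cohorts in service at the evaluation (all of which have own records);
## mean TBV is that of the post-replacement cohorts.
snapshot_metrics <- function(fl, males = integer(0), females = integer(0),
                             n_genotyped_now = NA_integer_,
                             service_rams = NULL, service_ewes = NULL) {
  if (is.null(service_rams)) service_rams <- fl$rams
  if (is.null(service_ewes)) service_ewes <- fl$ewes
  cohorts <- list(breeding_rams = fl$rams, breeding_ewes = fl$ewes)
  acc_cohorts <- list(breeding_rams = service_rams,
                      breeding_ewes = service_ewes)
  if (length(males)) cohorts$male_lambs <- acc_cohorts$male_lambs <- males
  if (length(females))
    cohorts$female_lambs <- acc_cohorts$female_lambs <- females
  rows <- lapply(names(cohorts), function(nm) {
    ids <- cohorts[[nm]]
    aid <- acc_cohorts[[nm]]
    acc <- tryCatch(
      ebv_accuracy(fl$tbv[aid, , drop = FALSE], fl$ebv[aid, , drop = FALSE]),
      error = function(e) c(NA_real_, NA_real_))
    data.frame(cycle = fl$cycle, cohort = nm,
               trait = c("health", "production"),
               mean_tbv = colMeans(fl$tbv[ids, , drop = FALSE]),
               accuracy = acc, stringsAsFactors = FALSE)
  })
  list(cohorts = do.call(rbind, rows),
       diversity = data.frame(
         cycle = fl$cycle,
         kinship = flock_ram_kinship(fl),
         heterozygosity = observed_heterozygosity(fl, fl$rams),
         n_genotyped_ref = length(fl$refgeno$ids),
         n_genotyped_now = n_genotyped_now,
         stringsAsFactors = FALSE))
}
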