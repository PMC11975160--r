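test_that("cohort spec derives selected counts from the selection proportions", {
  spec <- cohort_spec()
  expect_equal(spec$n_new_rams, 129L)     # 2% of 6450
  expect_equal(spec$n_new_ewes, 1293L)    # 20% of 6465
  expect_equal(spec$n_breeding_rams, 469L)
  expect_equal(spec$n_breeding_ewes, 7185L)
  sp <- cohort_spec(scale = 0.2)
  expect_equal(sp$n_male_lambs, 1290L)
  expect_equal(sp$n_new_rams, round(0.02 * sp$n_male_lambs))
  expect_equal(sp$n_new_ewes, round(0.20 * sp$n_female_lambs))
  expect_error(cohort_spec(litter_probs = c(0.5, 0.4, 0.1)),
               "inconsistent")
})

test_that("scenario table matches the seven genotyping strategies", {
  tab <- scenario_table()
  expect_equal(nrow(tab), 7L)
  ped <- scenario_config("Ped")
  expect_equal(ped$method, "PBLUP")
  expect_equal(ped$male_genotyping_prop, 0)
  g25 <- scenario_config("GSTop25")
  expect_equal(g25$method, "ssGBLUP")
  expect_equal(g25$male_genotyping_prop, 0.25)
  expect_equal(g25$female_genotyping_prop, 0)
  gff <- scenario_config("GS100+100")
  expect_equal(gff$female_genotyping_prop, 1)
  expect_error(scenario_config("GS999"), "unknown scenario")
})

test_that("lamb production hits exact cohort sizes with parents from the breeding cohorts", {
  tp <- tiny_pop()
  fl <- tp$flock
  fl$cycle <- fl$cycle + 1L
  set.seed(6)
  L <- produce_lambs(fl, tp$spec)
  expect_length(L$males, tp$spec$n_male_lambs)
  expect_length(L$females, tp$spec$n_female_lambs)
  lambs <- c(L$males, L$females)
  expect_true(all(L$flock$sire[lambs] %in% fl$rams))
  expect_true(all(L$flock$dam[lambs] %in% fl$ewes))
  expect_true(all(L$flock$sex[L$males] == 1L))
  expect_true(all(is.na(L$flock$phen[lambs, ])))
  expect_true(all(!is.na(L$flock$tbv[lambs, ])))
  bad <- fl; bad$rams <- integer(0)
  expect_error(produce_lambs(bad, tp$spec), "empty breeding cohorts")
})

test_that("preselection takes the ceiling share with deterministic tie-breaks", {
  ids <- 101:110
  idx <- c(5, 3, 9, 1, 1, 7, 2, 8, 6, 4)
  top <- preselect(ids, idx, 0.25)  # ceiling(2.5) = 3
  expect_length(top, 3L)
  expect_equal(top, ids[order(-idx, ids)][1:3])
  expect_equal(preselect(ids, idx, 1), ids[order(-idx, ids)])
  # all-equal index: first ids win
  expect_equal(preselect(ids, rep(0, 10), 0.3), 101:103)
  expect_equal(length(preselect(seq_len(6450), rnorm(6450), 0.25)), 1613L)
  expect_error(preselect(ids, idx, 0), "proportion")
  expect_error(preselect(ids, idx, 1.2), "proportion")
})

test_that("truncation selection of new breeders is optimal and size-checked", {
  set.seed(7)
  ids <- 1:40
  idx <- rnorm(40)
  sel <- select_new_breeders(ids, idx, 8L)
  expect_length(sel, 8L)
  best <- mean(idx[sel])
  for (k in 1:20) expect_gte(best, mean(idx[sample(40L, 8L)]))
  expect_equal(sort(select_new_breeders(ids, idx, 40L)), ids)
  expect_error(select_new_breeders(ids, idx, 41L), "exceeds")
})

test_that("culling prefers old animals and keeps cohort sizes constant", {
  tp <- tiny_pop()
  fl <- tp$flock
  # ages under the stationary start are spread out
  expect_gt(max(fl$age[fl$rams]), min(fl$age[fl$rams]))
  set.seed(8)
  reps <- 300L
  mean_age_culled <- mean_age_survivors <- numeric(reps)
  for (r in seq_len(reps)) {
    w <- as.numeric(fl$age[fl$ewes])^2
    out <- sample(fl$ewes, 10L, prob = w)
    mean_age_culled[r] <- mean(fl$age[out])
    mean_age_survivors[r] <- mean(fl$age[setdiff(fl$ewes, out)])
  }
  expect_gt(mean(mean_age_culled), mean(mean_age_survivors))
})

test_that("one cycle keeps breeding cohorts constant and phenotypes only new breeders", {
  tp <- tiny_pop()
  fl <- tp$flock
  n_rams0 <- length(fl$rams); n_ewes0 <- length(fl$ewes)
  set.seed(9)
  st <- run_cycle(fl, scenario_config("Ped"), tp$spec)
  fl2 <- st$flock
  expect_length(fl2$rams, n_rams0)
  expect_length(fl2$ewes, n_ewes0)
  # exactly the configured number of new breeders entered
  expect_equal(sum(fl2$birth[fl2$rams] == fl2$cycle), tp$spec$n_new_rams)
  expect_equal(sum(fl2$birth[fl2$ewes] == fl2$cycle), tp$spec$n_new_ewes)
  # phenotyped this cycle == the new breeders only
  new_phen <- which(!is.na(fl2$phen[, 1L]) & fl2$birth == fl2$cycle)
  expect_setequal(new_phen, c(fl2$rams[fl2$birth[fl2$rams] == fl2$cycle],
                              fl2$ewes[fl2$birth[fl2$ewes] == fl2$cycle]))
  # Ped: single evaluation per cycle, nothing genotyped
  expect_equal(fl2$n_evals - fl$n_evals, 1L)
  expect_equal(length(fl2$refgeno$ids), 0L)
})

test_that("two-stage scenarios evaluate twice and genotype only the preselected share", {
  tp <- tiny_pop()
  fl <- tp$flock
  fl <- herdsim:::flock_add_ref_genotypes(fl, fl$rams)  # cycle-0 ram panel
  n_ref0 <- length(fl$refgeno$ids)
  set.seed(10)
  st <- run_cycle(fl, scenario_config("GSTop25"), tp$spec)
  fl2 <- st$flock
  expect_equal(fl2$n_evals - fl$n_evals, 2L)
  expect_equal(st$metrics$diversity$n_genotyped_now,
               ceiling(0.25 * tp$spec$n_male_lambs))
  # reference population grows by the new breeding rams only
  expect_equal(length(fl2$refgeno$ids), n_ref0 + tp$spec$n_new_rams)
})

test_that("GS100+100 genotypes every lamb and single-steps in one evaluation", {
  tp <- tiny_pop()
  fl <- tp$flock
  fl <- herdsim:::flock_add_ref_genotypes(fl, fl$rams)
  set.seed(11)
  st <- run_cycle(fl, scenario_config("GS100+100"), tp$spec)
  expect_equal(st$flock$n_evals - fl$n_evals, 1L)
  expect_equal(st$metrics$diversity$n_genotyped_now,
               tp$spec$n_male_lambs + tp$spec$n_female_lambs)
  # both sexes' selected animals join the reference population
  expect_equal(length(st$flock$refgeno$ids),
               length(fl$rams) + tp$spec$n_new_rams + tp$spec$n_new_ewes)
})

test_that("reference population grows linearly in male-only scenarios", {
  tp <- tiny_pop()
  fl <- tp$flock
  fl <- herdsim:::flock_add_ref_genotypes(fl, fl$rams)
  set.seed(12)
  for (cyc in 1:3) {
    st <- run_cycle(fl, scenario_config("GS100"), tp$spec)
    fl <- st$flock
    expect_equal(length(fl$refgeno$ids),
                 length(tp$flock$rams) + cyc * tp$spec$n_new_rams)
  }
})

test_that("incremental kinship bookkeeping matches the pedigree matrix", {
  tp <- tiny_pop()
  fl <- tp$flock
  set.seed(13)
  for (cyc in 1:2) fl <- run_cycle(fl, scenario_config("Ped"), tp$spec)$flock
  # oracle: tabular A on the recorded pedigree with founders as base
  founders <- c(tp$flock$rams, tp$flock$ewes)
  ids <- fl$kin$ids
  repeat {
    par <- setdiff(unique(c(fl$sire[setdiff(ids, founders)],
                            fl$dam[setdiff(ids, founders)])), 0L)
    new <- setdiff(par, ids)
    if (!length(new)) break
    ids <- c(ids, new)
  }
  ids <- sort(ids)
  sire <- ifelse(!(ids %in% founders), match(fl$sire[ids], ids, nomatch = 0L),
                 0L)
  dam <- ifelse(!(ids %in% founders), match(fl$dam[ids], ids, nomatch = 0L),
                0L)
  A <- build_A(list(sire = as.integer(sire), dam = as.integer(dam)))
  pos <- match(fl$kin$ids, ids)
  expect_equal(unname(fl$kin$A), unname(A[pos, pos]), tolerance = 1e-12)
})
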