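# A miniature two-scenario experiment reused by several blocks.
mini_trace <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_config(scale = 0.01, n_markers = 300L,
                            n_chromosomes = 3L, n_ancestral = 20L,
                            n_mosaic = 120L, n_qtl = 60L,
                            burn_in = 2L, n_cycles = 3L)
      cache <<- run_experiment(c("Ped", "GS100"), n_runs = 2L,
                               base_seed = 11L, config = cfg)
    }
    cache
  }
})

test_that("experiment trace has the run x scenario x cycle structure", {
  tr <- mini_trace()
  d <- tr$cohorts
  expect_setequal(unique(d$scenario), c("Ped", "GS100"))
  expect_setequal(unique(d$run), 1:2)
  # cycle-0 baseline plus 3 cycles for the breeding cohorts
  ped_rams <- d[d$scenario == "Ped" & d$run == 1 &
                  d$cohort == "breeding_rams" & d$trait == "health", ]
  expect_equal(sort(ped_rams$cycle), 0:3)
  expect_equal(ped_rams$gain[ped_rams$cycle == 0], 0)
  expect_error(run_experiment(character(0)), "empty")
  expect_error(run_experiment("Nope", n_runs = 2L), "unknown scenarios")
})

test_that("scenarios within a run share the identical cycle-0 state", {
  tr <- mini_trace()
  d <- tr$cohorts[tr$cohorts$cycle == 0, ]
  for (r in 1:2) for (co in c("breeding_rams", "breeding_ewes"))
    for (trt in c("health", "production")) {
      v <- d$mean_tbv[d$run == r & d$cohort == co & d$trait == trt]
      expect_equal(length(unique(round(v, 10))), 1L)
    }
})

test_that("diversity metrics are recorded per cycle with the reference size", {
  tr <- mini_trace()
  dv <- tr$diversity
  g <- dv[dv$scenario == "GS100" & dv$run == 1, ]
  expect_equal(sort(g$cycle), 0:3)
  expect_true(all(diff(g$n_genotyped_ref) > 0))
  expect_true(all(g$kinship >= 0 & g$kinship < 1))
  expect_true(all(g$heterozygosity > 0 & g$heterozygosity < 1))
})

test_that("paired t-tests handle identical, one-sided and degenerate differences", {
  tr <- mini_trace()
  # identical values in two scenarios -> p = 1, shared letter
  tr2 <- tr
  tr2$cohorts$gain[tr2$cohorts$scenario == "GS100"] <-
    tr2$cohorts$gain[tr2$cohorts$scenario == "Ped"]
  pt <- paired_tests(tr2, "gain", cycle = 3L)
  expect_equal(pt$p["Ped", "GS100"], 1)
  expect_true(grepl(substr(pt$letters["Ped"], 1, 1), pt$letters["GS100"]))
  # large one-signed differences -> distinct letters (zero-variance flag)
  tr3 <- tr
  sel <- tr3$cohorts$scenario == "GS100"
  tr3$cohorts$gain[sel] <- tr3$cohorts$gain[!sel][seq_len(sum(sel))] + 5
  pt3 <- paired_tests(tr3, "gain", cycle = 3L)
  expect_equal(pt3$p["Ped", "GS100"], 0)
  expect_false(any(strsplit(pt3$letters["Ped"], "")[[1]] %in%
                     strsplit(pt3$letters["GS100"], "")[[1]]))
})

test_that("degenerate paired t statistic has a closed-form guard", {
  # diffs (1,1,1,1): mean/SE undefined (sd = 0) -> flagged p = 0
  P <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  lt <- herdsim:::cld_letters(P, 0.05)
  expect_false(lt["A"] == lt["B"])
})

test_that("letter groups are consistent with the pairwise outcomes", {
  # three scenarios: A~B non-significant, both differ from C
  P <- matrix(c(1, .5, .01, .5, 1, .02, .01, .02, 1), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  lt <- herdsim:::cld_letters(P, 0.05)
  shared <- function(a, b)
    any(strsplit(lt[a], "")[[1]] %in% strsplit(lt[b], "")[[1]])
  expect_true(shared("A", "B"))
  expect_false(shared("A", "C"))
  expect_false(shared("B", "C"))
})

test_that("relative gain follows its defining arithmetic", {
  tr <- mini_trace()
  # means 2.0 vs 1.6 -> 25%; scenario == reference -> 0%
  tr4 <- tr
  tr4$cohorts$gain[tr4$cohorts$scenario == "Ped" & tr4$cohorts$cycle == 3 &
                     tr4$cohorts$cohort == "breeding_rams" &
                     tr4$cohorts$trait == "health"] <- 1.6
  tr4$cohorts$gain[tr4$cohorts$scenario == "GS100" & tr4$cohorts$cycle == 3 &
                     tr4$cohorts$cohort == "breeding_rams" &
                     tr4$cohorts$trait == "health"] <- 2.0
  expect_equal(relative_gain(tr4, "GS100", "Ped", cycle = 3L), 25)
  expect_equal(relative_gain(tr4, "Ped", "Ped", cycle = 3L), 0)
  expect_error(relative_gain(tr, "GS100", "Nope"), "not in trace")
})

test_that("gain and accuracy tables summarise all scenario/cohort/trait cells", {
  tr <- mini_trace()
  gt <- gain_table(tr, cycle = 3L)
  expect_equal(nrow(gt), 2L * 2L * 2L)
  expect_true(all(c("mean", "sd", "letters") %in% names(gt)))
  at <- accuracy_table(tr, cycle = 3L)
  expect_equal(nrow(at), 2L * 4L * 2L)
  expect_true(all(is.finite(at$mean)))
})
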