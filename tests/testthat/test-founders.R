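test_that("ancestral panel has the right shape, no monomorphic markers, and is reproducible", {
  map <- genome_map(2L, 10L)
  p <- generate_ancestral_panel(map, n_ancestral = 2L, seed = 1L)
  expect_equal(dim(p$alleles), c(10L, 2L))
  expect_true(all(p$alleles %in% 0:1))
  rs <- rowSums(p$alleles)
  expect_true(all(rs > 0 & rs < 2L))
  p2 <- generate_ancestral_panel(map, n_ancestral = 2L, seed = 1L)
  expect_identical(p$alleles, p2$alleles)
  expect_error(generate_ancestral_panel(map, n_ancestral = 1L), "at least 2")
  expect_error(generate_ancestral_panel(map, freq_shape = 0), "positive")
})

test_that("allele-frequency spectrum matches an independent Beta(0.5, 0.5) draw", {
  m <- 100000L
  map <- genome_map(26L, m)
  n_anc <- 60L
  pan <- generate_ancestral_panel(map, n_ancestral = n_anc, freq_shape = 0.5,
                                  seed = 2L)
  freq <- rowMeans(pan$alleles)
  maf <- pmin(freq, 1 - freq)
  # oracle: same construction, independent implementation
  set.seed(99)
  p0 <- rbeta(m, 0.5, 0.5)
  cnt <- rbinom(m, n_anc, p0)
  while (any(cnt == 0L | cnt == n_anc)) {
    i <- cnt == 0L | cnt == n_anc
    p0[i] <- rbeta(sum(i), 0.5, 0.5)
    cnt[i] <- rbinom(sum(i), n_anc, p0[i])
  }
  f0 <- cnt / n_anc
  maf0 <- pmin(f0, 1 - f0)
  expect_lt(abs(mean(maf) - mean(maf0)), 0.005)
  # U-shape: extreme-frequency bins heavier than the central bin
  h <- hist(freq, breaks = seq(0, 1, 0.1), plot = FALSE)$counts
  expect_gt(h[1], h[5])
  expect_gt(h[10], h[6])
})

test_that("mosaic copying creates LD that decays with genetic distance", {
  # 5 chromosomes x 101 markers, 10 ancestral haplotypes: many marker pairs
  # at each distance keep the Monte-Carlo noise well below the decay signal
  map <- genome_map(5L, 505L)
  within_chr_lag <- function(x, lag) {
    v <- c()
    for (ch in 1:5) {
      idx <- which(map$marker_chr == ch)
      for (i in idx[seq_len(length(idx) - lag)]) {
        a <- x[i, ]; b <- x[i + lag, ]
        if (sd(a) > 0 && sd(b) > 0) v <- c(v, cor(a, b)^2)
      }
    }
    mean(v)
  }
  r2_1 <- r2_10 <- r2_inf <- numeric(3)
  for (s in 1:3) {
    pan <- generate_ancestral_panel(map, n_ancestral = 10L, seed = 3L + s)
    mos <- mosaic_copy(pan, map, n_out = 400L, switch_rate = 1.0,
                       seed = 40L + s)
    r2_1[s] <- within_chr_lag(mos$alleles, 1L)    # ~1 cM apart
    r2_10[s] <- within_chr_lag(mos$alleles, 10L)  # ~10 cM apart
    # near-infinite switch rate destroys LD down to the independence level
    mos_inf <- mosaic_copy(pan, map, n_out = 400L, switch_rate = 500,
                           seed = 50L + s)
    r2_inf[s] <- within_chr_lag(mos_inf$alleles, 1L)
  }
  expect_gt(mean(r2_1), mean(r2_10))
  expect_lt(mean(r2_inf), mean(r2_1))
  expect_lt(mean(r2_inf), 3 / 400 + 0.02)
})

test_that("mean r-squared is non-increasing over distance bins", {
  m <- 121L
  map <- genome_map(1L, m)
  vals <- matrix(0, 3L, 3L)
  for (s in 1:3) {
    pan <- generate_ancestral_panel(map, n_ancestral = 20L, seed = 10L + s)
    mos <- mosaic_copy(pan, map, n_out = 300L, switch_rate = 1.0,
                       seed = 20L + s)
    for (k in 1:3) {
      lag <- c(2L, 12L, 40L)[k]
      v <- vapply(seq_len(m - lag), function(i) {
        a <- mos$alleles[i, ]; b <- mos$alleles[i + lag, ]
        if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
        cor(a, b)^2
      }, numeric(1))
      vals[s, k] <- mean(v, na.rm = TRUE)
    }
  }
  avg <- colMeans(vals)
  expect_true(all(diff(avg) <= 0))
})

test_that("mosaic panel size and determinism contracts hold", {
  map <- genome_map(2L, 60L)
  pan <- generate_ancestral_panel(map, n_ancestral = 10L, seed = 6L)
  mos <- mosaic_copy(pan, map, n_out = 1570L, seed = 7L)
  expect_equal(mos$n_haplotypes, 1570L)
  expect_equal(dim(mos$alleles), c(60L, 1570L))
  mos2 <- mosaic_copy(pan, map, n_out = 1570L, seed = 7L)
  expect_identical(mos$alleles, mos2$alleles)
  expect_error(mosaic_copy(structure(list(alleles = NULL, n_haplotypes = 0L),
                                     class = "haplotype_panel"), map),
               "empty input panel")
})

test_that("founder population has configured sizes, sexes and pedigree depth", {
  map <- genome_map(2L, 80L)
  pan <- generate_ancestral_panel(map, n_ancestral = 20L, seed = 8L)
  mos <- mosaic_copy(pan, map, n_out = 200L, seed = 9L)
  spec <- cohort_spec(n_breeding_rams = 15L, n_breeding_ewes = 60L,
                      n_male_lambs = 150L, n_female_lambs = 240L)
  fl <- build_founder_population(mos, map, n_rams = 15L, n_ewes = 60L,
                                 n_random_mating_generations = 5L,
                                 spec = spec, seed = 10L)
  expect_equal(length(fl$rams), 15L)
  expect_equal(length(fl$ewes), 60L)
  expect_true(all(fl$sex[fl$rams] == 1L))
  expect_true(all(fl$sex[fl$ewes] == 2L))
  founders <- c(fl$rams, fl$ewes)
  expect_true(all(fl$sire[founders] > 0L & fl$dam[founders] > 0L))
  # sire chain reaches the panel diploids in exactly 5 steps
  x <- fl$rams[1L]
  for (k in 1:5) x <- fl$sire[x]
  expect_equal(fl$sire[x], 0L)
  # all individuals carry two haplotypes over the full map
  expect_true(all(vapply(founders, function(i) {
    h <- fl$hap[[i]]
    !is.null(h) && identical(dim(h), c(80L, 2L))
  }, logical(1))))
})

test_that("zero random-mating generations give direct panel diploids without pedigree", {
  map <- genome_map(2L, 40L)
  pan <- generate_ancestral_panel(map, n_ancestral = 30L, seed = 11L)
  spec <- cohort_spec(n_breeding_rams = 5L, n_breeding_ewes = 10L,
                      n_male_lambs = 50L, n_female_lambs = 50L)
  fl <- build_founder_population(pan, map, n_rams = 5L, n_ewes = 10L,
                                 n_random_mating_generations = 0L,
                                 spec = spec, seed = 12L)
  founders <- c(fl$rams, fl$ewes)
  expect_true(all(fl$sire[founders] == 0L & fl$dam[founders] == 0L))
  expect_error(
    build_founder_population(pan, map, n_rams = 20L, n_ewes = 20L,
                             n_random_mating_generations = 0L,
                             spec = spec, replace = FALSE),
    "replacement disabled")
})

test_that("founder populations are bit-identical under a repeated seed", {
  map <- genome_map(2L, 50L)
  pan <- generate_ancestral_panel(map, n_ancestral = 20L, seed = 13L)
  mk <- function() build_founder_population(
    pan, map, n_rams = 6L, n_ewes = 12L, n_random_mating_generations = 2L,
    spec = cohort_spec(n_breeding_rams = 6L, n_breeding_ewes = 12L,
                       n_male_lambs = 60L, n_female_lambs = 60L),
    seed = 14L)
  f1 <- mk(); f2 <- mk()
  expect_identical(f1$hap, f2$hap)
  expect_identical(f1$age, f2$age)
  expect_identical(f1$sire, f2$sire)
})

test_that("random mating changes allele frequencies only by drift", {
  m <- 1000L
  map <- genome_map(5L, m)
  pan <- generate_ancestral_panel(map, n_ancestral = 40L, seed = 15L)
  mos <- mosaic_copy(pan, map, n_out = 400L, seed = 16L)
  spec <- cohort_spec(n_breeding_rams = 50L, n_breeding_ewes = 150L,
                      n_male_lambs = 500L, n_female_lambs = 750L)
  fl <- build_founder_population(mos, map, n_rams = 50L, n_ewes = 150L,
                                 n_random_mating_generations = 5L,
                                 spec = spec, seed = 17L)
  gen0 <- which(fl$sire == 0L)
  founders <- c(fl$rams, fl$ewes)
  freq_of <- function(ids) {
    # generation-0 haplotypes were freed; recompute frequency from stored
    # haplotypes where available, else skip
    rowMeans(vapply(ids, function(i) {
      h <- fl$hap[[i]]
      (h[, 1L] + h[, 2L]) / 2
    }, numeric(m)))
  }
  f_final <- freq_of(founders)
  # generation-0 frequencies equal the sampled panel columns; reconstruct
  # from the recorded draw is not possible, so compare against the donor
  # panel frequency (the sampling base)
  f_base <- rowMeans(mos$alleles)
  shift <- f_final - f_base
  expect_lt(abs(mean(shift)), 3 * sd(shift) / sqrt(5 * 40))
})
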