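test_that("r-squared is 1 for identical and for perfectly opposed dosages", {
  d <- rbind(c(0, 0, 1, 1, 2, 2),
             c(0, 0, 1, 1, 2, 2),
             c(2, 2, 1, 1, 0, 0))
  vt <- vt_from_dosage(d, pos = c(10, 50, 90), lens = c(c1 = 1000L))
  ld <- ld_decay(vt, max_dist = 1000, bin_edges = c(0, 1000))
  expect_equal(ld$mean_r2, 1)
  expect_equal(ld$n_pairs, 3)
})

test_that("r-squared is invariant under allele-label swap at either locus", {
  set.seed(11)
  d1 <- matrix(rbinom(12, 2, 0.5), nrow = 2)
  d2 <- d1
  d2[2, ] <- 2 - d2[2, ] # swap ref/alt labels at the second locus
  r2_of <- function(d) {
    vt <- vt_from_dosage(d, pos = c(10, 20), lens = c(c1 = 100L))
    ld_decay(vt, max_dist = 100, bin_edges = c(0, 100))$mean_r2
  }
  expect_equal(r2_of(d1), r2_of(d2), tolerance = 1e-12)
})

test_that("block-LD fixtures give r2 = 1 within blocks, low between", {
  g <- generate_genome(n_contigs = 1, length_range = c(200000, 200000),
                       genes_per_contig = 0, spare_per_contig = 0, seed = 51)
  vv <- generate_variants(g, theta = c(intergenic = 0.002), ld_block = 5000,
                          missing_prob = 0, seed = 51)
  vt <- vv$variants
  d <- matrix(NA_integer_, nrow(vt$sites), length(vt$samples))
  d[vt$gt == "0/0"] <- 0L
  d[vt$gt %in% c("0/1", "1/0")] <- 1L
  d[vt$gt == "1/1"] <- 2L
  blk <- (vt$sites$pos - 1) %/% 5000
  pairs_within <- 0; pairs_between <- 0
  r2_within <- c(); r2_between <- c()
  set.seed(1)
  idx <- sample(nrow(d), min(nrow(d), 80))
  for (i in idx) {
    for (j in idx[idx > i]) {
      if (stats::sd(d[i, ]) == 0 || stats::sd(d[j, ]) == 0) next
      r2 <- stats::cor(d[i, ], d[j, ])^2
      if (blk[i] == blk[j]) r2_within <- c(r2_within, r2)
      else r2_between <- c(r2_between, r2)
    }
  }
  expect_true(length(r2_within) > 5 && length(r2_between) > 20)
  expect_equal(mean(r2_within), 1, tolerance = 1e-9)
  expect_lt(mean(r2_between), 0.3)
})

test_that("inbreeding F matches the hand-evaluated formula", {
  # three samples, two biallelic sites, no missingness
  d <- rbind(c(0, 1, 2),
             c(2, 2, 2))
  vt <- vt_from_dosage(d, pos = c(10, 20), lens = c(c1 = 100L))
  het <- inbreeding_F(vt)
  # site 1: p = 3/6, n = 3 -> e = 1 - 2*0.5*0.5*6/5 = 0.4
  # site 2: p = 1 (monomorphic alt) -> e = 1
  # sample 1: O = 2 (hom ref + hom alt), E = 1.4, N = 2 -> F = 1
  # sample 2: O = 1, E = 1.4, N = 2 -> F = (1-1.4)/(2-1.4) = -0.6667
  expect_equal(het$F[1], 1)
  expect_equal(het$F[2], (1 - 1.4) / (2 - 1.4), tolerance = 1e-12)
  expect_equal(het$F[3], 1)
  expect_equal(het$expected_hom, rep(1.4, 3))
})

test_that("F is 0 when observed equals expected and 1 when all homozygous", {
  # all-homozygous sample set
  d <- rbind(c(0, 2, 2, 0), c(2, 0, 0, 2))
  vt <- vt_from_dosage(d, pos = c(10, 20), lens = c(c1 = 100L))
  expect_equal(inbreeding_F(vt)$F, rep(1, 4))
})

test_that("variant summary arithmetic: density, ratio, degenerate input", {
  expect_equal(snp_density(594857, 255.5e6), 2.33)
  expect_equal(missense_silent_ratio(7517, 22116), 0.34)
  expect_true(is.na(missense_silent_ratio(5, 0)))
  expect_error(snp_density(10, 0), "positive")

  d <- rbind(c(0, 1), c(1, 2))
  vt <- vt_from_dosage(d, pos = c(10, 20), lens = c(c1 = 2000L))
  eff <- data.frame(variant_id = c("v001", "v002"),
                    effect = c("synonymous", "missense"))
  s <- variant_summary(eff, vt, 2000)
  expect_equal(s$totals$n_snps, 2)
  expect_equal(s$totals$density_per_kb, 1)
  expect_equal(s$totals$missense_silent_ratio, 1)
  expect_equal(s$totals$biallelic_fraction, 1)
})
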