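test_that("windowed pi matches the hand-derived single-site value", {
  # one site, 2 alt alleles among 4 haplotypes, 10 callable sites:
  # pi = 2*2 / choose(4,2) / 10 = 0.0667
  d <- matrix(c(1, 1), nrow = 1) # two het samples: c = 2 among n = 4
  vt <- vt_from_dosage(d, pos = 5, lens = c(c1 = 10L))
  w <- windowed_diversity(vt, window = 10)
  expect_equal(w$pi, 2 * 2 / choose(4, 2) / 10, tolerance = 1e-12)
})

test_that("watterson theta uses the harmonic number at the median allele count", {
  # S = 3 segregating sites among 4 haplotypes, 100 callable:
  # theta = 3 / (a_3 * 100), a_3 = 1 + 1/2 + 1/3
  d <- matrix(c(1, 0,
                0, 1,
                1, 1), nrow = 3, byrow = TRUE)
  vt <- vt_from_dosage(d, pos = c(10, 20, 30), lens = c(c1 = 100L))
  w <- windowed_diversity(vt, window = 100)
  expect_equal(w$theta_w, 3 / ((1 + 1/2 + 1/3) * 100), tolerance = 1e-12)
  expect_equal(w$n_segregating, 3)
})

test_that("monomorphic windows give zero, empty callable gives NA", {
  d <- matrix(c(2, 2), nrow = 1) # all haplotypes carry the alternate: not segregating
  vt <- vt_from_dosage(d, pos = 5, lens = c(c1 = 10L))
  w <- windowed_diversity(vt, window = 10)
  expect_equal(w$pi, 0)
  expect_equal(w$theta_w, 0)
  w2 <- windowed_diversity(vt, window = 10,
                           callable = data.frame(contig = "c1", start = 0,
                                                 end = 10, n_callable = 0))
  expect_true(is.na(w2$pi) && is.na(w2$theta_w))
})

test_that("pi equals the brute-force pairwise-difference oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n_hap <- sample(seq(2, 8, by = 2), 1)
    n_sites <- sample(1:50, 1)
    hap <- matrix(rbinom(n_sites * n_hap, 1, runif(1, 0.1, 0.9)),
                  nrow = n_sites)
    # collapse haplotypes into diploid dosages (samples = consecutive pairs)
    d <- hap[, seq(1, n_hap, by = 2), drop = FALSE] +
      hap[, seq(2, n_hap, by = 2), drop = FALSE]
    callable <- 500
    vt <- vt_from_dosage(d, pos = seq_len(n_sites) * 2, lens = c(c1 = 500L))
    w <- windowed_diversity(vt, window = 500)
    expect_equal(w$pi, brute_pi(hap, callable), tolerance = 1e-12,
                 label = sprintf("pi oracle rep %d", rep))
  }
})

test_that("feature contrasts detect a planted diversity reduction in exons", {
  g <- generate_genome(n_contigs = 2, length_range = c(120000, 140000),
                       genes_per_contig = 10, gene_spacing = 1000, seed = 41)
  vv <- generate_variants(g, theta = c(exon = 0.0004, intron = 0.0012,
                                       intergenic = 0.0012), seed = 41)
  fd <- feature_diversity(vv$variants, g$features, classes = "exon",
                          window = 5000)
  t <- fd$tests[fd$tests$class == "exon", ]
  expect_lt(t$median_pi, t$median_complement)
  expect_lt(t$p, 0.05)
})

test_that("identical class and complement distributions give p near 1", {
  # degenerate identical distributions: a monomorphic call set makes every
  # window pi exactly 0 on both sides
  g <- generate_genome(n_contigs = 2, length_range = c(60000, 80000),
                       genes_per_contig = 0, spare_per_contig = 0, seed = 42)
  vv <- generate_variants(g, theta = c(intergenic = 0.0005), seed = 42)
  vt <- vv$variants
  vt$gt[] <- "1/1" # every haplotype carries the alternate: nothing segregates
  fd0 <- suppressWarnings(
    feature_diversity(vt, g$features, classes = "repeat", window = 10000))
  expect_equal(fd0$tests$p[1], 1)
  # and a same-process class vs complement comparison is not grossly biased
  fd <- feature_diversity(vv$variants, g$features, classes = "repeat",
                          window = 10000)
  expect_gt(fd$tests$p[1], 0.001)
})

test_that("chromosome enrichment flags only a truly enriched contig", {
  set.seed(3)
  # synthetic windows: ctgA carries all the top-diversity windows
  win <- data.frame(contig = rep(c("ctgA", "ctgB", "ctgC"), each = 40),
                    start = rep(seq(0, 390000, by = 10000), 3),
                    end = rep(seq(10000, 400000, by = 10000), 3),
                    n_callable = 10000, n_segregating = 5,
                    pi = c(stats::runif(40, 0.002, 0.003),
                           stats::runif(40, 0.0005, 0.001),
                           stats::runif(40, 0.0005, 0.001)))
  class(win) <- c("diversity_windows", "data.frame")
  set.seed(3)
  enr <- chromosome_enrichment(win, top_frac = 0.05, alpha = 0.01)
  expect_true(enr$enriched[enr$contig == "ctgA"])
  expect_false(any(enr$enriched[enr$contig != "ctgA"]))
  # proportionally distributed top windows: nothing enriched
  win2 <- win
  win2$pi <- rep(stats::runif(40, 0.001, 0.002), 3)
  enr2 <- chromosome_enrichment(win2, top_frac = 0.05, alpha = 0.01)
  expect_false(any(enr2$enriched))
})

test_that("too few windows yields an NA notice result", {
  win <- data.frame(contig = c("a", "b"), start = c(0, 0), end = c(10, 10),
                    n_callable = 10, n_segregating = 0, pi = c(0.1, 0.2))
  class(win) <- c("diversity_windows", "data.frame")
  expect_message(enr <- chromosome_enrichment(win, top_frac = 0.05),
                 "too few windows")
  expect_true(all(is.na(enr$p)))
})
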