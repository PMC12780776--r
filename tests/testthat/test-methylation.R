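mst <- function(pos, cov, mod, contig = "c1", strand = "+", code = "m") {
  methyl_site_table(data.frame(contig = contig, pos = pos, strand = strand,
                               mod_code = code, valid_coverage = cov,
                               modified_count = mod))
}

test_that("site classification applies the weak and high thresholds", {
  t <- mst(pos = c(0, 10, 20, 30), cov = c(40, 40, 20, 0),
           mod = c(0, 1, 5, 0))
  cl <- classify_sites(t)
  expect_equal(as.character(cl$class), c("unmethylated", "weak", "high", NA))
  expect_equal(cl$methylatable, c(TRUE, TRUE, TRUE, FALSE))
  # exactly 20% counts as high by default, not under the strict flag
  t2 <- mst(pos = 0, cov = 20, mod = 4)
  expect_equal(as.character(classify_sites(t2)$class), "high")
  expect_equal(as.character(classify_sites(t2, high_strict = TRUE)$class), "weak")
})

test_that("a site inside several feature classes is counted in each", {
  lens <- c(c1 = 100L)
  fm <- feature_map(list(
    exon = data.frame(contig = "c1", start = 0L, end = 50L),
    intron = data.frame(contig = "c1", start = 50L, end = 80L),
    intergenic = data.frame(contig = "c1", start = 80L, end = 100L),
    `repeat` = data.frame(contig = "c1", start = 40L, end = 60L)
  ), lens)
  t <- mst(pos = c(45, 55, 90), cov = 10, mod = c(1, 0, 5))
  counts <- count_by_feature(classify_sites(t), fm)
  get <- function(f, col) counts[counts$feature == f & counts$mod_code == "m", col]
  expect_equal(get("exon", "methylatable_sites"), 1)
  expect_equal(get("exon", "weak_sites"), 1)
  expect_equal(get("repeat", "methylatable_sites"), 2) # pos 45 and 55
  expect_equal(get("repeat", "weak_sites"), 1)
  expect_equal(get("low_complexity", "methylatable_sites"), 0)
  expect_equal(get("genome_wide", "methylatable_sites"), 3)
  expect_equal(get("genome_wide", "high_sites"), 1)
})

test_that("percentage table rounds to two decimals and NA on empty classes", {
  counts <- data.frame(feature = c("exon", "none", "all"), mod_code = "m",
                       methylatable_sites = c(936051, 0, 10),
                       weak_sites = c(23738, 0, 10),
                       high_sites = c(0, 0, 10))
  tab <- methylation_table(counts)
  expect_equal(tab$weak_pct, c(2.54, NA, 100))
  expect_equal(tab$high_pct[3], 100)
})

test_that("window aggregation uses half-open tiles and conserves totals", {
  lens <- c(c1 = 250000L)
  fm <- feature_map(list(intergenic = data.frame(contig = "c1", start = 0L,
                                                 end = 250000L)), lens)
  t <- mst(pos = c(99999, 100000, 200000), cov = 10, mod = c(1, 1, 0))
  cl <- classify_sites(t)
  win <- window_aggregate(cl, fm, window = 100000)
  w <- win[win$feature == "intergenic", ]
  expect_equal(w$window_start, c(0, 100000, 200000))
  expect_equal(w$weak_sites, c(1, 1, 0)) # site at 100000 falls in window 2
  # conservation against the global per-feature counts
  glob <- count_by_feature(cl, fm)
  for (cls in unique(glob$feature[glob$feature != "genome_wide"])) {
    ww <- win[win$feature == cls, ]
    gg <- glob[glob$feature == cls, ]
    expect_equal(sum(ww$methylatable_sites), gg$methylatable_sites)
    expect_equal(sum(ww$weak_sites), gg$weak_sites)
    expect_equal(sum(ww$high_sites), gg$high_sites)
  }
})

test_that("window conservation holds on a random generated fixture", {
  g <- generate_genome(n_contigs = 2, length_range = c(30000, 50000), seed = 21)
  mp <- generate_methylation_pileup(g, seed = 21)
  cl <- classify_sites(mp)
  win <- window_aggregate(cl, g$features, window = 10000)
  glob <- count_by_feature(cl, g$features)
  for (code in c("m", "h")) {
    for (cls in setdiff(unique(glob$feature), "genome_wide")) {
      ww <- win[win$feature == cls & win$mod_code == code, ]
      gg <- glob[glob$feature == cls & glob$mod_code == code, ]
      expect_equal(sum(ww$methylatable_sites), gg$methylatable_sites)
      expect_equal(sum(ww$weak_sites), gg$weak_sites)
      expect_equal(sum(ww$high_sites), gg$high_sites)
    }
  }
  # structural invariants of the counts
  expect_true(all(glob$high_sites <= glob$weak_sites))
  expect_true(all(glob$weak_sites <= glob$methylatable_sites))
  tab <- methylation_table(glob)
  ok <- !is.na(tab$weak_pct)
  expect_true(all(tab$weak_pct[ok] >= 0 & tab$weak_pct[ok] <= 100))
})

test_that("genome-wide fraction counts called and methylated sites", {
  empty <- methyl_site_table(data.frame(contig = character(), pos = integer(),
                                        strand = character(), mod_code = character(),
                                        valid_coverage = integer(),
                                        modified_count = integer()))
  r <- genome_wide_fraction(empty)
  expect_equal(r$called_sites, 0)
  expect_true(is.na(r$fraction))

  t <- mst(pos = seq(0, 90, by = 10), cov = 10, mod = c(1, rep(0, 9)))
  r2 <- genome_wide_fraction(t, "m", "weak")
  expect_equal(r2$fraction, 0.10)
})

test_that("a CpG-free genome yields an empty pileup", {
  g <- list(contigs = contig_set(c(c1 = strrep("AT", 3000))),
            features = feature_map(list(intergenic = data.frame(
              contig = "c1", start = 0L, end = 6000L)), c(c1 = 6000L)))
  mp <- generate_methylation_pileup(g, seed = 1)
  expect_equal(nrow(mp), 0)
})

test_that("all-zero rates give an all-zero pileup", {
  g <- generate_genome(n_contigs = 1, length_range = c(10000, 10000),
                       genes_per_contig = 1, seed = 2)
  zero <- list(exon = list(m = c(0, 0), h = c(0, 0)),
               intron = list(m = c(0, 0), h = c(0, 0)),
               intergenic = list(m = c(0, 0), h = c(0, 0)))
  mp <- generate_methylation_pileup(g, rates = zero, seed = 2)
  expect_true(all(mp$modified_count == 0))
})
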