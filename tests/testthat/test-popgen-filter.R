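vt_fixture <- function(sites, gt, dp = NULL, lens = c(c1 = 100000L)) {
  if (is.null(dp)) dp <- matrix(20L, nrow = nrow(sites), ncol = ncol(gt))
  variant_table(sites, gt, dp, sprintf("S%02d", seq_len(ncol(gt))), lens)
}

test_that("variant filters use inclusive bounds and the stated rule order", {
  sites <- data.frame(
    variant_id = paste0("v", 1:6), contig = "c1", pos = 1:6 * 100,
    ref = c("A", "A", "A", "AT", "A", "A"),
    alt = c("G", "G", "G", "A", "G", "G"),
    qual = c(40.0, 39.9, 500, 10, 500, 500))
  gt <- matrix("0/1", nrow = 6, ncol = 10)
  gt[5, 1:3] <- "./."            # 30% missing: removed
  gt[6, 1:2] <- "./."            # exactly 20%: kept
  dp <- matrix(20L, 6, 10)
  dp[1, ] <- 5L                  # boundary mean depth 5.0: kept
  dp[3, ] <- 501L                # mean depth above 500: removed
  vt <- vt_fixture(sites, gt, dp)
  r <- filter_variants(vt)
  kept <- r$variants$sites$variant_id
  expect_setequal(kept, c("v1", "v6"))
  expect_equal(r$removed$reason[r$removed$variant_id == "v2"], "qual")
  expect_equal(r$removed$reason[r$removed$variant_id == "v3"], "depth")
  # indel rule fires first even though v4 also fails QUAL
  expect_equal(r$removed$reason[r$removed$variant_id == "v4"], "indel")
  expect_equal(r$removed$reason[r$removed$variant_id == "v5"], "missing")
  # conservation: input = kept + per-rule removals
  rep <- r$report
  expect_equal(rep$sites[rep$rule == "input"],
               rep$sites[rep$rule == "kept"] +
                 sum(rep$sites[rep$rule %in% c("indel", "qual", "depth", "missing")]))
})

test_that("planted artifact sites are removed for exactly the planted reasons", {
  g <- generate_genome(n_contigs = 2, length_range = c(30000, 40000), seed = 31)
  vv <- generate_variants(g, artifacts = c(low_qual = 4, bad_depth = 2,
                                           high_missing = 3, indel = 2),
                          seed = 31)
  r <- filter_variants(vv$variants)
  led <- vv$ledger[grepl("^filtered_out:", vv$ledger$detail), ]
  expect_equal(nrow(led), 11)
  m <- merge(led, r$removed, by = "variant_id")
  expect_equal(nrow(m), 11)
  expect_true(all(sub("filtered_out:", "", m$detail) == m$reason))
  # nothing else was removed
  expect_equal(nrow(r$removed), 11)
})

test_that("codon substitutions classify as synonymous / missense / nonsense", {
  # gene: ATG GAT GCT TAC AAA TAA at 0-based position 12 on the plus strand
  orf <- "ATGGATGCTTACAAATAA"
  genome <- orf_contig(orf, start = 12, pad_to = 40000)
  gms <- orf_tx(orf, start = 12)
  mk <- function(pos0, ref, alt) {
    vt_fixture(data.frame(variant_id = "x", contig = "c1", pos = pos0 + 1,
                          ref = ref, alt = alt, qual = 500),
               matrix(c("0/1", "0/0"), nrow = 1), lens = c(c1 = 40000L))
  }
  # GAT -> GAA (D -> E): missense at codon 2, third base (offset 12+5)
  expect_equal(classify_effects(mk(17, "T", "A"), gms, genome)$effect, "missense")
  # GCT -> GCC (A -> A): synonymous at codon 3, third base
  expect_equal(classify_effects(mk(20, "T", "C"), gms, genome)$effect, "synonymous")
  # TAC -> TAA: nonsense at codon 4, third base
  expect_equal(classify_effects(mk(23, "C", "A"), gms, genome)$effect, "nonsense")
  # far from any gene: intergenic
  expect_equal(classify_effects(mk(30000, substring(genome[[1]], 30001, 30001), "C"),
                                gms, genome)$effect, "intergenic")
  # within 5 kb downstream of the plus-strand gene
  expect_equal(classify_effects(mk(2000, "A", "C"), gms, genome)$effect, "downstream")
  # ref mismatch with the genome is a consistency error
  expect_error(classify_effects(mk(17, "G", "A"), gms, genome), "disagrees")
})

test_that("splice-site and intron calls depend on distance to the boundary", {
  g <- generate_genome(n_contigs = 1, length_range = c(30000, 30000),
                       genes_per_contig = 3, exon_range = c(2, 3), seed = 33)
  gs <- generate_gene_sets(g, seed = 33)
  ev <- gs$evidence
  t1 <- ev$transcripts$transcript_id[1]
  ex <- ev$exons[ev$exons$transcript_id == t1, ]
  ex <- ex[order(ex$start), ]
  intron <- c(ex$end[1], ex$start[2])
  mk <- function(pos0) {
    ref <- contig_subseq(g$contigs, "ctg01", pos0, pos0 + 1)
    vt_fixture(data.frame(variant_id = "x", contig = "ctg01", pos = pos0 + 1,
                          ref = ref, alt = setdiff(c("A", "C", "G", "T"), ref)[1],
                          qual = 500),
               matrix(c("0/1", "0/0"), nrow = 1),
               lens = contig_lengths(g$contigs))
  }
  expect_equal(classify_effects(mk(intron[1]), ev, g$contigs)$effect, "splice_site")
  expect_equal(classify_effects(mk(intron[1] + 1L), ev, g$contigs)$effect, "splice_site")
  expect_equal(classify_effects(mk(intron[2] - 1L), ev, g$contigs)$effect, "splice_site")
  mid <- (intron[1] + intron[2]) %/% 2
  expect_equal(classify_effects(mk(mid), ev, g$contigs)$effect, "intron")
})

test_that("classifier agrees with the full-translation oracle on random CDS variants", {
  g <- generate_genome(n_contigs = 2, length_range = c(30000, 40000),
                       genes_per_contig = 5, exon_range = c(1, 3), seed = 35)
  gs <- generate_gene_sets(g, seed = 35)
  ev <- gs$evidence
  set.seed(99)
  n_checked <- 0
  for (rep in 1:120) {
    t <- sample(ev$transcripts$transcript_id, 1)
    cd <- ev$cds[ev$cds$transcript_id == t, ]
    row <- ev$transcripts[ev$transcripts$transcript_id == t, ]
    i <- sample(nrow(cd), 1)
    pos0 <- cd$start[i] + sample(cd$end[i] - cd$start[i], 1) - 1L
    ref <- contig_subseq(g$contigs, row$contig, pos0, pos0 + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    vt <- vt_fixture(data.frame(variant_id = "x", contig = row$contig,
                                pos = pos0 + 1, ref = ref, alt = alt, qual = 500),
                     matrix(c("0/1", "0/0"), nrow = 1),
                     lens = contig_lengths(g$contigs))
    got <- classify_effects(vt, ev, g$contigs)
    want <- oracle_cds_effect(ev, t, g$contigs, row$contig, pos0, alt)
    if (got$transcript_id != t) next # most severe effect came from another transcript
    expect_equal(got$effect, want,
                 label = sprintf("%s pos %d %s>%s", t, pos0, ref, alt))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 80)
})
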