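# Hand-built interval fixtures are 0-based half-open on contig "c1" unless
# stated otherwise.

tx_row <- function(id, gene = "g1", contig = "c1", strand = "+",
                   source = "evidence", loss_class = NA, source_gene = NA) {
  data.frame(transcript_id = id, gene_id = gene, contig = contig,
             strand = strand, source = source,
             loss_class = as.character(loss_class),
             source_gene = as.character(source_gene))
}
ex_row <- function(id, start, end) {
  data.frame(transcript_id = id, start = start, end = end)
}

test_that("multilocus splitting follows overlap connectivity", {
  # single transcript: identity
  s1 <- make_gms(tx_row("a"), ex_row("a", 100, 200))
  expect_identical(split_multilocus_genes(s1)$set$transcripts$gene_id, "g1")

  # [100,200) and [500,600): two genes in genomic order
  s2 <- make_gms(rbind(tx_row("a"), tx_row("b")),
                 rbind(ex_row("a", 100, 200), ex_row("b", 500, 600)))
  r2 <- split_multilocus_genes(s2)$set
  expect_setequal(r2$transcripts$gene_id, c("g1.1", "g1.2"))
  expect_equal(r2$transcripts$gene_id[r2$transcripts$transcript_id == "a"], "g1.1")

  # A[0,300) B[250,400) C[390,500): one gene by transitivity
  s3 <- make_gms(rbind(tx_row("A"), tx_row("B"), tx_row("C")),
                 rbind(ex_row("A", 0, 300), ex_row("B", 250, 400),
                       ex_row("C", 390, 500)))
  expect_identical(unique(split_multilocus_genes(s3)$set$transcripts$gene_id), "g1")

  # opposite strands never join one component
  s4 <- make_gms(rbind(tx_row("p", strand = "+"), tx_row("m", strand = "-")),
                 rbind(ex_row("p", 0, 300), ex_row("m", 100, 200)))
  expect_length(unique(split_multilocus_genes(s4)$set$transcripts$gene_id), 2)
})

test_that("splitting agrees with a brute-force connected-component oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    starts <- sample(0:2000, n)
    ends <- starts + sample(50:600, n, replace = TRUE)
    ids <- paste0("t", seq_len(n))
    s <- make_gms(do.call(rbind, lapply(ids, tx_row)),
                  do.call(rbind, Map(ex_row, ids, starts, ends)))
    got <- split_multilocus_genes(s)$set$transcripts
    # oracle: grow components by repeated sweeps over the overlap matrix
    ov <- outer(seq_len(n), seq_len(n), function(i, j) {
      starts[i] < ends[j] & starts[j] < ends[i]
    })
    comp <- seq_len(n)
    repeat {
      before <- comp
      for (i in seq_len(n)) comp[ov[i, ]] <- min(comp[ov[i, ]], comp[i])
      if (identical(before, comp)) break
    }
    expect_equal(
      as.integer(factor(got$gene_id[match(ids, got$transcript_id)],
                        levels = unique(got$gene_id))),
      as.integer(factor(comp, levels = unique(comp))),
      label = sprintf("component structure (rep %d)", rep))
  }
})

test_that("cross-scaffold removal keeps the majority contig, ties by span", {
  base <- function(ids, contigs, starts, ends) {
    make_gms(do.call(rbind, Map(function(i, ctg) {
      tx_row(i, contig = ctg, source = "orthology",
             loss_class = "intact", source_gene = "sg1")
    }, ids, contigs)),
    do.call(rbind, Map(ex_row, ids, starts, ends)))
  }
  # 2-vs-1 majority
  s <- base(c("a", "b", "c"), c("c1", "c1", "c2"),
            c(0, 500, 0), c(300, 800, 300))
  r <- drop_cross_scaffold_transcripts(s)
  expect_setequal(r$set$transcripts$transcript_id, c("a", "b"))
  expect_equal(r$removals$transcript_id, "c")

  # all on one contig: unchanged
  s2 <- base(c("a", "b"), c("c1", "c1"), c(0, 500), c(300, 800))
  expect_equal(nrow(drop_cross_scaffold_transcripts(s2)$removals), 0)

  # 1-vs-1 tie: longer summed span on c2 wins, so the c1 transcript goes
  s3 <- base(c("a", "b"), c("c1", "c2"), c(0, 0), c(300, 900))
  expect_equal(drop_cross_scaffold_transcripts(s3)$removals$transcript_id, "a")

  # missing source_gene is a validation error
  s4 <- make_gms(tx_row("a", source = "orthology", loss_class = "intact"),
                 ex_row("a", 0, 300))
  expect_error(drop_cross_scaffold_transcripts(s4), "source_gene")
})

test_that("micro-intron collapse joins sub-threshold gaps to a fixed point", {
  s <- make_gms(tx_row("a"), rbind(ex_row("a", 0, 100), ex_row("a", 103, 200)))
  r <- collapse_micro_introns(s)$set
  expect_equal(r$exons[, c("start", "end")], data.frame(start = 0, end = 200))

  s2 <- make_gms(tx_row("a"), rbind(ex_row("a", 0, 100), ex_row("a", 104, 200)))
  r2 <- collapse_micro_introns(s2)$set
  expect_equal(nrow(r2$exons), 2)

  # chained gaps of 2 and 3 bp collapse to one exon
  s3 <- make_gms(tx_row("a"),
                 rbind(ex_row("a", 0, 10), ex_row("a", 12, 20), ex_row("a", 23, 40)))
  r3 <- collapse_micro_introns(s3)$set
  expect_equal(r3$exons[, c("start", "end")], data.frame(start = 0, end = 40))
  # CDS re-unioned alongside, phase of the 5' end preserved
  expect_equal(r3$cds[, c("start", "end", "phase")],
               data.frame(start = 0, end = 40, phase = 0L))
})

test_that("loss-class filtering keeps allowed labels and sweeps empty genes", {
  s <- make_gms(rbind(tx_row("a", source = "orthology", loss_class = "intact"),
                      tx_row("b", source = "orthology", loss_class = "lost"),
                      tx_row("c", gene = "g2", source = "orthology",
                             loss_class = "missing")),
                rbind(ex_row("a", 0, 100), ex_row("b", 0, 100),
                      ex_row("c", 500, 600)))
  r <- filter_orthology_classes(s)
  expect_setequal(r$set$transcripts$transcript_id, "a")
  expect_false("g2" %in% r$set$transcripts$gene_id)
  expect_setequal(r$removals$reason, c("loss_class:lost", "loss_class:missing"))

  s2 <- make_gms(tx_row("a", source = "orthology"), ex_row("a", 0, 100))
  expect_error(filter_orthology_classes(s2), "loss_class")
})

test_that("ORF validation keeps complete ORFs and names removal reasons", {
  keep <- orf_tx("ATGAAATAA")
  g <- orf_contig("ATGAAATAA")
  r <- validate_orfs(keep, g)
  expect_equal(n_transcripts(r$set), 1)

  bad <- orf_tx("ATGTAAAAATAA")
  g2 <- orf_contig("ATGTAAAAATAA")
  r2 <- validate_orfs(bad, g2)
  expect_equal(n_transcripts(r2$set), 0)
  expect_equal(r2$removals$reason, "internal_stop")

  nostart <- orf_tx("TTGAAATAA")
  r3 <- validate_orfs(nostart, orf_contig("TTGAAATAA"))
  expect_equal(r3$removals$reason, "missing_start")

  nostop <- orf_tx("ATGAAAGCC")
  r4 <- validate_orfs(nostop, orf_contig("ATGAAAGCC"))
  expect_equal(r4$removals$reason, "missing_stop")

  frame <- orf_tx("ATGAAAATAA")
  r5 <- validate_orfs(frame, orf_contig("ATGAAAATAA"))
  expect_equal(r5$removals$reason, "frame")
})

test_that("minus-strand ORF verdicts equal their plus-strand equivalents", {
  orf <- "ATGGATTAA"
  plus <- validate_orfs(orf_tx(orf), orf_contig(orf))
  minus_seq <- revcomp(orf)
  minus <- validate_orfs(orf_tx(minus_seq, strand = "-"), orf_contig(minus_seq))
  expect_equal(n_transcripts(plus$set), 1)
  expect_equal(n_transcripts(minus$set), n_transcripts(plus$set))

  # and a defective one fails on both strands alike
  bad <- "ATGTGATAA"
  p2 <- validate_orfs(orf_tx(bad), orf_contig(bad))
  m2 <- validate_orfs(orf_tx(revcomp(bad), strand = "-"), orf_contig(revcomp(bad)))
  expect_equal(n_transcripts(p2$set), 0)
  expect_equal(m2$removals$reason, p2$removals$reason)
})

test_that("validate_orfs errors on a missing contig", {
  s <- make_gms(tx_row("a", contig = "nope"), ex_row("a", 0, 9))
  expect_error(validate_orfs(s, tiny_contigs()), "missing contig")
})

test_that("merge drops duplicate chains, attaches overlapping novel isoforms, founds new genes", {
  g <- generate_genome(n_contigs = 2, length_range = c(30000, 40000),
                       genes_per_contig = 4, spare_per_contig = 1,
                       exon_range = c(2, 4), seed = 12)
  gs <- generate_gene_sets(g, list(unique_isoform = 2), seed = 12)
  r <- reconcile_pipeline(gs$evidence, gs$orthology, g$contigs)
  n_spare <- sum(gs$ledger$kind == "unique_gene")
  expect_equal(r$merge_stats$added_genes, n_spare)
  expect_equal(r$merge_stats$added_isoforms, 2)
  expect_equal(r$merge_stats$dropped_duplicates,
               n_transcripts(gs$orthology) - n_spare - 2)
  # planted unique isoforms were attached to their evidence genes
  ui <- gs$ledger[gs$ledger$kind == "unique_isoform", ]
  got <- r$set$transcripts[match(ui$transcript_id, r$set$transcripts$transcript_id), ]
  expect_equal(got$gene_id, ui$gene_id)
  # merge never removes or modifies evidence transcripts
  expect_true(all(gs$evidence$transcripts$transcript_id %in%
                    r$set$transcripts$transcript_id))
})

test_that("merge refuses uncleaned input when a genome is supplied", {
  orf <- "ATGAAATAA"
  g <- orf_contig(orf)
  clean <- orf_tx(orf)
  dirty_seq <- "ATGTAAAAATAA"
  g2 <- orf_contig(dirty_seq, start = 500)
  both <- contig_set(c(c1 = paste0(substring(g[[1]], 1, 400),
                                   substring(g2[[1]], 401))))
  dirty <- orf_tx(dirty_seq, start = 500, id = "t2", gene = "g2",
                  source = "orthology")
  expect_error(merge_gene_sets(clean, dirty, genome = both), "uncleaned")
})

test_that("the full pipeline is idempotent on its own output", {
  g <- generate_genome(n_contigs = 2, length_range = c(30000, 40000),
                       genes_per_contig = 4, spare_per_contig = 1, seed = 8)
  gs <- generate_gene_sets(g, list(internal_stop = 1, micro_intron = 1,
                                   unique_isoform = 1), seed = 8)
  r1 <- reconcile_pipeline(gs$evidence, gs$orthology, g$contigs)
  r2 <- reconcile_pipeline(r1$set, empty_gms(), g$contigs)
  norm <- function(s) {
    list(tx = s$transcripts[order(s$transcripts$transcript_id),
                            c("transcript_id", "gene_id", "contig", "strand")],
         ex = s$exons[order(s$exons$transcript_id, s$exons$start), ],
         cd = s$cds[order(s$cds$transcript_id, s$cds$start), ])
  }
  a <- norm(r1$set); b <- norm(r2$set)
  rownames(a$tx) <- rownames(b$tx) <- NULL
  rownames(a$ex) <- rownames(b$ex) <- NULL
  rownames(a$cd) <- rownames(b$cd) <- NULL
  expect_equal(b, a)
})

test_that("conservation holds at every removing stage", {
  g <- generate_genome(n_contigs = 2, length_range = c(40000, 50000),
                       genes_per_contig = 6, seed = 10)
  gs <- generate_gene_sets(g, list(internal_stop = 2, missing_start = 1,
                                   missing_stop = 1, cross_scaffold = 1,
                                   bad_loss_class = 2), seed = 10)
  r <- reconcile_pipeline(gs$evidence, gs$orthology, g$contigs)
  st <- r$stages
  expect_true(all(st$input - st$removed == st$output |
                    st$stage == "merge"))
  # merge accounting: inputs = output + dropped duplicates
  m <- st[st$stage == "merge", ]
  expect_equal(m$input - m$removed, m$output)
})
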