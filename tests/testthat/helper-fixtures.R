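# Shared in-code fixtures. Everything is generated, nothing is stored.

# tiny hand-built genome: one contig, explicit sequence
tiny_contigs <- function(seqs = c(c1 = strrep("ACGT", 300))) {
  contig_set(seqs)
}

# a minimal gene model set built by hand from explicit intervals
# (0-based half-open), defaulting to a clean single-exon plus-strand ORF
make_gms <- function(tx, exons, cds = NULL) {
  if (is.null(cds)) {
    cds <- exons
    cds$phase <- 0L
  }
  gene_model_set(tx, exons, cds)
}

empty_gms <- function() {
  gene_model_set(
    data.frame(transcript_id = character(), gene_id = character(),
               contig = character(), strand = character(), source = character()),
    data.frame(transcript_id = character(), start = integer(), end = integer()),
    data.frame(transcript_id = character(), start = integer(), end = integer(),
               phase = integer()))
}

# write a DNA string so that a given ORF occupies [start, start+len) of an
# A-padded contig; returns the contig_set
orf_contig <- function(orf, start = 100, pad_to = 2000, id = "c1") {
  s <- paste0(strrep("A", start), orf,
              strrep("A", pad_to - start - nchar(orf)))
  contig_set(stats::setNames(s, id))
}

# one clean transcript over the ORF planted by orf_contig()
orf_tx <- function(orf, start = 100, strand = "+", source = "evidence",
                   id = "t1", gene = "g1", loss_class = NA, source_gene = NA) {
  tx <- data.frame(transcript_id = id, gene_id = gene, contig = "c1",
                   strand = strand, source = source,
                   loss_class = as.character(loss_class),
                   source_gene = as.character(source_gene))
  ex <- data.frame(transcript_id = id, start = start, end = start + nchar(orf))
  make_gms(tx, ex)
}

gt_from_dosage <- function(d) {
  m <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  m[d == 0] <- "0/0"; m[d == 1] <- "0/1"; m[d == 2] <- "1/1"
  m
}

vt_from_dosage <- function(d, pos, lens = c(c1 = 10000L), contig = "c1") {
  sites <- data.frame(variant_id = sprintf("v%03d", seq_len(nrow(d))),
                      contig = contig, pos = pos, ref = "A", alt = "G",
                      qual = 500)
  variant_table(sites, gt_from_dosage(d),
                matrix(20L, nrow(d), ncol(d)),
                sprintf("S%02d", seq_len(ncol(d))), lens)
}

# brute-force mean pairwise difference per callable site over haplotypes:
# the independent oracle for pi (haplotype matrix: sites x haplotypes, 0/1)
brute_pi <- function(hap, callable) {
  n <- ncol(hap)
  if (n < 2) return(NA_real_)
  tot <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(hap[, i] != hap[, j])
    }
  }
  tot / choose(n, 2) / callable
}

# hypergeometric enumeration of the two-sided Fisher p for a 2x2 table:
# sum of probabilities of all tables with the observed margins whose
# probability does not exceed the observed one
brute_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  ptab <- function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }
  xs <- max(0, k - n):min(k, m)
  probs <- vapply(xs, ptab, numeric(1))
  p_obs <- ptab(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# full-translation effect oracle for a coding SNV: substitute the alternate
# base into the genome, re-splice and translate the whole CDS, and compare
# proteins
oracle_cds_effect <- function(gms, tx_id, genome, contig, pos0, alt) {
  ref_prot <- translate_cds(spliced_cds(gms, tx_id, genome))
  s <- unclass(genome)[[contig]]
  substring(s, pos0 + 1, pos0 + 1) <- alt
  mut <- contig_set(stats::setNames(s, contig))
  alt_prot <- translate_cds(spliced_cds(gms, tx_id, mut))
  if (alt_prot == ref_prot) return("synonymous")
  stops_ref <- gregexpr("*", ref_prot, fixed = TRUE)[[1]][1]
  stops_alt <- gregexpr("*", alt_prot, fixed = TRUE)[[1]][1]
  if (stops_alt != -1 && (stops_ref == -1 || stops_alt < stops_ref)) {
    return("nonsense")
  }
  "missense"
}
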