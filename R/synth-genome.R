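# Synthetic genome generation with planted gene loci.
#
# Every gene locus is built in "sense space" (reading-strand coordinates of
# the locus) and then mirrored onto the genome for minus-strand genes. A
# locus carries one clean ORF (ATG ... stop), an in-frame extension ending in
# a second stop codon, and in-frame stop-free introns. This layout lets the
# gene-set generator derive every annotation-defect class it needs
# (internal-stop, missing-start, missing-stop, micro-intron, intron-retained
# unique isoforms) purely by re-slicing coordinates, without touching the
# genome sequence.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

.NONSTOP_CODONS <- setdiff(.all_codons(), .STOP_CODONS)

.rand_dna <- function(n, gc) {
  if (n <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.seed_rng <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

# Derive an independent child seed from a master seed and a stream label, so
# each generator is independently regenerable from one master seed.
.child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Build one gene locus in sense space.
# Returns sense sequence plus the coordinate skeleton used for planting.
.make_locus <- function(n_exons, n_codons, ext_codons, intron_codon_range = c(20, 60)) {
  stopifnot(n_codons >= n_exons * 2 + 2, n_codons >= 6)
  codons <- c("ATG",
              sample(.NONSTOP_CODONS, n_codons - 2, replace = TRUE),
              sample(.STOP_CODONS, 1))
  # second codon must not be ATG so a planted missing-start defect is
  # unambiguous
  while (codons[2] == "ATG") codons[2] <- sample(.NONSTOP_CODONS, 1)
  if (n_exons > 1) {
    # intron after codon b keeps >= 2 codons in the flanking exons
    bounds <- sort(sample(2:(n_codons - 2), n_exons - 1))
    introns <- lapply(seq_len(n_exons - 1), function(i) {
      m <- sample(intron_codon_range[1]:intron_codon_range[2], 1)
      paste(sample(.NONSTOP_CODONS, m, replace = TRUE), collapse = "")
    })
  } else {
    bounds <- integer(0)
    introns <- list()
  }
  piece_idx <- findInterval(seq_len(n_codons) - 1L, bounds) + 1L
  pieces <- vapply(seq_len(n_exons), function(i) {
    paste(codons[piece_idx == i], collapse = "")
  }, character(1))
  seq_parts <- character(0)
  orf_exons <- matrix(0L, nrow = n_exons, ncol = 2)
  cursor <- 0L
  for (i in seq_len(n_exons)) {
    orf_exons[i, ] <- c(cursor, cursor + nchar(pieces[i]))
    seq_parts <- c(seq_parts, pieces[i])
    cursor <- cursor + nchar(pieces[i])
    if (i < n_exons) {
      seq_parts <- c(seq_parts, introns[[i]])
      cursor <- cursor + nchar(introns[[i]])
    }
  }
  orf_end <- cursor
  ext <- paste0(paste(sample(.NONSTOP_CODONS, ext_codons, replace = TRUE), collapse = ""),
                sample(.STOP_CODONS, 1))
  list(seq = paste0(paste(seq_parts, collapse = ""), ext),
       orf_exons = orf_exons,
       orf_end = orf_end,
       ext_end = orf_end + nchar(ext),
       n_codons = n_codons)
}

# Map sense-space intervals (matrix of [a,b), rows) onto the genome.
.map_ivs <- function(ivs, locus_start, locus_len, strand) {
  if (strand == "+") {
    out <- cbind(locus_start + ivs[, 1], locus_start + ivs[, 2])
  } else {
    out <- cbind(locus_start + locus_len - ivs[, 2],
                 locus_start + locus_len - ivs[, 1])
  }
  out[order(out[, 1]), , drop = FALSE]
}

# GFF3 phases for CDS pieces given in sense (translation) order.
.phases_in_sense_order <- function(lens) {
  cum <- c(0L, cumsum(lens))[seq_along(lens)]
  as.integer((3L - cum %% 3L) %% 3L)
}

# Build genomic exon/CDS data.frames (with phases) for a transcript whose
# sense-space exon intervals are `ivs` (matrix) inside the given locus.
.tx_intervals <- function(ivs, locus_start, locus_len, strand) {
  sense_lens <- ivs[, 2] - ivs[, 1]
  phases <- .phases_in_sense_order(sense_lens)
  g <- cbind(if (strand == "+") locus_start + ivs[, 1] else locus_start + locus_len - ivs[, 2],
             if (strand == "+") locus_start + ivs[, 2] else locus_start + locus_len - ivs[, 1])
  df <- data.frame(start = as.integer(g[, 1]), end = as.integer(g[, 2]),
                   phase = phases)
  df[order(df$start), ]
}

#' Generate a synthetic genome with planted gene loci and feature map
#'
#' Builds `n_contigs` random DNA sequences at the requested GC content, with
#' optional telomeric `AACCT` tandem arrays on contig ends (reverse
#' complement at the 3' end), and plants gene loci whose coding structure is
#' fully recorded. Exon, intron and intergenic tracks of the returned
#' feature map exactly partition each contig; repeat and low-complexity
#' tracks are overlaid independently and may overlap everything else, the
#' way repeat annotations overlap genic and intergenic space in real
#' assemblies.
#'
#' Each planted locus contains a valid ORF (starts `ATG`, ends in a stop, no
#' internal stop). Loci flagged as *spare* carry a valid ORF but are left
#' out of the annotated feature partition; the gene-set generator uses them
#' to plant orthology-only gene predictions.
#'
#' @param n_contigs number of contigs (>= 1).
#' @param length_range two-element bp range for contig lengths (>= 1 kb).
#' @param gc GC fraction in (0, 1).
#' @param telomere_prob probability that each contig end carries a telomeric
#'   array of >= 25 motif copies.
#' @param genes_per_contig annotated gene loci planted per contig.
#' @param spare_per_contig unannotated (spare) loci planted per contig.
#' @param gene_spacing minimum intergenic gap between loci, bp.
#' @param exon_range range of exon counts per gene.
#' @param seed integer seed; identical inputs give byte-identical fixtures.
#' @return A list of class `synthetic_genome` with elements `contigs`
#'   ([contig_set()]), `features` ([feature_map()]), `loci` (planted-locus
#'   records), and `params`.
#' @export
generate_genome <- function(n_contigs = 3, length_range = c(40000, 60000),
                            gc = 0.35, telomere_prob = 1,
                            genes_per_contig = 5, spare_per_contig = 1,
                            gene_spacing = 2000, exon_range = c(1, 4),
                            seed = 1) {
  stopifnot(n_contigs >= 1, gc > 0, gc < 1, min(length_range) >= 1000,
            telomere_prob >= 0, telomere_prob <= 1)
  .seed_rng(seed)
  motif <- "AACCT"
  margin <- 1000L
  contigs <- character(0)
  loci <- list()
  exon_tr <- intron_tr <- gene_span_tr <- rep_tr <- low_tr <- NULL
  gene_counter <- 0L
  for (ci in seq_len(n_contigs)) {
    cid <- sprintf("ctg%02d", ci)
    L <- as.integer(round(stats::runif(1, length_range[1], length_range[2])))
    seqv <- .rand_dna(L, gc)
    telo <- c(`5p` = FALSE, `3p` = FALSE)
    rep_iv <- list()
    if (stats::runif(1) < telomere_prob) {
      ncp <- sample(25:40, 1)
      seqv[seq_len(5L * ncp)] <- strsplit(strrep(motif, ncp), "")[[1]]
      telo["5p"] <- TRUE
      rep_iv[[length(rep_iv) + 1L]] <- c(0L, 5L * ncp)
    }
    if (stats::runif(1) < telomere_prob) {
      ncp <- sample(25:40, 1)
      rcm <- revcomp(motif)
      seqv[(L - 5L * ncp + 1L):L] <- strsplit(strrep(rcm, ncp), "")[[1]]
      telo["3p"] <- TRUE
      rep_iv[[length(rep_iv) + 1L]] <- c(L - 5L * ncp, L)
    }

    n_loci <- genes_per_contig + spare_per_contig
    ctg_loci <- list()
    if (n_loci > 0) {
      spare_flag <- rep(FALSE, n_loci)
      if (spare_per_contig > 0) {
        spare_flag[sample(seq_len(n_loci), spare_per_contig)] <- TRUE
      }
      built <- lapply(seq_len(n_loci), function(i) {
        k <- sample(exon_range[1]:exon_range[2], 1)
        .make_locus(n_exons = k, n_codons = sample((2 * k + 8):90, 1),
                    ext_codons = sample(5:15, 1))
      })
      lens <- vapply(built, function(x) nchar(x$seq), integer(1))
      need <- sum(lens) + (n_loci + 1L) * gene_spacing + 2L * margin
      if (need > L) {
        stop("cannot place ", n_loci, " gene loci on contig ", cid,
             ": need ", need, " bp but contig has ", L)
      }
      slack <- L - need
      w <- stats::rexp(n_loci + 1L)
      extra <- floor(slack * w / sum(w))
      pos <- margin
      for (i in seq_len(n_loci)) {
        pos <- pos + gene_spacing + extra[i]
        locus_start <- as.integer(pos)
        lc <- built[[i]]
        strand <- sample(c("+", "-"), 1)
        locus_len <- nchar(lc$seq)
        sseq <- if (strand == "+") lc$seq else revcomp(lc$seq)
        seqv[(locus_start + 1L):(locus_start + locus_len)] <- strsplit(sseq, "")[[1]]
        gene_counter <- gene_counter + 1L
        ctg_loci[[i]] <- list(
          gene_num = gene_counter, contig = cid, strand = strand,
          start = locus_start, locus_len = locus_len,
          orf_exons = lc$orf_exons, orf_end = lc$orf_end,
          ext_end = lc$ext_end, n_codons = lc$n_codons,
          n_exons = nrow(lc$orf_exons), spare = spare_flag[i]
        )
        pos <- pos + locus_len
      }
    }
    contigs[cid] <- paste(seqv, collapse = "")
    loci <- c(loci, ctg_loci)

    # annotated partition: exon/intron from non-spare primary transcripts
    for (lc in ctg_loci) {
      if (lc$spare) next
      ex <- .map_ivs(lc$orf_exons, lc$start, lc$locus_len, lc$strand)
      exon_tr <- rbind(exon_tr, data.frame(contig = cid, start = ex[, 1], end = ex[, 2]))
      gene_span_tr <- rbind(gene_span_tr,
                            data.frame(contig = cid, start = min(ex[, 1]), end = max(ex[, 2])))
      if (nrow(ex) > 1) {
        intron_tr <- rbind(intron_tr,
                           data.frame(contig = cid,
                                      start = ex[-nrow(ex), 2], end = ex[-1, 1]))
      }
    }
    # repeat / low-complexity overlays (independent of the partition)
    n_rep <- max(1L, L %/% 20000L)
    for (i in seq_len(n_rep)) {
      w <- sample(500:3000, 1)
      s <- sample.int(L - w, 1)
      rep_iv[[length(rep_iv) + 1L]] <- c(s, s + w)
    }
    rep_tr <- rbind(rep_tr, data.frame(contig = cid,
                                       start = vapply(rep_iv, `[`, integer(1), 1),
                                       end = vapply(rep_iv, `[`, integer(1), 2)))
    n_low <- max(1L, L %/% 30000L)
    lows <- t(vapply(seq_len(n_low), function(i) {
      w <- sample(50:300, 1)
      s <- sample.int(L - w, 1)
      c(s, s + w)
    }, integer(2)))
    low_tr <- rbind(low_tr, data.frame(contig = cid, start = lows[, 1], end = lows[, 2]))
  }

  lens <- stats::setNames(nchar(contigs), names(contigs))
  # intergenic = complement of annotated gene spans
  inter_tr <- NULL
  for (cid in names(lens)) {
    sp <- if (is.null(gene_span_tr)) NULL else gene_span_tr[gene_span_tr$contig == cid, , drop = FALSE]
    if (is.null(sp) || nrow(sp) == 0) {
      inter_tr <- rbind(inter_tr, data.frame(contig = cid, start = 0L, end = lens[[cid]]))
      next
    }
    sp <- sp[order(sp$start), ]
    bounds <- c(0L, as.vector(t(sp[, c("start", "end")])), lens[[cid]])
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- starts < ends
    inter_tr <- rbind(inter_tr, data.frame(contig = cid, start = starts[keep], end = ends[keep]))
  }
  feats <- feature_map(list(
    exon = if (is.null(exon_tr)) data.frame(contig = character(), start = integer(), end = integer()) else exon_tr,
    intron = if (is.null(intron_tr)) data.frame(contig = character(), start = integer(), end = integer()) else intron_tr,
    intergenic = inter_tr,
    `repeat` = rep_tr,
    low_complexity = low_tr
  ), lens)
  structure(list(contigs = contig_set(contigs), features = feats, loci = loci,
                 params = list(gc = gc, telomere_prob = telomere_prob,
                               gene_spacing = gene_spacing, seed = seed)),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome:", length(x$contigs), "contig(s),",
      sum(contig_lengths(x$contigs)), "bp,",
      length(x$loci), "planted locus/loci (",
      sum(vapply(x$loci, function(l) l$spare, logical(1))), "spare )\n")
  invisible(x)
}
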