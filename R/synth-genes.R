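# Synthetic gene-model sets with planted annotation defects.
#
# The evidence set mimics a transcript/protein-based predictor; the
# orthology set mimics projection from a related reference genome and
# carries loss-classification labels plus the id of the projected source
# gene. Each defect class the reconciliation pipeline removes can be planted
# in known numbers, and every plant is recorded in a truth ledger keyed by
# gene/transcript id so recovery can be checked exactly.

#' Default defect configuration (all zero)
#'
#' Supported defect classes:
#' \describe{
#'   \item{multilocus}{pairs of evidence genes fused under one gene id whose
#'     transcripts do not overlap (to be split).}
#'   \item{internal_stop}{extra evidence transcripts whose CDS runs through
#'     the ORF stop into an in-frame extension ending at a second stop.}
#'   \item{missing_start}{extra orthology transcripts starting at codon 2.}
#'   \item{missing_stop}{extra orthology transcripts truncated before the
#'     stop codon.}
#'   \item{micro_intron}{orthology primary transcripts whose largest exon is
#'     split by a spurious 1-3 bp intron.}
#'   \item{cross_scaffold}{extra orthology transcripts of a source-gene group
#'     placed on a different contig.}
#'   \item{bad_loss_class}{extra orthology transcripts labelled `lost` or
#'     `missing`.}
#'   \item{unique_isoform}{orthology-only intron-retained isoforms of
#'     multi-exon genes (valid ORFs, novel intron chain) that the merge must
#'     add to the evidence gene.}
#' }
#' @return Named list of zero counts.
#' @export
defect_config <- function() {
  list(multilocus = 0L, internal_stop = 0L, missing_start = 0L,
       missing_stop = 0L, micro_intron = 0L, cross_scaffold = 0L,
       bad_loss_class = 0L, unique_isoform = 0L)
}

.ledger_row <- function(kind, gene_id = NA, transcript_id = NA, detail = NA) {
  data.frame(kind = kind, gene_id = as.character(gene_id),
             transcript_id = as.character(transcript_id),
             detail = as.character(detail))
}

#' Write / read a truth ledger as TSV
#' @param ledger data.frame ledger.
#' @param path file path.
#' @return `path` (write) or the ledger data.frame (read).
#' @export
write_ledger <- function(ledger, path) {
  utils::write.table(ledger, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, colClasses = "character")
}

# pick n items from pool without replacement, with a clear constraint error
.pick <- function(pool, n, what) {
  if (n > length(pool)) {
    stop("cannot plant ", n, " ", what, " defect(s): only ", length(pool),
         " eligible locus/loci")
  }
  if (n == 0) return(pool[0])
  pool[sample.int(length(pool), n)]
}

#' Generate evidence and orthology gene-model sets with planted defects
#'
#' Derives two raw annotation sets from the planted loci of a
#' [generate_genome()] object. With an all-zero defect configuration both
#' sets are already clean and pass reconciliation unchanged (the orthology
#' primaries are exact duplicates of the evidence primaries, and spare loci
#' become orthology-only genes). Every planted defect is recorded in the
#' returned truth ledger.
#'
#' @param genome a `synthetic_genome`.
#' @param defects named list of defect counts, see [defect_config()].
#' @param seed integer seed.
#' @return list with `evidence`, `orthology` (both [gene_model_set()]) and
#'   `ledger` (data.frame: kind, gene_id, transcript_id, detail).
#' @export
generate_gene_sets <- function(genome, defects = defect_config(), seed = 1) {
  stopifnot(inherits(genome, "synthetic_genome"))
  cfg <- utils::modifyList(defect_config(), defects)
  if (any(unlist(cfg) < 0)) stop("defect counts must be >= 0")
  .seed_rng(.child_seed(seed, "gene_sets"))

  loci <- genome$loci
  if (length(loci) == 0) stop("genome has no planted loci")
  main <- Filter(function(l) !l$spare, loci)
  spare <- Filter(function(l) l$spare, loci)
  num <- function(l) l$gene_num
  ledger <- NULL

  ev_tx <- ev_ex <- ev_cd <- NULL
  or_tx <- or_ex <- or_cd <- NULL
  add_tx <- function(store, tid, gid, l, ivs_sense, source, loss_class = NA,
                     source_gene = NA) {
    iv <- .tx_intervals(ivs_sense, l$start, l$locus_len, l$strand)
    list(tx = data.frame(transcript_id = tid, gene_id = gid, contig = l$contig,
                         strand = l$strand, source = source,
                         loss_class = as.character(loss_class),
                         source_gene = as.character(source_gene)),
         ex = data.frame(transcript_id = tid, start = iv$start, end = iv$end),
         cd = data.frame(transcript_id = tid, start = iv$start, end = iv$end,
                         phase = iv$phase))
  }

  # ---- evidence set ---------------------------------------------------
  ev_gene_id <- stats::setNames(sprintf("Eg%03d", vapply(main, num, integer(1))),
                                vapply(main, num, integer(1)))
  # multilocus fusions: pairs of genes on the same contig and strand share
  # one gene id; their transcripts do not overlap, so splitting recovers them
  if (cfg$multilocus > 0) {
    key <- vapply(main, function(l) paste(l$contig, l$strand), character(1))
    pairs <- list()
    for (k in unique(key)) {
      idx <- which(key == k)
      while (length(idx) >= 2) {
        pairs[[length(pairs) + 1L]] <- idx[1:2]
        idx <- idx[-(1:2)]
      }
    }
    if (cfg$multilocus > length(pairs)) {
      stop("cannot plant ", cfg$multilocus, " multilocus defect(s): only ",
           length(pairs), " same-contig same-strand gene pair(s) available")
    }
    pairs <- pairs[sample(seq_along(pairs), cfg$multilocus)]
    for (p in pairs) {
      a <- main[[p[1]]]; b <- main[[p[2]]]
      fused <- sprintf("Eg%03dm", num(a))
      ev_gene_id[as.character(num(a))] <- fused
      ev_gene_id[as.character(num(b))] <- fused
      ledger <- rbind(ledger, .ledger_row("multilocus", fused,
                                          detail = sprintf("members=%d,%d", num(a), num(b))))
    }
  }
  for (l in main) {
    tid <- sprintf("Et%03d.1", num(l))
    r <- add_tx(NULL, tid, ev_gene_id[as.character(num(l))], l, l$orf_exons, "evidence")
    ev_tx <- rbind(ev_tx, r$tx); ev_ex <- rbind(ev_ex, r$ex); ev_cd <- rbind(ev_cd, r$cd)
  }
  stop_genes <- .pick(seq_along(main), cfg$internal_stop, "internal_stop")
  for (i in stop_genes) {
    l <- main[[i]]
    ivs <- l$orf_exons
    ivs[nrow(ivs), 2] <- l$ext_end  # run through the stop into the extension
    tid <- sprintf("Et%03d.stop", num(l))
    r <- add_tx(NULL, tid, ev_gene_id[as.character(num(l))], l, ivs, "evidence")
    ev_tx <- rbind(ev_tx, r$tx); ev_ex <- rbind(ev_ex, r$ex); ev_cd <- rbind(ev_cd, r$cd)
    ledger <- rbind(ledger, .ledger_row("internal_stop", r$tx$gene_id, tid))
  }

  # ---- orthology set --------------------------------------------------
  ok_class <- c("intact", "partially intact", "uncertain loss")
  micro_genes <- .pick(seq_along(main), cfg$micro_intron, "micro_intron")
  widths <- if (cfg$micro_intron > 0) rep_len(1:3, cfg$micro_intron) else integer(0)
  for (li in seq_along(loci)) {
    l <- loci[[li]]
    gid <- sprintf("Og%03d", num(l))
    tid <- sprintf("Ot%03d.1", num(l))
    src <- sprintf("src%03d", num(l))
    cls <- sample(ok_class, 1, prob = c(0.7, 0.2, 0.1))
    r <- add_tx(NULL, tid, gid, l, l$orf_exons, "orthology", cls, src)
    or_tx <- rbind(or_tx, r$tx)
    or_ex <- rbind(or_ex, r$ex); or_cd <- rbind(or_cd, r$cd)
    if (l$spare) {
      ledger <- rbind(ledger, .ledger_row("unique_gene", gid, tid))
    }
  }
  # micro-intron: split the widest exon of the orthology primary by a 1-3 bp
  # gap; joining the exons back restores the original transcript exactly
  for (j in seq_along(micro_genes)) {
    l <- main[[micro_genes[j]]]
    tid <- sprintf("Ot%03d.1", num(l))
    g <- widths[j]
    ex <- or_ex[or_ex$transcript_id == tid, , drop = FALSE]
    wi <- which.max(ex$end - ex$start)
    A <- ex$start[wi]; B <- ex$end[wi]
    M <- A + (B - A) %/% 2L
    new_ex <- rbind(ex[-wi, c("start", "end")],
                    data.frame(start = c(A, M + g), end = c(M, B)))
    new_ex <- new_ex[order(new_ex$start), ]
    or_ex <- or_ex[or_ex$transcript_id != tid, , drop = FALSE]
    or_ex <- rbind(or_ex, data.frame(transcript_id = tid, start = new_ex$start,
                                     end = new_ex$end))
    lens <- new_ex$end - new_ex$start
    ord <- if (l$strand == "+") order(new_ex$start) else order(-new_ex$start)
    ph <- integer(nrow(new_ex))
    ph[ord] <- .phases_in_sense_order(lens[ord])
    or_cd <- or_cd[or_cd$transcript_id != tid, , drop = FALSE]
    or_cd <- rbind(or_cd, data.frame(transcript_id = tid, start = new_ex$start,
                                     end = new_ex$end, phase = ph))
    ledger <- rbind(ledger, .ledger_row("micro_intron", sprintf("Og%03d", num(l)),
                                        tid, detail = sprintf("width=%d", g)))
  }
  # missing start / missing stop: extra transcripts on intact genes
  ms_genes <- .pick(seq_along(main), cfg$missing_start, "missing_start")
  for (i in ms_genes) {
    l <- main[[i]]
    ivs <- l$orf_exons; ivs[1, 1] <- ivs[1, 1] + 3L
    tid <- sprintf("Ot%03d.nostart", num(l))
    r <- add_tx(NULL, tid, sprintf("Og%03d", num(l)), l, ivs, "orthology",
                "intact", sprintf("src%03d", num(l)))
    or_tx <- rbind(or_tx, r$tx); or_ex <- rbind(or_ex, r$ex); or_cd <- rbind(or_cd, r$cd)
    ledger <- rbind(ledger, .ledger_row("missing_start", r$tx$gene_id, tid))
  }
  me_genes <- .pick(seq_along(main), cfg$missing_stop, "missing_stop")
  for (i in me_genes) {
    l <- main[[i]]
    ivs <- l$orf_exons; ivs[nrow(ivs), 2] <- ivs[nrow(ivs), 2] - 3L
    tid <- sprintf("Ot%03d.nostop", num(l))
    r <- add_tx(NULL, tid, sprintf("Og%03d", num(l)), l, ivs, "orthology",
                "intact", sprintf("src%03d", num(l)))
    or_tx <- rbind(or_tx, r$tx); or_ex <- rbind(or_ex, r$ex); or_cd <- rbind(or_cd, r$cd)
    ledger <- rbind(ledger, .ledger_row("missing_stop", r$tx$gene_id, tid))
  }
  # cross-scaffold: short extra transcript of the group on another contig
  if (cfg$cross_scaffold > 0 && length(genome$contigs) < 2) {
    stop("cannot plant cross_scaffold defects on a single-contig genome")
  }
  cs_genes <- .pick(seq_along(main), cfg$cross_scaffold, "cross_scaffold")
  for (i in cs_genes) {
    l <- main[[i]]
    other <- setdiff(names(genome$contigs), l$contig)[1]
    tid <- sprintf("Ot%03d.xscaf", num(l))
    pos <- 500L
    or_tx <- rbind(or_tx, data.frame(transcript_id = tid,
                                     gene_id = sprintf("Og%03d", num(l)),
                                     contig = other, strand = l$strand,
                                     source = "orthology", loss_class = "intact",
                                     source_gene = sprintf("src%03d", num(l))))
    or_ex <- rbind(or_ex, data.frame(transcript_id = tid, start = pos, end = pos + 30L))
    or_cd <- rbind(or_cd, data.frame(transcript_id = tid, start = pos,
                                     end = pos + 30L, phase = 0L))
    ledger <- rbind(ledger, .ledger_row("cross_scaffold", sprintf("Og%03d", num(l)),
                                        tid, detail = other))
  }
  # lost/missing loss-class labels on extra duplicate transcripts
  bl_genes <- .pick(seq_along(main), cfg$bad_loss_class, "bad_loss_class")
  for (i in bl_genes) {
    l <- main[[i]]
    cls <- sample(c("lost", "missing"), 1)
    tid <- sprintf("Ot%03d.lost", num(l))
    r <- add_tx(NULL, tid, sprintf("Og%03d", num(l)), l, l$orf_exons, "orthology",
                cls, sprintf("src%03d", num(l)))
    or_tx <- rbind(or_tx, r$tx); or_ex <- rbind(or_ex, r$ex); or_cd <- rbind(or_cd, r$cd)
    ledger <- rbind(ledger, .ledger_row("bad_loss_class", r$tx$gene_id, tid, cls))
  }
  # unique intron-retained isoforms on multi-exon genes (valid ORFs by
  # construction: introns are in-frame and stop-free)
  multi <- which(vapply(main, function(l) l$n_exons >= 2, logical(1)))
  ui_genes <- .pick(multi, cfg$unique_isoform, "unique_isoform (multi-exon)")
  for (i in ui_genes) {
    l <- main[[i]]
    ivs <- matrix(c(0L, l$orf_end), nrow = 1)
    tid <- sprintf("Ot%03d.ret", num(l))
    r <- add_tx(NULL, tid, sprintf("Og%03d", num(l)), l, ivs, "orthology",
                "intact", sprintf("src%03d", num(l)))
    or_tx <- rbind(or_tx, r$tx); or_ex <- rbind(or_ex, r$ex); or_cd <- rbind(or_cd, r$cd)
    ledger <- rbind(ledger, .ledger_row("unique_isoform",
                                        ev_gene_id[as.character(num(l))], tid))
  }

  if (is.null(ledger)) {
    ledger <- .ledger_row(character(0))[0, ]
  }
  list(
    evidence = gene_model_set(ev_tx, ev_ex, ev_cd),
    orthology = gene_model_set(or_tx, or_ex, or_cd),
    ledger = ledger
  )
}
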